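#' Configuration of the synthetic screen generator
#'
#' The generator emulates the statistical structure of a nine-chip podocyte
#' TopoChip screen: two chip density classes (six chips at 39 +/- 13 cells
#' per unit, three at 15 +/- 11), single-cell nuclear area with total SD 161
#' px^2 around a mean of 737 px^2 while unit means spread with SD 65 px^2,
#' a DAPI-phalloidin intensity correlation of 0.83 and a solidity versus
#' peripheral-actin-fraction correlation of -0.87.
#'
#' The nuclear-area variance is decomposed at build time into a within-unit
#' component `sigma_w` and a between-unit component `sigma_b` such that
#' `sigma_b^2 + sigma_w^2 = sd_total^2` and the variance of unit means,
#' `sigma_b^2 + sigma_w^2 * E[1/n]`, equals `unit_mean_sd^2`.  `E[1/n]` is
#' computed exactly from the two truncated rounded-normal count classes
#' (the harmonic moment, not the arithmetic mean count, is what drives the
#' spread of unit means when counts vary as strongly as they do here).
#' The decomposition fails, with the offending value reported, when
#' `unit_mean_sd` is too small to be reachable for the configured counts.
#'
#' The between-unit component is further split into a design effect shared
#' by the two replicate units of a design (`design_sd_frac * sigma_b`) and
#' an independent unit effect, so replicate-consistency filtering has real
#' signal to preserve.  Counts receive an analogous design effect.
#'
#' @param n_chips number of usable chips (default 9).
#' @param high_density_chips how many chips belong to the high-density class.
#' @param low_chip_ids indices of the low-density chips (default 4, 7, 8 for
#'   a nine-chip screen, otherwise the trailing chips).
#' @param count_mean_high,count_sd_high cells/unit in the high-density class.
#' @param count_mean_low,count_sd_low cells/unit in the low-density class.
#' @param nuc_area_mean,nuc_area_sd_total single-cell nuclear area mean and
#'   total SD, px^2.
#' @param unit_mean_sd target SD of per-unit mean nuclear area, px^2.
#' @param r_dapi_phalloidin target Pearson correlation of per-cell mean DAPI
#'   and phalloidin intensities.
#' @param r_solidity_peripheral target Pearson correlation of solidity and
#'   peripheral actin fraction.
#' @param design_sd_frac fraction of `sigma_b` attributed to the design
#'   (shared across replicates) rather than the individual unit.
#' @param lognormal_tail_weight mixture weight of a right-skew log-normal
#'   tail on single-cell nuclear area (0 keeps the decomposition exact).
#' @param border_rate,wall_rate Bernoulli rates of border / wall contact
#'   flags on cells (the object-level QC targets).
#' @param artifact_rates named numeric vector of planted-artifact fractions
#'   (see [plant_artifacts()]); all zero by default.
#' @param n_designs,n_rows,n_cols,flat_count chip geometry, as in
#'   [chip_layout()].
#' @param seed integer master seed.
#' @return An object of class `screen_config` (a validated list, including
#'   the solved `sigma_w`, `sigma_b`, `sigma_design` and `e_inv_n`).
#' @export
screen_config <- function(n_chips = 9, high_density_chips = 6,
                          low_chip_ids = NULL,
                          count_mean_high = 39, count_sd_high = 13,
                          count_mean_low = 15, count_sd_low = 11,
                          nuc_area_mean = 737, nuc_area_sd_total = 161,
                          unit_mean_sd = 65,
                          r_dapi_phalloidin = 0.83,
                          r_solidity_peripheral = -0.87,
                          design_sd_frac = 0.5,
                          lognormal_tail_weight = 0,
                          border_rate = 0.02, wall_rate = 0.02,
                          artifact_rates = NULL,
                          n_designs = 2176, n_rows = 66, n_cols = 66,
                          flat_count = 4, seed = 42) {
  stopifnot(n_chips >= 1, high_density_chips >= 0, high_density_chips <= n_chips,
            count_sd_high > 0, count_sd_low > 0,
            nuc_area_sd_total > 0, unit_mean_sd > 0,
            design_sd_frac >= 0, design_sd_frac <= 1,
            lognormal_tail_weight >= 0, lognormal_tail_weight < 1,
            border_rate >= 0, border_rate <= 0.5, wall_rate >= 0, wall_rate <= 0.5)
  if (abs(r_dapi_phalloidin) >= 1 || abs(r_solidity_peripheral) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)

  if (is.null(low_chip_ids)) {
    n_low <- n_chips - high_density_chips
    low_chip_ids <- if (n_chips == 9 && n_low == 3) c(4L, 7L, 8L)
                    else utils::tail(seq_len(n_chips), n_low)
  }
  low_chip_ids <- as.integer(low_chip_ids)
  if (length(low_chip_ids) != n_chips - high_density_chips ||
      any(low_chip_ids < 1 | low_chip_ids > n_chips) || anyDuplicated(low_chip_ids))
    stop("low_chip_ids must name exactly n_chips - high_density_chips distinct chips", call. = FALSE)

  rates <- c(underpopulated = 0, overpopulated = 0, out_of_focus = 0,
             ntoc_extreme = 0, replicate_inconsistent = 0)
  if (!is.null(artifact_rates)) {
    bad <- setdiff(names(artifact_rates), names(rates))
    if (length(bad)) stop("unknown artifact kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(artifact_rates < 0 | artifact_rates > 0.5))
      stop("artifact fractions must lie in [0, 0.5]", call. = FALSE)
    rates[names(artifact_rates)] <- artifact_rates
  }

  # exact E[1/n] for n = max(1, round(N(m, s))), mixed over the two classes
  w_high <- high_density_chips / n_chips
  e_inv_n <- w_high * e_inv_count(count_mean_high, count_sd_high) +
    (1 - w_high) * e_inv_count(count_mean_low, count_sd_low)

  s2 <- nuc_area_sd_total^2
  u2 <- unit_mean_sd^2
  if (u2 >= s2)
    stop("unit_mean_sd must be smaller than the single-cell SD", call. = FALSE)
  sigma_w2 <- (s2 - u2) / (1 - e_inv_n)
  sigma_b2 <- s2 - sigma_w2
  if (sigma_b2 < 0)
    stop(sprintf(paste0(
      "variance decomposition unsatisfiable: unit_mean_sd^2 = %.1f is below the ",
      "within-unit floor sd_total^2 * E[1/n] = %.1f (computed sigma_b^2 = %.1f)"),
      u2, s2 * e_inv_n, sigma_b2), call. = FALSE)

  structure(
    list(n_chips = n_chips, high_density_chips = high_density_chips,
         low_chip_ids = low_chip_ids,
         count_mean_high = count_mean_high, count_sd_high = count_sd_high,
         count_mean_low = count_mean_low, count_sd_low = count_sd_low,
         nuc_area_mean = nuc_area_mean, nuc_area_sd_total = nuc_area_sd_total,
         unit_mean_sd = unit_mean_sd,
         r_dapi_phalloidin = r_dapi_phalloidin,
         r_solidity_peripheral = r_solidity_peripheral,
         design_sd_frac = design_sd_frac,
         lognormal_tail_weight = lognormal_tail_weight,
         border_rate = border_rate, wall_rate = wall_rate,
         artifact_rates = rates,
         n_designs = n_designs, n_rows = n_rows, n_cols = n_cols,
         flat_count = flat_count, seed = as.integer(seed),
         sigma_w = sqrt(sigma_w2), sigma_b = sqrt(sigma_b2),
         sigma_design = design_sd_frac * sqrt(sigma_b2),
         e_inv_n = e_inv_n),
    class = "screen_config"
  )
}

# E[1/n] for n = max(1, round(X)), X ~ N(m, s); exact by enumeration.
e_inv_count <- function(m, s) {
  jmax <- max(2L, ceiling(m + 12 * s))
  j <- seq(2L, jmax)
  p1 <- stats::pnorm(1.5, m, s)
  pj <- stats::pnorm(j + 0.5, m, s) - stats::pnorm(j - 0.5, m, s)
  p1 + sum(pj / j)
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("synthetic screen config: %d chips (%d high density), %dx%d grid, %d designs\n",
              x$n_chips, x$high_density_chips, x$n_rows, x$n_cols, x$n_designs))
  cat(sprintf("counts: high %g +/- %g, low %g +/- %g (low chips: %s)\n",
              x$count_mean_high, x$count_sd_high, x$count_mean_low, x$count_sd_low,
              paste(x$low_chip_ids, collapse = ", ")))
  cat(sprintf("nuclear area: mean %g, SD %g (sigma_w %.1f, sigma_b %.1f, unit-mean SD target %g)\n",
              x$nuc_area_mean, x$nuc_area_sd_total, x$sigma_w, x$sigma_b, x$unit_mean_sd))
  cat(sprintf("seed %d\n", x$seed))
  invisible(x)
}

# Pearson attenuation of a Gaussian copula pushed through the Beta(8,2) /
# Beta(2,3) marginals used for solidity and peripheral actin fraction,
# measured once from the copula math (2e6 draws); the latent correlation is
# inflated by 1/COPULA_ATTENUATION so the realized Pearson r matches the
# configured target.
COPULA_ATTENUATION <- 0.9856

#' Generate a synthetic screen
#'
#' Draws a full cell-level feature table with the variance structure
#' described in [screen_config()]: per-unit counts from the chip's density
#' class (truncated at 1), nuclear area as mean + design effect + unit
#' effect + within-unit noise, correlated intensity and shape features, a
#' unit-level focus score, and Bernoulli border/wall contact flags.  If the
#' config carries nonzero `artifact_rates` the artifacts are planted before
#' returning (see [plant_artifacts()]).
#'
#' @param cfg a [screen_config()].
#' @return An object of class `synthetic_screen`: list with `config`,
#'   `layout` (a [chip_layout()]), `cells` (one row per cell), `units`
#'   (per-unit aggregates, see [aggregate_units()]) and `truth` (the
#'   planted-artifact registry, empty on a clean screen).
#' @examples
#' scr <- generate_screen(screen_config(n_chips = 2, n_designs = 6,
#'                                      n_rows = 4, n_cols = 4, seed = 1))
#' nrow(scr$cells)
#' @export
generate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  layout <- chip_layout(cfg$n_designs, cfg$n_rows, cfg$n_cols,
                        cfg$flat_count, seed = cfg$seed)
  rng <- local_rng(cfg$seed + 1L)

  ids <- if (cfg$n_designs > 0) design_ids(cfg$n_designs) else character()
  all_ids <- c(ids, "FLAT")
  # design effects, shared by the two replicate units of a design; the flat
  # control carries none
  area_eff <- c(rng$rnorm(length(ids), 0, cfg$sigma_design), 0)
  sd_cd <- min(cfg$count_sd_high, cfg$count_sd_low) / 2
  count_eff <- c(rng$rnorm(length(ids), 0, sd_cd), 0)
  names(area_eff) <- names(count_eff) <- all_ids

  grid <- as.data.frame(layout)
  units <- do.call(rbind, lapply(seq_len(cfg$n_chips), function(i) {
    g <- grid
    g$chip_id <- sprintf("chip%d", i)
    g$density_class <- if (i %in% cfg$low_chip_ids) "low" else "high"
    g
  }))
  n_units <- nrow(units)

  is_low <- units$density_class == "low"
  m <- ifelse(is_low, cfg$count_mean_low, cfg$count_mean_high) +
    count_eff[units$design_id]
  s <- ifelse(is_low,
              sqrt(cfg$count_sd_low^2 - sd_cd^2),
              sqrt(cfg$count_sd_high^2 - sd_cd^2))
  units$cell_count <- pmax(1L, as.integer(round(rng$rnorm(n_units, m, s))))

  sigma_bu <- sqrt(cfg$sigma_b^2 - cfg$sigma_design^2)
  units$unit_area_eff <- area_eff[units$design_id] + rng$rnorm(n_units, 0, sigma_bu)
  units$unit_focus <- rng$rnorm(n_units, 1, 0.05)

  idx <- rep(seq_len(n_units), units$cell_count)
  n_cells <- length(idx)
  cells <- data.frame(
    chip_id = units$chip_id[idx],
    row = units$row[idx],
    col = units$col[idx],
    design_id = units$design_id[idx],
    stringsAsFactors = FALSE
  )
  cells$cell_id <- sprintf("%s_r%02d_c%02d_%04d", cells$chip_id, cells$row, cells$col,
                           sequence(units$cell_count))

  area <- cfg$nuc_area_mean + units$unit_area_eff[idx] +
    rng$rnorm(n_cells, 0, cfg$sigma_w)
  if (cfg$lognormal_tail_weight > 0) {
    mix <- rng$runif(n_cells) < cfg$lognormal_tail_weight
    area[mix] <- cfg$nuc_area_mean *
      rng$rlnorm(sum(mix), meanlog = 0, sdlog = cfg$nuc_area_sd_total / cfg$nuc_area_mean)
  }
  cells$nuclear_area <- pmax(area, 1)
  cells$nucleus_diameter <- 2 * sqrt(cells$nuclear_area / pi)
  cells$nuclear_perimeter <- 2 * sqrt(pi * cells$nuclear_area) *
    (1 + abs(rng$rnorm(n_cells, 0, 0.08)))  # at or above the circle minimum

  cyto_ratio <- rng$rlnorm(n_cells, meanlog = log(6), sdlog = 0.15)
  cells$cell_area <- cells$nuclear_area * cyto_ratio
  cells$cell_perimeter <- 2 * sqrt(pi * cells$cell_area) *
    (1 + abs(rng$rnorm(n_cells, 0, 0.25)))

  z <- rng$mvnorm2(n_cells, cfg$r_dapi_phalloidin)
  cells$mean_dapi <- 500 + 100 * z[, 1]
  cells$mean_phalloidin <- 300 + 80 * z[, 2]

  rz <- max(-0.999, min(0.999, cfg$r_solidity_peripheral / COPULA_ATTENUATION))
  zc <- rng$mvnorm2(n_cells, rz)
  cells$solidity <- stats::qbeta(stats::pnorm(zc[, 1]), 8, 2)
  cells$peripheral_actin_fraction <- stats::qbeta(stats::pnorm(zc[, 2]), 2, 3)

  cells$focus_score <- units$unit_focus[idx] + rng$rnorm(n_cells, 0, 0.01)
  cells$touches_border <- rng$runif(n_cells) < cfg$border_rate
  cells$touches_wall <- rng$runif(n_cells) < cfg$wall_rate

  scr <- structure(
    list(config = cfg, layout = layout, cells = cells,
         units = aggregate_units(cells),
         truth = empty_truth()),
    class = "synthetic_screen"
  )
  if (any(cfg$artifact_rates > 0))
    scr <- plant_artifacts(scr, cfg$artifact_rates, seed = cfg$seed + 2L)
  scr
}

empty_truth <- function() {
  data.frame(kind = character(), chip_id = character(), row = integer(),
             col = integer(), design_id = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf("synthetic screen: %d chips, %d units, %d cells\n",
              x$config$n_chips, nrow(x$units), nrow(x$cells)))
  if (nrow(x$truth))
    cat("planted artifacts:", paste(sprintf("%s (%d)", names(table(x$truth$kind)),
                                            as.integer(table(x$truth$kind))), collapse = ", "), "\n")
  invisible(x)
}

#' Plant QC artifacts into a synthetic screen
#'
#' Corrupts a seeded selection of units (or designs) and records every
#' corruption in the screen's truth registry, so QC filters can be scored
#' against known ground truth.  Kinds:
#'
#' * `underpopulated` / `overpopulated`: the unit's cell list is cut to
#'   1-5 cells, or padded with jittered copies to 70-90 cells.
#' * `out_of_focus`: the unit's focus scores are shifted down by 0.5.
#' * `ntoc_extreme`: the unit's cell areas are shrunk to 1.05x the nuclear
#'   area, driving the nucleus-to-cytoplasm ratio to an extreme value.
#' * `replicate_inconsistent`: for a fraction of designs, the cells of one
#'   of the design's two replicate positions (across all chips) have their
#'   nuclear area shifted by `shift_sd` pooled SDs.
#'
#' For the unit-level kinds, `floor(rate * n_units)` distinct units are
#' corrupted; units are never corrupted twice, so re-planting on an already
#' planted screen adds nothing that would overlap.
#'
#' @param screen a `synthetic_screen`.
#' @param rates named numeric vector; names among the kinds above, values in
#'   `[0, 0.5]`.
#' @param seed integer seed for the selection.
#' @param shift_sd location shift of the inconsistent replicate, in units of
#'   the pooled single-cell nuclear-area SD (default 3).
#' @return the modified `synthetic_screen` (units re-aggregated, truth
#'   registry extended).
#' @export
plant_artifacts <- function(screen, rates, seed = 1L, shift_sd = 3) {
  stopifnot(inherits(screen, "synthetic_screen"))
  kinds <- c("underpopulated", "overpopulated", "out_of_focus",
             "ntoc_extreme", "replicate_inconsistent")
  bad <- setdiff(names(rates), kinds)
  if (length(bad)) stop("unknown artifact kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(rates > 0.5)) stop("artifact rates above 0.5 break the QC assumptions", call. = FALSE)
  rates <- rates[rates > 0]
  if (!length(rates)) return(screen)

  rng <- local_rng(seed)
  cells <- screen$cells
  truth <- screen$truth
  units <- unique(cells[c("chip_id", "row", "col", "design_id")])
  ukey <- function(df) paste(df$chip_id, df$row, df$col)
  taken <- ukey(truth)

  pick_units <- function(n) {
    avail <- which(!(ukey(units) %in% taken))
    sel <- avail[rng$sample(length(avail), size = min(n, length(avail)))]
    taken <<- c(taken, ukey(units[sel, ]))
    units[sel, , drop = FALSE]
  }
  record <- function(kind, u, detail) {
    truth <<- rbind(truth, data.frame(
      kind = kind, chip_id = u$chip_id, row = u$row, col = u$col,
      design_id = u$design_id, detail = detail, stringsAsFactors = FALSE))
  }
  cell_unit <- match(paste(cells$chip_id, cells$row, cells$col), ukey(units))

  for (kind in intersect(names(rates), kinds)) {
    if (kind == "replicate_inconsistent") next
    n_sel <- floor(rates[[kind]] * nrow(units))
    if (n_sel == 0) next
    sel <- pick_units(n_sel)
    sel_idx <- match(ukey(sel), ukey(units))
    if (kind == "underpopulated") {
      keep_n <- 1L + as.integer(rng$runif(nrow(sel)) * 5)  # 1..5 cells kept
      drop_idx <- integer()
      for (i in seq_len(nrow(sel))) {
        rows <- which(cell_unit == sel_idx[i])
        if (length(rows) > keep_n[i]) drop_idx <- c(drop_idx, rows[-seq_len(keep_n[i])])
      }
      if (length(drop_idx)) {
        cells <- cells[-drop_idx, ]
        cell_unit <- cell_unit[-drop_idx]
      }
      record(kind, sel, sprintf("kept %d cells", keep_n))
    } else if (kind == "overpopulated") {
      target <- 70L + as.integer(rng$runif(nrow(sel)) * 21)  # 70..90 cells
      add <- vector("list", nrow(sel))
      add_unit <- vector("list", nrow(sel))
      for (i in seq_len(nrow(sel))) {
        rows <- which(cell_unit == sel_idx[i])
        need <- target[i] - length(rows)
        if (need > 0) {
          src <- rows[1L + as.integer(rng$runif(need) * length(rows))]
          dup <- cells[src, ]
          dup$nuclear_area <- dup$nuclear_area * (1 + rng$rnorm(need, 0, 0.05))
          dup$cell_id <- paste0(dup$cell_id, "_dup", seq_len(need))
          add[[i]] <- dup
          add_unit[[i]] <- rep(sel_idx[i], need)
        }
      }
      add <- do.call(rbind, add)
      if (!is.null(add)) {
        cells <- rbind(cells, add)
        cell_unit <- c(cell_unit, unlist(add_unit))
      }
      record(kind, sel, sprintf("padded to %d cells", target))
    } else if (kind == "out_of_focus") {
      hit <- cell_unit %in% sel_idx
      cells$focus_score[hit] <- cells$focus_score[hit] - 0.5
      record(kind, sel, "focus shifted by -0.5")
    } else if (kind == "ntoc_extreme") {
      hit <- cell_unit %in% sel_idx
      cells$cell_area[hit] <- cells$nuclear_area[hit] * 1.05
      record(kind, sel, "cell area shrunk to 1.05x nucleus")
    }
  }

  if ("replicate_inconsistent" %in% names(rates)) {
    lay <- screen$layout
    designs <- setdiff(unique(as.vector(lay$design_at)), "FLAT")
    n_sel <- floor(rates[["replicate_inconsistent"]] * length(designs))
    if (n_sel > 0) {
      sel_designs <- designs[rng$sample(length(designs), size = n_sel)]
      shift <- shift_sd * screen$config$nuc_area_sd_total
      for (d in sel_designs) {
        pos <- which(lay$design_at == d, arr.ind = TRUE)
        p <- pos[1L + as.integer(rng$runif(1) * nrow(pos)), , drop = FALSE]
        hit <- cells$row == p[1, "row"] & cells$col == p[1, "col"]
        cells$nuclear_area[hit] <- cells$nuclear_area[hit] + shift
        u <- unique(cells[hit, c("chip_id", "row", "col", "design_id")])
        if (nrow(u)) {
          truth <- rbind(truth, data.frame(
            kind = "replicate_inconsistent", chip_id = u$chip_id, row = u$row,
            col = u$col, design_id = d,
            detail = sprintf("nuclear_area shifted by %+.1f", shift),
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  rownames(cells) <- NULL
  screen$cells <- cells
  screen$units <- aggregate_units(cells)
  screen$truth <- truth
  screen
}

#' Synthetic topography-design-descriptor table
#'
#' Draws a TDD table with the descriptor families the field uses to
#' parameterize pillar patterns (pillar length, circularity, internal
#' asymmetry, roughness, pattern density, pillar spacing).  Descriptors are
#' mildly correlated with nothing; they exist so the ranking/split/model
#' matrix stages have realistic inputs.
#'
#' @param design_ids character vector of design ids (no `FLAT`).
#' @param seed integer seed.
#' @return data.frame: `design_id` plus six numeric descriptor columns.
#' @export
synthetic_design_table <- function(design_ids, seed = 1L) {
  stopifnot(length(design_ids) >= 1, !anyDuplicated(design_ids))
  rng <- local_rng(seed)
  n <- length(design_ids)
  data.frame(
    design_id = design_ids,
    pillar_length = rng$rlnorm(n, log(10), 0.4),
    circularity = stats::qbeta(rng$runif(n), 4, 2),
    internal_asymmetry = rng$runif(n),
    roughness = rng$rlnorm(n, log(0.5), 0.3),
    pattern_density = stats::qbeta(rng$runif(n), 2, 2),
    pillar_spacing = rng$rlnorm(n, log(5), 0.3),
    stringsAsFactors = FALSE
  )
}
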