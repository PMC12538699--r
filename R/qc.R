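#' Object-level QC: nucleus size band and contact rules
#'
#' Drops cells whose nucleus diameter falls outside `[diam_min, diam_max]`
#' pixels (band inclusive), cells touching the image border, and cells
#' whose cell body touches the walls separating TopoUnits (the linkage
#' rule: wall contact of the secondary object removes the whole cell
#' record).  Each removed cell is logged with the first rule it failed, in
#' the order diameter, border, wall.
#'
#' @param cells data.frame with `nucleus_diameter`, `touches_border`,
#'   `touches_wall` (and a `cell_id` for the log).
#' @param diam_min,diam_max inclusive nucleus diameter band, px.
#' @return list: `retained` (data.frame), `removed` (data.frame),
#'   `log` (data.frame `cell_id`, `rule`), `tier` (ledger tier record).
#' @export
filter_objects <- function(cells, diam_min = 15, diam_max = 65) {
  if (diam_min >= diam_max) stop("diam_min must be below diam_max", call. = FALSE)
  if (!nrow(cells)) {
    return(list(retained = cells, removed = cells,
                log = data.frame(cell_id = character(), rule = character()),
                tier = ledger_tier("object filters", 0L, 0L)))
  }
  rule <- rep(NA_character_, nrow(cells))
  bad_diam <- cells$nucleus_diameter < diam_min | cells$nucleus_diameter > diam_max
  rule[bad_diam] <- "diameter"
  hit <- is.na(rule) & cells$touches_border
  rule[hit] <- "border-contact"
  hit <- is.na(rule) & cells$touches_wall
  rule[hit] <- "wall-contact"
  removed <- !is.na(rule)
  list(
    retained = cells[!removed, , drop = FALSE],
    removed = cells[removed, , drop = FALSE],
    log = data.frame(cell_id = if ("cell_id" %in% names(cells)) cells$cell_id[removed]
                     else which(removed),
                     rule = rule[removed], stringsAsFactors = FALSE),
    tier = ledger_tier("object filters", 0L, sum(removed))
  )
}

#' IQR-based acceptance bounds
#'
#' Quartiles by linear interpolation between order statistics (the common
#' type-7 rule; switchable), bounds at `q1 - k * IQR` and `q3 + k * IQR`.
#'
#' @param values numeric sample of at least 4 values.
#' @param k IQR multiplier (default 1.5).
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return object of class `iqr_bounds`: list with `q1`, `q3`, `iqr`, `k`,
#'   `lower`, `upper`, `type`.
#' @export
iqr_bounds <- function(values, k = 1.5, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values for IQR bounds", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, k = k,
                 lower = q[1] - k * iqr, upper = q[2] + k * iqr, type = type),
            class = "iqr_bounds")
}

#' @export
print.iqr_bounds <- function(x, ...) {
  cat(sprintf("IQR bounds: q1 %.4g, q3 %.4g, k %.3g -> accept [%.4g, %.4g]\n",
              x$q1, x$q3, x$k, x$lower, x$upper))
  invisible(x)
}

#' Unit-level IQR filter
#'
#' Computes [iqr_bounds()] on one unit-level column and retains the units
#' inside `[lower, upper]` (inclusive).  Pass a precomputed `bounds` to
#' re-apply frozen thresholds (the filter never re-estimates on its own
#' output, so re-application cannot cascade).
#'
#' @param units a [aggregate_units()] data.frame.
#' @param feature unit column name (e.g. `"cell_count"`,
#'   `"focus_score_mean"`).
#' @param k IQR multiplier.
#' @param bounds optional frozen [iqr_bounds()].
#' @return list: `retained`, `removed`, `bounds`, `tier`.
#' @export
iqr_unit_filter <- function(units, feature, k = 1.5, bounds = NULL) {
  col <- if (feature %in% names(units)) feature else paste0(feature, "_mean")
  if (!col %in% names(units)) stop("unknown unit feature: ", feature, call. = FALSE)
  x <- units[[col]]
  if (is.null(bounds)) bounds <- iqr_bounds(x, k = k)
  out <- !is.na(x) & x >= bounds$lower & x <= bounds$upper
  list(retained = units[out, , drop = FALSE],
       removed = units[!out, , drop = FALSE],
       bounds = bounds,
       tier = ledger_tier(sprintf("IQR filter (%s, k=%.3g)", col, bounds$k),
                          sum(!out), sum(units$cell_count[!out])))
}

#' Cell-count stability band
#'
#' Derives the acceptable cells-per-unit range from CV-versus-count curves:
#' the maximal contiguous run of counts (over the counts observed in every
#' curve) on which each curve's CV stays at or below `cv_ceiling` times
#' that curve's minimum CV.  When no count qualifies, the fixed default
#' band of 11-64 cells is returned with a warning.
#'
#' @param curves list of [cv_by_count()] curves (at least one).
#' @param cv_ceiling multiplier on each curve's minimum CV (> 0).
#' @param fallback fixed band used when no contiguous range qualifies.
#' @return object of class `count_band`: list with `lower`, `upper`,
#'   `provenance` (`"derived_from_cv"` or `"fixed"`).
#' @export
select_count_band <- function(curves, cv_ceiling = 1.5, fallback = c(11, 64)) {
  if (inherits(curves, "cv_curve")) curves <- list(curves)
  if (!length(curves)) stop("need at least one CV curve", call. = FALSE)
  if (cv_ceiling <= 0) stop("cv_ceiling must be positive", call. = FALSE)
  common <- Reduce(intersect, lapply(curves, function(cu) cu$count))
  common <- sort(common)
  ok <- rep(TRUE, length(common))
  for (cu in curves) {
    thr <- cv_ceiling * min(cu$cv)
    ok <- ok & (cu$cv[match(common, cu$count)] <= thr)
  }
  if (!any(ok)) {
    warning("no contiguous count range satisfies the CV ceiling; falling back to the fixed band")
    return(count_band(fallback[1], fallback[2], "fixed"))
  }
  # longest run of qualifying counts, contiguous in the observed count grid
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  count_band(common[starts[best]], common[ends[best]], "derived_from_cv")
}

count_band <- function(lower, upper, provenance) {
  stopifnot(lower >= 1, lower <= upper)
  structure(list(lower = lower, upper = upper, provenance = provenance),
            class = "count_band")
}

#' @export
print.count_band <- function(x, ...) {
  cat(sprintf("cell-count band: keep %g..%g cells/unit (%s)\n",
              x$lower, x$upper, x$provenance))
  invisible(x)
}

#' Cell-count band filter
#'
#' Retains units whose cell count lies inside the band (inclusive);
#' underpopulated and overpopulated units are removed and carry all their
#' cells into the tier's object count.
#'
#' @param units a [aggregate_units()] data.frame.
#' @param band a `count_band` (from [select_count_band()]) or a length-2
#'   numeric `(lower, upper)`.
#' @return list: `retained`, `removed`, `band`, `tier`.
#' @export
count_band_filter <- function(units, band = c(11, 64)) {
  if (!inherits(band, "count_band")) band <- count_band(band[1], band[2], "fixed")
  keep <- units$cell_count >= band$lower & units$cell_count <= band$upper
  list(retained = units[keep, , drop = FALSE],
       removed = units[!keep, , drop = FALSE],
       band = band,
       tier = ledger_tier(sprintf("count band [%g, %g]", band$lower, band$upper),
                          sum(!keep), sum(units$cell_count[!keep])))
}

#' NtoC percentile filter
#'
#' Computes percentile thresholds of the per-unit mean nucleus-to-cytoplasm
#' ratio (default the 2.5th and 97.5th percentiles) and removes units
#' strictly outside them.  Units whose NtoC is the invalid sentinel (every
#' cell degenerate) are always removed and counted separately.  Pass the
#' `thresholds` of a previous run to re-apply frozen cutoffs: thresholds
#' are computed once on the input distribution, never re-estimated on the
#' filter's own output.
#'
#' @param units a [aggregate_units()] data.frame with `ntoc_mean`.
#' @param p_low,p_high percentiles in `[0, 100]`, `p_low < p_high`.
#' @param thresholds optional frozen numeric `(lower, upper)`.
#' @param type quantile type (default 7).
#' @return list: `retained`, `removed`, `thresholds`, `n_invalid`, `tier`.
#' @export
ntoc_percentile_filter <- function(units, p_low = 2.5, p_high = 97.5,
                                   thresholds = NULL, type = 7) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop("need 0 <= p_low < p_high <= 100", call. = FALSE)
  if (!"ntoc_mean" %in% names(units))
    stop("units lack an ntoc_mean column", call. = FALSE)
  x <- units$ntoc_mean
  if (all(is.na(x))) stop("all unit NtoC values are invalid", call. = FALSE)
  if (is.null(thresholds))
    thresholds <- stats::quantile(x, c(p_low, p_high) / 100, na.rm = TRUE,
                                  type = type, names = FALSE)
  invalid <- is.na(x)
  outside <- !invalid & (x < thresholds[1] | x > thresholds[2])
  keep <- !invalid & !outside
  list(retained = units[keep, , drop = FALSE],
       removed = units[!keep, , drop = FALSE],
       thresholds = thresholds,
       n_invalid = sum(invalid),
       tier = ledger_tier(sprintf("NtoC percentiles [%.4g, %.4g]",
                                  thresholds[1], thresholds[2]),
                          sum(!keep), sum(units$cell_count[!keep])))
}

#' @rdname build_ledger
#' @param name tier label.
#' @param images_removed,objects_removed counts removed at the tier.
#' @export
ledger_tier <- function(name, images_removed, objects_removed) {
  list(name = name, images_removed = as.numeric(images_removed),
       objects_removed = as.numeric(objects_removed))
}

#' QC ledger: tiered accounting of removed images and objects
#'
#' Chains tier removal records into a conservation-checked ledger: at every
#' tier, `in - removed = next tier's in`, independently for images (unit
#' tiles) and objects (cells).  Any tier removing more than remains is
#' rejected, which is what surfaces inconsistent tier inputs.
#'
#' @param tiers list of tier records (each a list with `name`,
#'   `images_removed`, `objects_removed`, as produced by the unit filters).
#' @param images_in,objects_in totals entering the first tier.
#' @return object of class `qc_ledger`: a data.frame with one row per tier
#'   plus in/out columns, and attributes `images_retained`,
#'   `objects_retained`.
#' @examples
#' led <- build_ledger(list(ledger_tier("count band", 5278, 63789),
#'                          ledger_tier("NtoC", 2006, 27804)),
#'                     images_in = 39204, objects_in = 1213838)
#' led
#' @export
build_ledger <- function(tiers, images_in, objects_in) {
  if (images_in < 0 || objects_in < 0) stop("negative input totals", call. = FALSE)
  img <- images_in; obj <- objects_in
  rows <- vector("list", length(tiers))
  for (i in seq_along(tiers)) {
    t <- tiers[[i]]
    if (t$images_removed < 0 || t$objects_removed < 0)
      stop("negative removal counts in tier ", sQuote(t$name), call. = FALSE)
    if (t$images_removed > img || t$objects_removed > obj)
      stop(sprintf(
        "tier %s removes more than remains (images %g > %g or objects %g > %g)",
        sQuote(t$name), t$images_removed, img, t$objects_removed, obj), call. = FALSE)
    rows[[i]] <- data.frame(
      tier = t$name,
      images_in = img, images_removed = t$images_removed,
      images_out = img - t$images_removed,
      objects_in = obj, objects_removed = t$objects_removed,
      objects_out = obj - t$objects_removed,
      stringsAsFactors = FALSE
    )
    img <- img - t$images_removed
    obj <- obj - t$objects_removed
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tier = character(), images_in = numeric(), images_removed = numeric(),
               images_out = numeric(), objects_in = numeric(),
               objects_removed = numeric(), objects_out = numeric())
  attr(out, "images_in") <- images_in
  attr(out, "objects_in") <- objects_in
  attr(out, "images_retained") <- img
  attr(out, "objects_retained") <- obj
  class(out) <- c("qc_ledger", "data.frame")
  out
}

#' @rdname build_ledger
#' @export
ledger_totals <- function(ledger) {
  stopifnot(inherits(ledger, "qc_ledger"))
  list(images_in = attr(ledger, "images_in"),
       objects_in = attr(ledger, "objects_in"),
       images_removed = sum(ledger$images_removed),
       objects_removed = sum(ledger$objects_removed),
       images_retained = attr(ledger, "images_retained"),
       objects_retained = attr(ledger, "objects_retained"))
}

#' @export
print.qc_ledger <- function(x, ...) {
  tot <- ledger_totals(x)
  cat(sprintf("QC ledger: %s images / %s objects in\n",
              format(tot$images_in, big.mark = ","),
              format(tot$objects_in, big.mark = ",")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-38s -%s images, -%s objects -> %s / %s\n", x$tier[i],
                format(x$images_removed[i], big.mark = ","),
                format(x$objects_removed[i], big.mark = ","),
                format(x$images_out[i], big.mark = ","),
                format(x$objects_out[i], big.mark = ",")))
  }
  cat(sprintf("retained: %s images with %s objects (removed %s / %s)\n",
              format(tot$images_retained, big.mark = ","),
              format(tot$objects_retained, big.mark = ","),
              format(tot$images_removed, big.mark = ","),
              format(tot$objects_removed, big.mark = ",")))
  invisible(x)
}

#' @rdname build_ledger
#' @param ledger a `qc_ledger`.
#' @param path CSV output path.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
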