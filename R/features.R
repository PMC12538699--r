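#' Form factor (circularity) of a shape
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a perfect circle, smaller for
#' elongated or irregular outlines (isoperimetric inequality, for exact
#' area and perimeter of a convex analytic shape).  On rasterized masks the
#' digitized perimeter can make the value exceed 1; such values are
#' returned as computed, not clamped (flag them downstream if needed).
#'
#' @param area shape area, px^2 (> 0), vectorized.
#' @param perimeter shape perimeter, px (> 0), vectorized.
#' @return numeric vector of form factors.
#' @examples
#' form_factor(100 * pi, 20 * pi)  # exact circle of radius 10 -> 1
#' form_factor(4, 8)               # unit-ish square -> pi / 4
#' @export
form_factor <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive and finite", call. = FALSE)
  4 * pi * area / perimeter^2
}

#' Nucleus-to-cytoplasm area ratio (NtoC)
#'
#' The nuclear area divided by the area of the surrounding cytoplasm,
#' `A_nuc / (A_cell - A_nuc)`: a value of 1 means nucleus and cytoplasm
#' occupy equal areas, values near 0 mean the cytoplasm dominates.  A cell
#' whose recorded cell area does not exceed its nuclear area is exactly
#' the kind of mis-segmentation this metric exists to catch, so such rows
#' yield `NA` (the invalid sentinel) rather than an error.
#'
#' A config switch is offered for readers of "nucleus-to-cell-body ratio"
#' who prefer the plain `A_nuc / A_cell` quotient: the default
#' `denominator = "cytoplasm"` is what makes "a value of 1 means equal
#' areas" true.
#'
#' @param nuclear_area,cell_area areas in px^2 (> 0), vectorized.
#' @param denominator `"cytoplasm"` (default, `A_cell - A_nuc`) or
#'   `"cell"` (`A_cell`).
#' @return numeric vector; `NA` where the segmentation is degenerate.
#' @examples
#' nto_c(100, 200)  # equal areas -> 1
#' nto_c(50, 550)   # -> 0.1
#' @export
nto_c <- function(nuclear_area, cell_area, denominator = c("cytoplasm", "cell")) {
  denominator <- match.arg(denominator)
  if (any(nuclear_area <= 0, na.rm = TRUE) || any(cell_area <= 0, na.rm = TRUE))
    stop("areas must be positive", call. = FALSE)
  out <- if (denominator == "cytoplasm")
    nuclear_area / (cell_area - nuclear_area)
  else nuclear_area / cell_area
  out[cell_area <= nuclear_area] <- NA_real_
  out
}

#' Fraction of signal in the outermost radial bin
#'
#' Given integrated intensities in 4 equal-width radial shells of the cell
#' (bin 1 innermost, bin 4 the cell periphery), returns the peripheral
#' fraction `bin4 / sum(bins)`.
#'
#' @param bins numeric vector of 4 non-negative totals, or a 4-column
#'   matrix (one row per cell).
#' @return fraction in `[0, 1]`; `NA` where all four bins are zero.
#' @examples
#' radial_fraction(c(3, 2, 1, 4))
#' @export
radial_fraction <- function(bins) {
  if (is.matrix(bins)) {
    if (ncol(bins) != 4) stop("expected 4 radial bins", call. = FALSE)
    if (any(bins < 0)) stop("bin intensities must be non-negative", call. = FALSE)
    tot <- rowSums(bins)
    out <- bins[, 4] / tot
    out[tot == 0] <- NA_real_
    return(out)
  }
  if (length(bins) != 4) stop("expected 4 radial bins", call. = FALSE)
  if (any(bins < 0)) stop("bin intensities must be non-negative", call. = FALSE)
  if (sum(bins) == 0) return(NA_real_)
  bins[4] / sum(bins)
}

# Features aggregated per unit, in the order they appear in unit tables.
UNIT_FEATURES <- c("nuclear_area", "cell_area", "mean_dapi", "mean_phalloidin",
                   "solidity", "peripheral_actin_fraction", "focus_score",
                   "ntoc", "form_factor")

#' Aggregate a cell table into per-TopoUnit summaries
#'
#' Groups cells by `(chip_id, row, col)` and computes, per unit: the cell
#' count, and mean and SD (n-1 denominator) of every available feature,
#' including the derived NtoC and nuclear form factor.  Invalid NtoC
#' sentinels are excluded from the NtoC mean, with the exclusion count
#' recorded per unit (`ntoc_invalid`), so cells are conserved:
#' `sum(cell_count) == nrow(cells)`.
#'
#' @param cells data.frame of cell records (see [generate_screen()] for the
#'   column set; only `chip_id`, `row`, `col` are mandatory).
#' @param features which cell columns to summarize; defaults to the
#'   intersection of the standard feature set with what is present.
#' @return data.frame of class `unit_summary` with one row per unit:
#'   keys, `design_id`, `cell_count`, `<feature>_mean`, `<feature>_sd`
#'   (SD is `NA` for single-cell units) and `ntoc_invalid`.
#' @export
aggregate_units <- function(cells, features = NULL) {
  if (!nrow(cells)) {
    out <- data.frame(chip_id = character(), row = integer(), col = integer(),
                      design_id = character(), cell_count = integer())
    class(out) <- c("unit_summary", "data.frame")
    return(out)
  }
  stopifnot(all(c("chip_id", "row", "col") %in% names(cells)))
  work <- cells
  if (all(c("nuclear_area", "cell_area") %in% names(work)) && is.null(work$ntoc))
    work$ntoc <- nto_c(work$nuclear_area, work$cell_area)
  if (all(c("nuclear_area", "nuclear_perimeter") %in% names(work)) && is.null(work$form_factor))
    work$form_factor <- form_factor(work$nuclear_area, work$nuclear_perimeter)
  if (is.null(features)) features <- intersect(UNIT_FEATURES, names(work))

  key <- interaction(work$chip_id, work$row, work$col, drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  out <- data.frame(
    chip_id = work$chip_id[first], row = work$row[first], col = work$col[first],
    stringsAsFactors = FALSE
  )
  if ("design_id" %in% names(work)) out$design_id <- work$design_id[first]
  out$cell_count <- as.integer(tabulate(key)[as.integer(key)[first]])

  ones <- rep(1, nrow(work))
  ki <- as.integer(key)  # level codes; rowsum output is in level order 1..L
  lev_of_first <- ki[first]
  for (f in features) {
    x <- work[[f]]
    ok <- !is.na(x)
    n <- as.vector(rowsum(ones * ok, ki))
    sx <- as.vector(rowsum(ifelse(ok, x, 0), ki))
    sxx <- as.vector(rowsum(ifelse(ok, x^2, 0), ki))
    n <- n[lev_of_first]; sx <- sx[lev_of_first]; sxx <- sxx[lev_of_first]
    m <- ifelse(n > 0, sx / n, NA_real_)
    v <- ifelse(n > 1, (sxx - n * m^2) / (n - 1), NA_real_)
    out[[paste0(f, "_mean")]] <- m
    out[[paste0(f, "_sd")]] <- sqrt(pmax(v, 0))
    if (f == "ntoc") out$ntoc_invalid <- out$cell_count - as.integer(n)
  }
  rownames(out) <- NULL
  class(out) <- c("unit_summary", "data.frame")
  out
}

#' @export
print.unit_summary <- function(x, ...) {
  cat(sprintf("unit summary: %d units, %d cells; features: %s\n",
              nrow(x), sum(x$cell_count),
              paste(sub("_mean$", "", grep("_mean$", names(x), value = TRUE)),
                    collapse = ", ")))
  NextMethod()
}

#' Coefficient-of-variation curve across cell-count bins
#'
#' For every distinct cell count carried by at least `min_units` units,
#' computes the CV (SD / mean, n-1 SD) of a unit-level feature across the
#' units sharing that count.  This is the curve used to locate the stable
#' cell-count band: sampling noise inflates the CV at low counts and
#' multilayering inflates it at high counts.
#'
#' @param units a [aggregate_units()] result.
#' @param feature unit column to analyze (a `<feature>_mean` column name,
#'   or the bare feature name which is resolved to its unit mean).
#' @param min_units minimum units per count bin (default 20).
#' @return object of class `cv_curve`: data.frame with `count`, `n_units`,
#'   `cv`, plus attribute `feature`.  Bins whose feature mean is 0 are
#'   excluded (CV undefined), with a warning.
#' @export
cv_by_count <- function(units, feature, min_units = 20) {
  col <- if (feature %in% names(units)) feature else paste0(feature, "_mean")
  if (!col %in% names(units))
    stop(sprintf("feature '%s' not found in unit summaries", feature), call. = FALSE)
  x <- units[[col]]
  cnt <- units$cell_count
  keep <- !is.na(x)
  x <- x[keep]; cnt <- cnt[keep]
  tab <- table(cnt)
  counts <- as.integer(names(tab))[tab >= min_units]
  rows <- lapply(counts, function(k) {
    xi <- x[cnt == k]
    m <- mean(xi)
    if (m == 0) return(NULL)
    data.frame(count = k, n_units = length(xi), cv = stats::sd(xi) / abs(m))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped) warning(sprintf("%d count bin(s) dropped: feature mean is 0", dropped))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(count = integer(), n_units = integer(), cv = numeric())
  attr(out, "feature") <- feature
  class(out) <- c("cv_curve", "data.frame")
  out
}

#' @export
plot.cv_curve <- function(x, ...) {
  graphics::plot(x$count, x$cv, type = "b", pch = 16,
                 xlab = "cells per unit", ylab = "coefficient of variation",
                 main = attr(x, "feature"), ...)
  invisible(x)
}
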