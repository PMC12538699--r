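#' k-sample Anderson-Darling test (midrank version for ties)
#'
#' Tests whether k samples are drawn from one common, unspecified
#' continuous distribution.  The statistic is the rank-based k-sample
#' Anderson-Darling statistic in its tie-corrected (midrank) form,
#' standardized by its exact null variance; the p-value comes from the
#' standard interpolation of the statistic's asymptotic critical values in
#' `1/sqrt(k-1)`.  Small p-values indicate the samples follow different
#' distributions, which for replicate TopoUnits of one design flags an
#' irreproducible surface.
#'
#' Being rank-based, the statistic is invariant under any strictly
#' increasing transform of the pooled values and under permutation of the
#' sample order.  A seeded permutation p-value is available as an
#' independent reference via [ad_ksample_perm()].
#'
#' @param samples list of k >= 2 numeric vectors, each with >= 2 values.
#' @return object of class `ad_result`: list with `statistic` (the
#'   tie-corrected A2), `t` (standardized statistic), `sigma` (null SD),
#'   `k`, `total_n`, `p_value`.
#' @examples
#' ad_ksample(list(rnorm(20), rnorm(20)))
#' @export
ad_ksample <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need at least 2 samples", call. = FALSE)
  if (any(vapply(samples, length, integer(1)) < 2))
    stop("each sample needs at least 2 values", call. = FALSE)
  if (any(!is.finite(unlist(samples))))
    stop("samples must be finite", call. = FALSE)
  pooled <- unlist(samples)
  if (length(unique(pooled)) < 2)
    stop("degenerate input: all pooled values are identical, the test is undefined",
         call. = FALSE)
  k <- length(samples)
  n <- vapply(samples, length, integer(1))
  N <- sum(n)

  z <- sort(unique(pooled))          # distinct pooled values
  l <- tabulate(match(pooled, z), nbins = length(z))  # multiplicities
  # B_j: pooled count below z_j plus half the ties at z_j
  B <- cumsum(l) - l / 2
  inner <- numeric(k)
  for (i in seq_len(k)) {
    f <- tabulate(match(samples[[i]], z), nbins = length(z))
    M <- cumsum(f) - f / 2           # sample-i count below z_j plus half ties
    denom <- B * (N - B) - N * l / 4
    term <- (l / N) * (N * M - n[i] * B)^2 / denom
    term[denom <= 0] <- 0            # only the all-tied extremes, measure zero
    inner[i] <- sum(term) / n[i]
  }
  A2 <- (N - 1) / N * sum(inner)

  # exact null variance (midrank version shares the continuous normalization)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  i_seq <- seq_len(N - 2)
  g <- sum(vapply(i_seq, function(i) sum(1 / ((N - i) * seq(i + 1, N - 1))), numeric(1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma2 <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  sigma <- sqrt(max(sigma2, .Machine$double.eps))
  t_obs <- (A2 - (k - 1)) / sigma

  structure(list(statistic = A2, t = t_obs, sigma = sigma, k = k,
                 total_n = N, p_value = ad_pvalue(t_obs, k)),
            class = "ad_result")
}

# asymptotic critical-value coefficients for the standardized statistic,
# at upper tail probabilities 0.25 .. 0.001; tm = b0 + b1/sqrt(m) + b2/m
AD_TAIL_P <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
AD_B0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
AD_B1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
AD_B2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)

ad_pvalue <- function(t_obs, k) {
  m <- k - 1
  tm <- AD_B0 + AD_B1 / sqrt(m) + AD_B2 / m
  co <- stats::lm.fit(cbind(1, tm, tm^2), log(AD_TAIL_P))$coefficients
  # keep the extrapolation monotone: past the parabola vertex the quadratic
  # in log(p) would bend upward, so freeze it there
  t_eval <- if (co[3] > 0) min(t_obs, -co[2] / (2 * co[3])) else t_obs
  p <- exp(co[1] + co[2] * t_eval + co[3] * t_eval^2)
  min(1, max(p, 1e-12))
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("k-sample Anderson-Darling: A2 = %.4g (standardized %.3f), k = %d, N = %d, p = %.4g\n",
              x$statistic, x$t, x$k, x$total_n, x$p_value))
  invisible(x)
}

#' Permutation reference for the k-sample Anderson-Darling test
#'
#' Recomputes the tie-corrected statistic under random (or, for two small
#' samples, all) reassignments of the pooled values to the sample sizes,
#' and returns the permutation p-value `P(A2* >= A2)` with the add-one
#' correction.  This is the reference against which the analytic p-value
#' approximation is validated.
#'
#' @param samples as in [ad_ksample()].
#' @param n_perm number of random permutations (ignored when `exhaustive`).
#' @param exhaustive if `TRUE` (only for k = 2) enumerate all
#'   `choose(N, n1)` assignments exactly.
#' @param seed integer seed for random permutations.
#' @return list with `statistic`, `p_value`, `n_perm`, `exhaustive`.
#' @export
ad_ksample_perm <- function(samples, n_perm = 2000, exhaustive = FALSE, seed = 1L) {
  obs <- ad_ksample(samples)$statistic
  n <- vapply(samples, length, integer(1))
  pooled <- unlist(samples)
  N <- sum(n)
  stat_for <- function(perm) {
    ad_ksample(split(pooled[perm], rep(seq_along(n), n)))$statistic
  }
  if (exhaustive) {
    if (length(samples) != 2) stop("exhaustive enumeration implemented for k = 2", call. = FALSE)
    sets <- utils::combn(N, n[1])
    stats <- apply(sets, 2, function(s) stat_for(c(s, setdiff(seq_len(N), s))))
    p <- mean(stats >= obs - 1e-12)
    return(list(statistic = obs, p_value = p, n_perm = ncol(sets), exhaustive = TRUE))
  }
  rng <- local_rng(seed)
  stats <- vapply(seq_len(n_perm), function(i) stat_for(rng$sample(N)), numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1),
       n_perm = n_perm, exhaustive = FALSE)
}

#' Signal-to-noise ratio of replicate measurements
#'
#' `|mean| / sd` with the n-1 SD: the magnitude of the replicate signal
#' relative to its variability.  A constant sample has no noise, giving
#' the `+Inf` sentinel (which the acceptance band `(2, 20)` rejects).
#'
#' @param values numeric sample of at least 2 values.
#' @return object of class `snr_result`: list with `mean`, `sd`, `snr`.
#' @examples
#' snr(c(5, 10, 15))
#' @export
snr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for SNR", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  structure(list(mean = m, sd = s,
                 snr = if (s == 0) Inf else abs(m) / s),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR: mean %.4g, sd %.4g -> %.4g\n", x$mean, x$sd, x$snr))
  invisible(x)
}

#' Dual Anderson-Darling + SNR replicate-consistency filter
#'
#' A surface design is retained only if (i) the Anderson-Darling test on
#' its replicate groups does not reject a common distribution (p-value
#' inside the acceptance band, default `(0.05, 1]`: retain iff p > 0.05)
#' and (ii) the SNR of its pooled replicate values lies strictly inside
#' the SNR band (default `(2, 20)`; the upper bound rejects suspiciously
#' noise-free surfaces, a convention carried in the report).  The two
#' criteria are applied in parallel on the full design set and removal is
#' their union; designs with a single replicate group are flagged
#' untestable rather than silently classified.  A design whose pooled
#' values are all identical cannot be AD-tested; it is handled by the SNR
#' arm (infinite SNR, removed).
#'
#' @param designs named list: one element per design, each a list of
#'   replicate groups (numeric vectors).  Cell-level mode passes the
#'   per-replicate-position cell value distributions (k = 2 groups pooled
#'   across chips); unit-level mode passes chip-wise unit summary values.
#' @param feature label for the report.
#' @param ad_band length-2: AD p-value acceptance interval `(lo, hi]`.
#' @param snr_band length-2: SNR acceptance interval, open.
#' @return list: `retained`, `removed`, `untestable` (character vectors of
#'   design ids) and `report` (a `filter_report`).
#' @export
dual_filter <- function(designs, feature = "feature",
                        ad_band = c(0.05, 1), snr_band = c(2, 20)) {
  stopifnot(is.list(designs), length(designs) >= 1, !is.null(names(designs)))
  ids <- names(designs)
  res <- data.frame(design_id = ids, ad_p = NA_real_, snr = NA_real_,
                    fail_ad = FALSE, fail_snr = FALSE,
                    status = "retained", stringsAsFactors = FALSE)
  for (i in seq_along(designs)) {
    groups <- designs[[i]]
    if (!is.list(groups)) groups <- list(groups)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    pooled <- unlist(groups)
    if (length(groups) < 2) {
      res$status[i] <- "untestable"
      next
    }
    sv <- snr(pooled)$snr
    res$snr[i] <- sv
    res$fail_snr[i] <- !(sv > snr_band[1] && sv < snr_band[2])
    p <- tryCatch(ad_ksample(groups)$p_value, error = function(e) NA_real_)
    res$ad_p[i] <- p
    res$fail_ad[i] <- !is.na(p) && !(p > ad_band[1] && p <= ad_band[2])
    if (res$fail_ad[i] || res$fail_snr[i]) res$status[i] <- "removed"
  }
  report <- structure(
    list(feature = feature, n_designs = length(ids),
         removed_by_ad = sum(res$fail_ad),
         removed_by_snr = sum(res$fail_snr),
         removed_union = sum(res$status == "removed"),
         untestable = sum(res$status == "untestable"),
         ad_band = ad_band, snr_band = snr_band,
         per_design = res),
    class = "filter_report")
  list(retained = ids[res$status == "retained"],
       removed = ids[res$status == "removed"],
       untestable = ids[res$status == "untestable"],
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("replicate-consistency filter on %s: %d designs\n", x$feature, x$n_designs))
  cat(sprintf("  removed by AD p-value (%g; %g): %d\n", x$ad_band[1], x$ad_band[2], x$removed_by_ad))
  cat(sprintf("  removed by SNR (%g; %g): %d  (upper bound is a screening convention)\n",
              x$snr_band[1], x$snr_band[2], x$removed_by_snr))
  cat(sprintf("  removed (union): %d; untestable: %d\n", x$removed_union, x$untestable))
  invisible(x)
}

#' Tabulate per-feature removal counts
#'
#' Collates one or more `filter_report`s into the screening summary table:
#' one row per feature, removal counts by the AD band and by the SNR band,
#' plus their union.
#'
#' @param reports a `filter_report` or list of them.
#' @return data.frame with columns `feature`, `removed_by_ad`,
#'   `removed_by_snr`, `removed_total`.
#' @export
removal_report <- function(reports) {
  if (inherits(reports, "filter_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one filter report", call. = FALSE)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(feature = r$feature,
               removed_by_ad = r$removed_by_ad,
               removed_by_snr = r$removed_by_snr,
               removed_total = r$removed_union,
               stringsAsFactors = FALSE)
  }))
}

#' Assemble replicate groups from a screen's cell table
#'
#' For every non-flat design, collects the cell-level values of one feature
#' at each of the design's replicate grid positions, pooled across chips
#' (k = 2 groups, the default grouping mode), or chip-wise unit-level
#' summary values (`mode = "unit"`).
#'
#' @param cells cell table (with `row`, `col`, `design_id`).
#' @param layout the [chip_layout()] giving each design's positions.
#' @param feature cell column (`mode = "cell"`) or unit column root
#'   (`mode = "unit"`).
#' @param mode `"cell"` or `"unit"`.
#' @return named list suitable for [dual_filter()].
#' @export
replicate_groups <- function(cells, layout, feature = "nuclear_area",
                             mode = c("cell", "unit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "chip_layout"))
  designs <- setdiff(sort(unique(as.vector(layout$design_at))), "FLAT")
  if (mode == "unit") {
    units <- aggregate_units(cells)
    col <- if (feature %in% names(units)) feature else paste0(feature, "_mean")
    vals <- units[[col]]
    pos_key <- paste(units$row, units$col)
  } else {
    vals <- cells[[feature]]
    pos_key <- paste(cells$row, cells$col)
  }
  by_pos <- split(vals, pos_key)
  out <- lapply(designs, function(d) {
    pos <- which(layout$design_at == d, arr.ind = TRUE)
    lapply(seq_len(nrow(pos)), function(i) {
      v <- by_pos[[paste(pos[i, "row"], pos[i, "col"])]]
      if (is.null(v)) numeric() else v
    })
  })
  names(out) <- designs
  out
}
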