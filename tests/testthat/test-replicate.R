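test_that("identical samples cannot look inconsistent", {
  r <- ad_ksample(list(1:20, 1:20))
  expect_gt(r$p_value, 0.25)
  expect_equal(r$total_n, 40)
  expect_equal(r$k, 2)
})

test_that("well-separated samples are detected, in agreement with permutation", {
  set.seed(10)
  x <- rnorm(50); y <- rnorm(50, 5)
  r <- ad_ksample(list(x, y))
  expect_lt(r$p_value, 0.001)
  perm <- ad_ksample_perm(list(x, y), n_perm = 10000, seed = 1)
  expect_lt(perm$p_value, 0.001)
})

test_that("analytic p tracks the exhaustive permutation distribution on small samples", {
  # the tabulated critical values cover the decision tail (p <= 0.25), so
  # agreement is asserted on cases whose exhaustive p lies there
  cases <- list(
    list(c(0.2, 0.5, 0.9, 1.4), c(5.1, 5.6, 6.2, 7.0)),  # fully separated
    list(c(0.5, 1.0, 1.5, 2.0), c(1.8, 2.6, 3.1, 3.9)),
    list(c(0.5, 1.2, 2.0, 2.8), c(2.2, 3.0, 3.8, 4.6))
  )
  for (samples in cases) {
    exact <- ad_ksample_perm(samples, exhaustive = TRUE)
    expect_equal(exact$n_perm, choose(8, 4))  # all 70 assignments
    expect_lte(exact$p_value, 0.25)
    approx <- ad_ksample(samples)$p_value
    # the permutation p is granular (1/70); exhaustively separated samples
    # bottom out at 2/70 while the analytic tail keeps going
    expect_lt(abs(approx - exact$p_value), 0.05 + 1 / 70)
  }
  # far outside the tail both routes agree the samples are exchangeable
  inter <- list(c(3, 1, 4, 2), c(2.5, 1.5, 3.5, 4.5))
  expect_gt(ad_ksample(inter)$p_value, 0.25)
  expect_gt(ad_ksample_perm(inter, exhaustive = TRUE)$p_value, 0.25)
})

test_that("the statistic is rank-based: monotone transforms and sample order", {
  set.seed(5)
  samples <- list(rnorm(15), rnorm(12, 0.5), rnorm(18, -0.3))
  a <- ad_ksample(samples)$statistic
  for (f in list(function(x) exp(x), function(x) x^3, function(x) atan(x))) {
    expect_equal(ad_ksample(lapply(samples, f))$statistic, a, tolerance = 1e-12)
  }
  expect_equal(ad_ksample(samples[c(3, 1, 2)])$statistic, a, tolerance = 1e-12)
})

test_that("degenerate and undersized inputs are rejected with clear messages", {
  expect_error(ad_ksample(list(c(2, 2, 2), c(2, 2, 2))), "identical")
  expect_error(ad_ksample(list(1:5)), "at least 2 samples")
  expect_error(ad_ksample(list(1:5, 3)), "at least 2 values")
})

test_that("SNR is |mean|/sd with the infinite sentinel for constants", {
  r <- snr(c(5, 10, 15))
  expect_equal(r$snr, 10 / 5)
  expect_equal(snr(rep(3, 5))$snr, Inf)
  expect_error(snr(7), "at least 2")
  # counts like 39 +/- 13 give SNR near 3
  set.seed(6)
  vals <- rnorm(5000, 39, 13)
  expect_equal(snr(vals)$snr, 3, tolerance = 0.1)
})

test_that("dual filter type-I error matches the nominal AD level under the null", {
  set.seed(12)
  designs <- lapply(1:600, function(i) list(rnorm(30), rnorm(30)))
  names(designs) <- sprintf("D%03d", 1:600)
  res <- dual_filter(designs, ad_band = c(0.05, 1), snr_band = c(-Inf, Inf))
  rate <- res$report$removed_by_ad / 600
  # 3 binomial SDs around alpha = 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
  expect_equal(res$report$removed_by_snr, 0)
})

test_that("constant replicates are removed through the SNR arm", {
  designs <- list(good = list(rnorm(20, 10), rnorm(20, 10)),
                  flatline = list(rep(4, 5), rep(4, 5)),
                  lonely = list(rnorm(10)))
  set.seed(3)
  res <- dual_filter(designs)
  expect_true("flatline" %in% res$removed)
  rep_row <- res$report$per_design[res$report$per_design$design_id == "flatline", ]
  expect_true(rep_row$fail_snr)
  expect_equal(res$untestable, "lonely")
})

test_that("planted inconsistent replicates are all removed at a 3-SD shift", {
  scr <- small_screen()
  planted <- plant_artifacts(scr, c(replicate_inconsistent = 0.05), seed = 7, shift_sd = 3)
  bad <- unique(planted$truth$design_id)
  groups <- replicate_groups(planted$cells, planted$layout, "nuclear_area")
  res <- dual_filter(groups, feature = "nuclear_area", snr_band = c(-Inf, Inf))
  expect_true(all(bad %in% res$removed))  # recall 1.0 on the planted set
})

test_that("the removal report collates per-feature counts consistently", {
  set.seed(4)
  null_designs <- lapply(1:50, function(i) list(rnorm(20), rnorm(20)))
  names(null_designs) <- sprintf("D%02d", 1:50)
  shifted <- null_designs
  for (i in 1:10) shifted[[i]][[2]] <- shifted[[i]][[2]] + 10

  f1 <- dual_filter(null_designs, feature = "cell_count", snr_band = c(-Inf, Inf))
  f2 <- dual_filter(shifted, feature = "nuclear_area", snr_band = c(-Inf, Inf))
  tab <- removal_report(list(f1$report, f2$report))
  expect_equal(tab$feature, c("cell_count", "nuclear_area"))
  expect_gte(tab$removed_total[2], 10)
  # union never exceeds the per-criterion sum, never undercuts either arm
  expect_true(all(tab$removed_total <= tab$removed_by_ad + tab$removed_by_snr))
  expect_true(all(tab$removed_total >= pmax(tab$removed_by_ad, tab$removed_by_snr)))
  expect_equal(tab$removed_total[1], length(f1$removed))
})
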