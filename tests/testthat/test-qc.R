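make_cells <- function(diams, border = FALSE, wall = FALSE) {
  n <- length(diams)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)), nucleus_diameter = diams,
             touches_border = rep_len(border, n), touches_wall = rep_len(wall, n),
             stringsAsFactors = FALSE)
}

test_that("object filter applies the inclusive diameter band and contact rules", {
  r <- filter_objects(make_cells(c(10, 15, 40, 65, 70)))
  expect_equal(r$retained$nucleus_diameter, c(15, 40, 65))
  expect_equal(r$log$rule, c("diameter", "diameter"))

  ok <- make_cells(c(20, 30, 40))
  expect_identical(filter_objects(ok)$retained, ok)

  set.seed(2)
  cells <- make_cells(runif(100, 20, 60))
  cells$touches_wall[sample(100, 17)] <- TRUE
  r2 <- filter_objects(cells)
  expect_equal(nrow(r2$removed), 17)
  expect_true(all(r2$log$rule == "wall-contact"))
  expect_equal(r2$tier$objects_removed, 17)
  # first-failing-rule precedence: diameter before contact
  both <- make_cells(5, border = TRUE)
  expect_equal(filter_objects(both)$log$rule, "diameter")
  expect_error(filter_objects(ok, 65, 15), "below")
})

test_that("IQR bounds follow the interpolated-quartile arithmetic", {
  b <- iqr_bounds(c(1:10, 100), k = 1.5)
  expect_equal(b$q1, 3.5)  # type-7 position 3.5 in the sorted sample
  expect_equal(b$q3, 8.5)
  expect_equal(b$lower, 3.5 - 1.5 * 5)
  expect_equal(b$upper, 8.5 + 1.5 * 5)
  outside <- c(1:10, 100)[c(1:10, 100) < b$lower | c(1:10, 100) > b$upper]
  expect_equal(outside, 100)

  same <- iqr_bounds(rep(7, 10))
  expect_equal(c(same$lower, same$upper), c(7, 7))

  sym <- iqr_bounds(c(-4, -2, -1, 0, 1, 2, 4))
  expect_equal(sym$lower, -sym$upper)  # symmetric sample, median 0
  expect_error(iqr_bounds(1:3), "at least 4")
})

test_that("count band derives from CV curves, checked by exhaustive range scan", {
  mk_curve <- function(penalty_lo, penalty_hi) {
    counts <- 1:80
    cv <- 0.1 + 0.5 * (counts < penalty_lo | counts > penalty_hi)
    structure(data.frame(count = counts, n_units = 50, cv = cv),
              class = c("cv_curve", "data.frame"))
  }
  curves <- list(mk_curve(12, 60), mk_curve(10, 58))
  band <- select_count_band(curves, cv_ceiling = 1.5)
  expect_equal(band$provenance, "derived_from_cv")

  # independent oracle: brute-force scan of all contiguous count ranges
  ok_count <- function(k) all(vapply(curves, function(cu)
    cu$cv[cu$count == k] <= 1.5 * min(cu$cv), logical(1)))
  qualifying <- Filter(ok_count, 1:80)
  runs <- split(qualifying, cumsum(c(1, diff(qualifying) != 1)))
  best <- runs[[which.max(lengths(runs))]]
  expect_equal(c(band$lower, band$upper), range(best))
  expect_equal(c(band$lower, band$upper), c(12, 58))

  # flat curves: the whole observed range qualifies
  flat <- mk_curve(0, 100)
  full <- select_count_band(list(flat), 1.5)
  expect_equal(c(full$lower, full$upper), c(1, 80))

  # nothing qualifies: fixed fallback band
  hostile <- structure(data.frame(count = 1:5, n_units = 50,
                                  cv = c(0.1, 1, 1, 1, 1)),
                       class = c("cv_curve", "data.frame"))
  hostile$cv[1] <- 1e-9  # every other bin is far above 1.5x the minimum
  hostile2 <- hostile; hostile2$cv <- rev(hostile$cv)
  expect_warning(fb <- select_count_band(list(hostile, hostile2), 1.001), "falling back")
  expect_equal(c(fb$lower, fb$upper), c(11, 64))
  expect_equal(fb$provenance, "fixed")
})

test_that("count-band filter keeps the inclusive 11..64 range", {
  u <- data.frame(chip_id = "c", row = 1:4, col = 1,
                  cell_count = c(10L, 11L, 64L, 65L))
  r <- count_band_filter(u, c(11, 64))
  expect_equal(r$retained$cell_count, c(11L, 64L))
  expect_equal(r$tier$images_removed, 2)
  expect_equal(r$tier$objects_removed, 10 + 65)
  wide <- count_band_filter(u, c(1, .Machine$integer.max))
  expect_identical(wide$retained, u)
})

test_that("NtoC percentile filter freezes thresholds and honors sentinels", {
  u <- data.frame(chip_id = "c", row = 1:6, col = 1, cell_count = 10L,
                  ntoc_mean = rep(0.2, 6))
  none <- ntoc_percentile_filter(u)
  expect_equal(nrow(none$removed), 0)  # degenerate distribution, strict bounds

  set.seed(3)
  u2 <- data.frame(chip_id = "c", row = 1:1000, col = 1, cell_count = 10L,
                   ntoc_mean = runif(1000))
  r <- ntoc_percentile_filter(u2, 2.5, 97.5)
  expect_equal(nrow(r$removed), 50, tolerance = 0.45)  # about 5 %, binomial spread

  # frozen thresholds: re-application to the filter's own output removes nothing
  again <- ntoc_percentile_filter(r$retained, thresholds = r$thresholds)
  expect_equal(nrow(again$removed), 0)
  expect_identical(again$retained, r$retained)

  u3 <- u2; u3$ntoc_mean[7] <- NA  # all-invalid unit: always removed
  r3 <- ntoc_percentile_filter(u3)
  expect_equal(r3$n_invalid, 1)
  expect_true(7 %in% r3$removed$row)
  expect_error(ntoc_percentile_filter(u3, 97.5, 2.5), "p_low")
})

test_that("the ledger chains tier removals with exact conservation", {
  led <- build_ledger(list(ledger_tier("count band", 5278, 63789),
                           ledger_tier("NtoC percentile", 2006, 27804)),
                      images_in = 39204, objects_in = 1213838)
  tot <- ledger_totals(led)
  expect_equal(tot$images_retained, 31920)
  expect_equal(tot$objects_retained, 1122245)
  expect_equal(tot$images_removed, 7284)
  expect_equal(tot$objects_removed, 91593)
  # per-tier conservation, images and objects independently
  expect_equal(led$images_in - led$images_removed, led$images_out)
  expect_equal(led$objects_in - led$objects_removed, led$objects_out)
  expect_equal(led$images_in[2], led$images_out[1])
  expect_equal(led$objects_in[2], led$objects_out[1])

  none <- build_ledger(list(ledger_tier("noop", 0, 0)), 100, 1000)
  expect_equal(ledger_totals(none)$images_retained, 100)
  expect_error(build_ledger(list(ledger_tier("greedy", 200, 0)), 100, 1000),
               "more than remains")
})

test_that("unit filters are idempotent under frozen thresholds", {
  scr <- small_screen()
  r1 <- iqr_unit_filter(scr$units, "focus_score")
  r2 <- iqr_unit_filter(r1$retained, "focus_score", bounds = r1$bounds)
  expect_identical(r2$retained, r1$retained)
  b1 <- count_band_filter(scr$units, c(11, 64))
  b2 <- count_band_filter(b1$retained, c(11, 64))
  expect_identical(b2$retained, b1$retained)
})
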