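test_that("form factor matches closed forms and the quadrature oracle", {
  expect_equal(form_factor(100 * pi, 20 * pi), 1)          # exact circle r = 10
  expect_equal(form_factor(4, 8), pi / 4)                  # square of side 2
  # 2:1 ellipse: perimeter from the arc-length integral (independent oracle)
  a <- 2; b <- 1
  P <- integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                 0, 2 * pi, rel.tol = 1e-12)$value
  expect_equal(form_factor(pi * a * b, P), 0.8412, tolerance = 1e-3)
  expect_error(form_factor(0, 10), "positive")
  expect_error(form_factor(10, -1), "positive")
})

test_that("form factor of convex shapes never exceeds the circle's", {
  # regular n-gons: A = n r^2 sin(2 pi / n) / 2, P = 2 n r sin(pi / n)
  for (n in c(3, 4, 5, 8, 16, 64)) {
    A <- n * sin(2 * pi / n) / 2
    P <- 2 * n * sin(pi / n)
    ff <- form_factor(A, P)
    expect_lt(ff, 1)
    if (n == 64) expect_gt(ff, 0.999)  # approaches the circle from below
  }
})

test_that("NtoC follows the cytoplasm-denominator definition", {
  expect_equal(nto_c(100, 200), 1)      # equal areas
  expect_equal(nto_c(50, 550), 0.1)
  expect_true(is.na(nto_c(300, 200)))   # degenerate segmentation: sentinel
  expect_equal(nto_c(100, 200, denominator = "cell"), 0.5)
  # scale invariance
  for (k in c(0.5, 2, 17)) {
    expect_equal(nto_c(k * 120, k * 700), nto_c(120, 700))
  }
  expect_error(nto_c(-5, 10), "positive")
})

test_that("radial fraction is the outermost bin's share", {
  expect_equal(radial_fraction(c(1, 1, 1, 1)), 0.25)
  expect_equal(radial_fraction(c(0, 0, 0, 5)), 1)
  bins <- c(3, 2, 1, 4)
  expect_equal(radial_fraction(bins), bins[4] / sum(bins))  # 0.4 by the sum oracle
  expect_true(is.na(radial_fraction(c(0, 0, 0, 0))))
  expect_error(radial_fraction(c(1, 2, 3)), "4 radial bins")
  m <- rbind(c(1, 1, 1, 1), c(0, 0, 0, 5))
  expect_equal(radial_fraction(m), c(0.25, 1))
})

test_that("unit aggregation matches hand arithmetic and conserves cells", {
  cells <- data.frame(
    chip_id = "chip1", row = c(1, 1, 1, 2), col = c(1, 1, 1, 1),
    design_id = c("D1", "D1", "D1", "D2"),
    nuclear_area = c(700, 737, 774, 500),
    cell_area = c(4200, 4422, 4644, 400),  # last cell: degenerate NtoC
    stringsAsFactors = FALSE
  )
  u <- aggregate_units(cells)
  expect_equal(nrow(u), 2)
  one <- u[u$row == 1, ]
  expect_equal(one$cell_count, 3L)
  expect_equal(one$nuclear_area_mean, 737)
  expect_equal(one$nuclear_area_sd, 37)
  # single-cell unit: SD undefined
  two <- u[u$row == 2, ]
  expect_true(is.na(two$nuclear_area_sd))
  # invalid NtoC excluded from the mean but counted
  expect_equal(two$ntoc_invalid, 1L)
  expect_true(is.na(two$ntoc_mean))
  # conservation: unit counts plus nothing lost
  expect_equal(sum(u$cell_count), nrow(cells))
  expect_equal(nrow(aggregate_units(cells[0, ])), 0)
})

test_that("aggregation conserves cells on a generated screen", {
  scr <- small_screen()
  expect_equal(sum(scr$units$cell_count), nrow(scr$cells))
  expect_equal(sum(scr$units$ntoc_invalid), sum(is.na(nto_c(scr$cells$nuclear_area,
                                                            scr$cells$cell_area))))
})

test_that("CV curves recover known coefficients of variation", {
  # identical unit values: cv 0 everywhere
  u <- data.frame(chip_id = "c", row = rep(1:50, 2), col = rep(1:2, each = 50),
                  cell_count = rep(c(10L, 20L), 50), feat_mean = 5)
  cv0 <- cv_by_count(u, "feat", min_units = 10)
  expect_true(all(cv0$cv == 0))
  expect_setequal(cv0$count, c(10, 20))
  # N(100, 10^2) unit values at one count: cv about 0.1
  set.seed(8)
  u2 <- data.frame(chip_id = "c", row = 1:2000, col = 1,
                   cell_count = 30L, feat_mean = rnorm(2000, 100, 10))
  cv2 <- cv_by_count(u2, "feat", min_units = 100)
  expect_equal(cv2$cv, 0.1, tolerance = 0.05)
  expect_error(cv_by_count(u2, "nope"), "not found")
})

test_that("low-count units have inflated CV, as the variance model implies", {
  scr <- small_screen()
  curve <- cv_by_count(scr$units, "nuclear_area", min_units = 5)
  low <- curve$cv[curve$count < 11]
  mid <- curve$cv[curve$count >= 20 & curve$count <= 50]
  expect_gt(length(low), 0)
  expect_gt(length(mid), 0)
  expect_gt(mean(low), mean(mid))
})
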