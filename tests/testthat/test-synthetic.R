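test_that("identical config and seed reproduce the screen exactly", {
  cfg <- screen_config(n_chips = 2, high_density_chips = 1, n_designs = 30,
                       n_rows = 8, n_cols = 8, seed = 21)
  a <- generate_screen(cfg)
  b <- generate_screen(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$layout$design_at, b$layout$design_at)
  c <- generate_screen(screen_config(n_chips = 2, high_density_chips = 1,
                                     n_designs = 30, n_rows = 8, n_cols = 8, seed = 22))
  expect_false(identical(a$cells$nuclear_area, c$cells$nuclear_area))
})

test_that("variance decomposition is solved and guarded at build time", {
  cfg <- screen_config()
  expect_equal(cfg$sigma_w^2 + cfg$sigma_b^2, 161^2, tolerance = 1e-9)
  # unit_mean_sd too small for the count structure: sigma_b^2 would be negative
  expect_error(screen_config(unit_mean_sd = 20), "sigma_b")
  expect_error(screen_config(unit_mean_sd = 200), "smaller than the single-cell SD")
})

test_that("with no between-unit component, unit means spread as sd/sqrt(n)", {
  # near-constant counts at n = 25 make E[1/n] = 1/25; setting the unit-mean
  # SD to sigma/sqrt(25) forces sigma_b to 0
  cfg <- screen_config(n_chips = 2, high_density_chips = 2,
                       count_mean_high = 25, count_sd_high = 1e-6,
                       nuc_area_sd_total = 150, unit_mean_sd = 150 / 5,
                       design_sd_frac = 0,
                       n_designs = 126, n_rows = 16, n_cols = 16, seed = 9)
  expect_lt(cfg$sigma_b, 1e-3)
  scr <- generate_screen(cfg)
  expect_true(all(scr$units$cell_count == 25))
  expect_equal(sd(scr$units$nuclear_area_mean), 150 / 5, tolerance = 0.1)
})

test_that("cell records map to layout positions and chips", {
  scr <- small_screen()
  lay <- scr$layout
  expect_true(all(scr$cells$row >= 1 & scr$cells$row <= lay$n_rows))
  expect_true(all(scr$cells$col >= 1 & scr$cells$col <= lay$n_cols))
  expect_identical(scr$cells$design_id,
                   design_at(lay, scr$cells$row, scr$cells$col))
})

test_that("planting no artifacts is the identity", {
  scr <- small_screen()
  out <- plant_artifacts(scr, c(underpopulated = 0), seed = 1)
  expect_identical(out$cells, scr$cells)
  expect_equal(nrow(out$truth), 0)
  expect_error(plant_artifacts(scr, c(underpopulated = 0.6)), "0.5")
  expect_error(plant_artifacts(scr, c(bogus = 0.1)), "unknown artifact kind")
})

test_that("underpopulation planting hits exactly the floored unit count", {
  scr <- generate_screen(screen_config(
    n_chips = 1, high_density_chips = 1, n_designs = 2176, seed = 31))
  out <- plant_artifacts(scr, c(underpopulated = 0.02), seed = 5)
  expect_equal(nrow(out$truth), floor(0.02 * 4356))  # 87 units on one chip
  tu <- truth_units(out, "underpopulated")
  counts <- out$units$cell_count[unit_keys(out$units) %in% tu]
  expect_length(counts, 87)
  expect_true(all(counts < 11))
})

test_that("inconsistent replicates differ in mean by about the configured shift", {
  scr <- small_screen()
  out <- plant_artifacts(scr, c(replicate_inconsistent = 0.1), seed = 3, shift_sd = 3)
  planted <- unique(out$truth$design_id[out$truth$kind == "replicate_inconsistent"])
  expect_equal(length(planted), floor(0.1 * 126))
  shift <- 3 * scr$config$nuc_area_sd_total
  for (d in planted) {
    groups <- replicate_groups(out$cells, out$layout, "nuclear_area")[[d]]
    gap <- abs(mean(groups[[1]]) - mean(groups[[2]]))
    # the planted shift dominates the natural between-unit difference
    expect_gt(gap, shift - 4 * scr$config$sigma_b)
  }
})

test_that("re-planting cannot corrupt a unit twice", {
  scr <- small_screen()
  once <- plant_artifacts(scr, c(out_of_focus = 0.05), seed = 3)
  twice <- plant_artifacts(once, c(ntoc_extreme = 0.05), seed = 4)
  expect_equal(anyDuplicated(paste(twice$truth$chip_id, twice$truth$row, twice$truth$col)), 0)
})
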