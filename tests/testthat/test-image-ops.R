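test_that("z-projection follows its pixelwise definitions", {
  a <- matrix(c(0, 2, 1, 0), 2, byrow = TRUE)
  b <- matrix(c(1, 1, 0, 3), 2, byrow = TRUE)
  expect_equal(project_zstack(list(a, b), "max"),
               matrix(c(1, 2, 1, 3), 2, byrow = TRUE))
  # single-plane projection is the identity for both methods
  expect_identical(project_zstack(list(a), "max"), a)
  expect_identical(project_zstack(list(a), "average"), a)
  # integer planes: average rounds half-up at the same bit depth
  ia <- matrix(1L, 2, 2); ib <- matrix(2L, 2, 2)
  avg <- project_zstack(list(ia, ib), "average")
  expect_true(is.integer(avg))
  expect_true(all(avg == 2L))
  expect_error(project_zstack(list(a, matrix(0, 3, 2))), "same shape")
})

test_that("max projection dominates average projection on fuzzed stacks", {
  set.seed(4)
  for (i in 1:20) {
    stack <- lapply(1:sample(2:5, 1), function(j) matrix(runif(48), 6, 8))
    expect_true(all(project_zstack(stack, "max") >=
                      project_zstack(stack, "average") - 1e-12))
  }
})

test_that("synthetic z-stacks follow the blur profile", {
  lay <- chip_layout(n_designs = 6, n_rows = 4, n_cols = 4, flat_count = 4, seed = 2)
  base <- generate_stitched_image(lay, px_per_unit = 16, seed = 1)$image
  # the 16 um range / 4 um step protocol gives 16/4 + 1 = 5 planes
  stack <- generate_zstack(base, blur_profile = c(2, 1, 0, 1, 2), noise_sd = 0)
  expect_length(stack, 5)
  expect_identical(stack[[3]], base)  # zero-blur plane is the in-focus image
  expect_identical(generate_zstack(base, 0, noise_sd = 0)[[1]], base)
  expect_error(generate_zstack(base, c(0, -1)), "non-negative")
  # blur redistributes but never exceeds the base maximum
  expect_lte(max(stack[[1]]), max(base) + 1e-12)
})

test_that("tilt map is exact bilinear interpolation over unit centers", {
  flat <- tilt_map(c(5, 5, 5, 5), 4, 6)
  expect_true(all(abs(flat$values - 5) < 1e-12))
  tm <- tilt_map(c(0, 1, 0, 1), 3, 3)
  expect_equal(tm$values[, 2], rep(0.5, 3))
  expect_equal(tm$values[1, 1], 0)  # corners reproduced exactly
  expect_equal(tm$values[3, 3], 1)
  down <- tilt_map(c(0, 0, 2, 2), 5, 4)
  expect_true(all(diff(down$values[, 1]) > 0))  # monotone down the rows
  expect_true(all(down$values >= 0 & down$values <= 2))
  expect_error(tilt_map(c(0, 1, NA, 2), 3, 3), "finite")
})

test_that("orientation is recovered from the flat landmark for every rotation", {
  lay <- chip_layout(n_designs = 30, n_rows = 8, n_cols = 8, flat_count = 4, seed = 2)
  img <- generate_stitched_image(lay, px_per_unit = 16, seed = 1)$image
  expect_equal(orient_chip(img, lay)$rotation, 0L)
  for (k in c(90L, 180L, 270L)) {
    res <- orient_chip(rotate_image(img, k), lay)
    expect_equal(res$rotation, (360L - k) %% 360L)
    expect_identical(res$image, img)
    # reported rotation applied to the input reproduces the output
    expect_identical(rotate_image(rotate_image(img, k), res$rotation), res$image)
  }
})

test_that("an erased landmark yields an ambiguity report, not a rotation", {
  lay <- chip_layout(n_designs = 30, n_rows = 8, n_cols = 8, flat_count = 4, seed = 2)
  img <- generate_stitched_image(lay, px_per_unit = 16, seed = 1)$image
  # paint pillar texture into the flat block: no unit is flat any more
  for (i in seq_len(nrow(lay$flat_positions))) {
    r0 <- (lay$flat_positions$row[i] - 1) * 16
    c0 <- (lay$flat_positions$col[i] - 1) * 16
    img[r0 + seq(3, 14, 4), c0 + seq(3, 14, 4)] <- 0.35
  }
  res <- orient_chip(img, lay)
  expect_true(is.na(res$rotation))
  expect_match(res$error, "landmark")
  expect_identical(res$image, img)
})

test_that("grid cropping is lossless and strict about divisibility", {
  lay <- chip_layout(n_designs = 0, n_rows = 2, n_cols = 2, flat_count = 4, seed = 1)
  img <- matrix(runif(64 * 64), 64, 64)
  ts <- crop_units(img, lay, "chip1", "DAPI", "DNA")
  expect_length(ts$tiles, 4)
  expect_equal(dim(ts$tiles[[1]]), c(32, 32))
  expect_identical(reassemble_tiles(ts, lay), img)
  expect_error(crop_units(img[1:63, ], lay, "c", "X", "S"), "pad")
})

test_that("a full synthetic chip crops into 4356 named tiles", {
  lay <- chip_layout(seed = 1)
  img <- generate_stitched_image(lay, px_per_unit = 16, seed = 1)$image
  ts <- crop_units(img, lay, "chip1", "DAPI", "DNA")
  expect_equal(nrow(ts$manifest), 4356)
  expect_identical(names(ts$tiles), ts$manifest$name)
  expect_identical(reassemble_tiles(ts, lay), img)
})

test_that("16-bit TIFF tiles round-trip through disk", {
  img <- matrix(round(runif(32 * 32) * 65535) / 65535, 32, 32)
  f <- withr::local_tempfile(fileext = ".tif")
  write_tile_tiff(img, f)
  expect_equal(read_tile_tiff(f), img, tolerance = 1e-12)
})
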