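test_that("rank selection takes the exact top and bottom blocks", {
  readouts <- stats::setNames(1:200, sprintf("D%03d", 1:200))
  sel <- rank_select(readouts, n_extreme = 90)
  expect_equal(nrow(sel), 180)
  expect_equal(sum(sel$label), 90)
  expect_setequal(sel$readout[sel$label == 1], 111:200)
  expect_setequal(sel$readout[sel$label == 0], 1:90)
})

test_that("ties break stably by design id", {
  r <- stats::setNames(c(5, 5, 7), c("b", "a", "c"))
  sel <- rank_select(r, n_extreme = 1)
  expect_equal(sel$design_id[sel$label == 1], "c")
  expect_equal(sel$design_id[sel$label == 0], "a")  # lexicographically first 5
  # fully degenerate readouts: still N per class, all decided by the tie rule
  same <- stats::setNames(rep(1, 6), letters[1:6])
  sel2 <- rank_select(same, n_extreme = 2)
  expect_equal(sum(sel2$label), 2)
  expect_equal(nrow(sel2), 4)
  expect_equal(anyDuplicated(sel2$design_id), 0)
  expect_error(rank_select(same, n_extreme = 4), "cannot take")
})

test_that("the nested split hits the 144/29/7 sizes on 180 balanced items", {
  sel <- rank_select(stats::setNames(1:200, sprintf("D%03d", 1:200)), 90)
  sp <- nested_split(sel, seed = 0)
  sizes <- table(factor(sp$subset, c("train", "test", "validation")))
  expect_equal(unname(c(sizes)), c(144L, 29L, 7L))
  # class balance within one item per subset
  for (s in c("train", "test", "validation")) {
    cl <- table(sp$label[sp$subset == s])
    expect_lte(abs(cl[["0"]] - cl[["1"]]), 1)
  }
  # nominal validation fraction of the 20 % x 20 % nesting is 4 %
  expect_equal(0.20 * 0.20, 0.04)
  expect_equal(7 / 180, 0.04, tolerance = 0.03)
})

test_that("half-and-half fractions split 8 balanced items into 4/2/2", {
  lab <- data.frame(design_id = letters[1:8], label = rep(0:1, 4))
  sp <- nested_split(lab, test_fraction = 0.5, val_of_test_fraction = 0.5, seed = 1)
  sizes <- table(factor(sp$subset, c("train", "test", "validation")))
  expect_equal(unname(c(sizes)), c(4L, 2L, 2L))
})

test_that("splits are deterministic partitions with stratification", {
  sel <- rank_select(stats::setNames(rnorm(120), sprintf("D%03d", 1:120)), 40)
  a <- nested_split(sel, seed = 5)
  b <- nested_split(sel, seed = 5)
  expect_identical(a$subset, b$subset)
  c <- nested_split(sel, seed = 6)
  expect_false(identical(a$subset, c$subset))
  # partition: disjoint cover of the input
  expect_equal(sort(a$design_id), sort(sel$design_id))
  expect_true(all(a$subset %in% c("train", "test", "validation")))
  # stratification bound: class fraction off by at most 1/|subset|
  whole <- mean(sel$label)
  for (s in unique(a$subset)) {
    sub <- a$label[a$subset == s]
    expect_lte(abs(mean(sub) - whole), 1 / length(sub) + 1e-12)
  }
})

test_that("classes too small to reach every subset are rejected", {
  lab <- data.frame(design_id = letters[1:6], label = c(0, 1, 1, 1, 1, 1))
  expect_error(nested_split(lab, seed = 1), "too small")
  one <- data.frame(design_id = letters[1:4], label = rep(1, 4))
  expect_error(nested_split(one, seed = 1), "both classes")
})

test_that("model matrices standardize on the training subset only", {
  sel <- rank_select(stats::setNames(1:200, sprintf("D%03d", 1:200)), 90)
  sp <- nested_split(sel, seed = 0)
  tdds <- synthetic_design_table(sprintf("D%03d", 1:200), seed = 2)
  m <- export_model_matrix(sp, tdds)
  train <- m$x[m$subset == "train", ]
  expect_true(all(abs(colMeans(train)) < 1e-12))
  expect_true(all(abs(apply(train, 2, sd) - 1) < 1e-12))
  # test columns standardized with training parameters: means off zero
  test <- m$x[m$subset == "test", ]
  expect_false(all(abs(colMeans(test)) < 1e-6))
  # global mode centers the whole labelled set instead
  g <- export_model_matrix(sp, tdds, scope = "global")
  expect_true(all(abs(colMeans(g$x)) < 1e-12))

  tdds$dead <- 1
  expect_warning(m2 <- export_model_matrix(sp, tdds), "zero-variance")
  expect_equal(m2$dropped, "dead")
  expect_false("dead" %in% colnames(m2$x))
  expect_error(export_model_matrix(sp, tdds[-1, ]), "without a TDD row")
})

test_that("the boosting hyperparameter fixture loads as structured config", {
  cfg <- boosting_config()
  expect_equal(cfg$general$num_leaves, 191)
  expect_equal(cfg$general$boosting_type, "gbdt")
  expect_equal(cfg$general$n_estimators, 12042)
  expect_false(cfg$regularization$uniform_drop)
})
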