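#' Select the top- and bottom-ranked surfaces for binary classification
#'
#' Ranks designs by a readout (e.g. mean cell count of the retained
#' replicate units) and labels the top `n_extreme` designs 1 and the
#' bottom `n_extreme` designs 0.  Ties are broken stably by `design_id`
#' (lexicographic), so the selection is deterministic.
#'
#' @param readouts named numeric vector: one finite readout per design.
#' @param n_extreme designs per class (default 90, i.e. 180 labelled
#'   designs in total).
#' @return data.frame of class `rank_selection`: `design_id`, `readout`,
#'   `label` (1 = top, 0 = bottom), ordered top block first.
#' @export
rank_select <- function(readouts, n_extreme = 90) {
  if (is.null(names(readouts)) || anyNA(readouts) || any(!is.finite(readouts)))
    stop("readouts must be a named vector of finite values", call. = FALSE)
  n <- length(readouts)
  if (2 * n_extreme > n)
    stop(sprintf("cannot take 2 x %d extremes from %d designs", n_extreme, n), call. = FALSE)
  ids <- names(readouts)
  top <- order(-readouts, ids)[seq_len(n_extreme)]
  # bottom block drawn from the designs not already taken by the top block,
  # so heavily tied readouts still yield disjoint classes
  bottom <- setdiff(order(readouts, ids), top)[seq_len(n_extreme)]
  out <- data.frame(
    design_id = c(ids[top], ids[bottom]),
    readout = c(readouts[top], readouts[bottom]),
    label = rep(c(1L, 0L), each = n_extreme),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("rank_selection", "data.frame")
  out
}

round_half_up <- function(x) floor(x + 0.5)

# largest-remainder allocation of `total` slots to classes proportionally
# to sizes; deterministic (remainder desc, then class order)
allocate_stratified <- function(sizes, total) {
  target <- total * sizes / sum(sizes)
  base <- floor(target)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(target - base), seq_along(sizes))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Nested stratified train/test/validation split
#'
#' First splits the labelled items into training and holdout sets with a
#' holdout fraction of `test_fraction` (stratified on the label), then
#' splits the holdout into test and validation with `val_of_test_fraction`
#' of it going to validation, again stratified.  With the defaults
#' (0.20 and 0.20) the nominal fractions are 80 % train, 16 % test and
#' 4 % validation.  Subset sizes use round-half-up on the totals and a
#' largest-remainder allocation across classes, so per-class proportions
#' are preserved within one item per subset.  Deterministic under `seed`.
#'
#' @param labeled data.frame with `design_id` and a binary `label` column
#'   (as from [rank_select()]).
#' @param test_fraction fraction held out of training (default 0.20).
#' @param val_of_test_fraction fraction of the holdout used for validation
#'   (default 0.20).
#' @param seed integer seed.
#' @return data.frame of class `nested_split`: the input plus a `subset`
#'   column (`"train"`, `"test"`, `"validation"`).
#' @export
nested_split <- function(labeled, test_fraction = 0.20,
                         val_of_test_fraction = 0.20, seed = 0L) {
  stopifnot(all(c("design_id", "label") %in% names(labeled)))
  if (!(test_fraction > 0 && test_fraction < 1) ||
      !(val_of_test_fraction > 0 && val_of_test_fraction < 1))
    stop("fractions must lie strictly inside (0, 1)", call. = FALSE)
  classes <- sort(unique(labeled$label))
  if (length(classes) < 2) stop("both classes must be present", call. = FALSE)

  n <- nrow(labeled)
  n_holdout <- round_half_up(n * test_fraction)
  n_val <- round_half_up(n_holdout * val_of_test_fraction)
  sizes <- vapply(classes, function(cl) sum(labeled$label == cl), integer(1))
  hold_per_class <- allocate_stratified(sizes, n_holdout)
  val_per_class <- allocate_stratified(hold_per_class, n_val)
  if (any(hold_per_class == 0) || any(sizes - hold_per_class == 0) ||
      any(val_per_class == 0) || any(hold_per_class - val_per_class == 0))
    stop(sprintf("a class is too small to appear in every subset (class sizes: %s)",
                 paste(sizes, collapse = ", ")), call. = FALSE)

  rng <- local_rng(seed)
  subset <- rep("train", n)
  for (ci in seq_along(classes)) {
    rows <- which(labeled$label == classes[ci])
    hold <- rows[rng$sample(length(rows), size = hold_per_class[ci])]
    val <- hold[rng$sample(length(hold), size = val_per_class[ci])]
    subset[hold] <- "test"
    subset[val] <- "validation"
  }
  out <- labeled
  out$subset <- subset
  class(out) <- c("nested_split", "data.frame")
  attr(out, "spec") <- list(test_fraction = test_fraction,
                            val_of_test_fraction = val_of_test_fraction,
                            seed = seed)
  out
}

#' @export
print.nested_split <- function(x, ...) {
  tab <- table(factor(x$subset, c("train", "test", "validation")), x$label)
  cat(sprintf("nested stratified split of %d items: train %d, test %d, validation %d\n",
              nrow(x), sum(x$subset == "train"), sum(x$subset == "test"),
              sum(x$subset == "validation")))
  print(tab)
  invisible(x)
}

#' Build the standardized model matrix for a labelled design set
#'
#' Joins the labelled designs to their topography design descriptors and
#' z-scores every descriptor.  By default standardization parameters are
#' estimated on the training subset only and applied to all subsets
#' (preventing information leakage from test/validation into the scaler);
#' `scope = "global"` standardizes on all labelled rows before splitting,
#' for compatibility with workflows that scale first.  Zero-variance
#' descriptors are dropped with a warning and recorded.
#'
#' @param labeled a [nested_split()] (or any data.frame with `design_id`,
#'   `label`, and optionally `subset`).
#' @param tdds a design table (see [read_design_table()]).
#' @param scope `"train"` (default) or `"global"`.
#' @return list: `x` (numeric matrix, rows in `labeled` order), `y` (label
#'   vector), `subset` (or `NULL`), `center`, `scale` (named parameters on
#'   the kept columns), `dropped` (character).
#' @export
export_model_matrix <- function(labeled, tdds, scope = c("train", "global")) {
  scope <- match.arg(scope)
  validate_design_table(tdds)
  miss <- setdiff(labeled$design_id, tdds$design_id)
  if (length(miss))
    stop("designs without a TDD row: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  rows <- match(labeled$design_id, tdds$design_id)
  x <- as.matrix(tdds[rows, setdiff(names(tdds), "design_id"), drop = FALSE])
  rownames(x) <- labeled$design_id

  ref <- if (scope == "train" && "subset" %in% names(labeled))
    labeled$subset == "train" else rep(TRUE, nrow(x))
  center <- apply(x[ref, , drop = FALSE], 2, mean)
  scale_ <- apply(x[ref, , drop = FALSE], 2, stats::sd)
  dropped <- colnames(x)[is.na(scale_) | scale_ == 0]
  if (length(dropped)) {
    warning("dropped zero-variance descriptor(s): ", paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(x), dropped)
    x <- x[, keep, drop = FALSE]
    center <- center[keep]; scale_ <- scale_[keep]
  }
  x <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  list(x = x, y = labeled$label,
       subset = if ("subset" %in% names(labeled)) labeled$subset else NULL,
       center = center, scale = scale_, dropped = dropped)
}

#' Reference gradient-boosting hyperparameters
#'
#' Loads the shipped gradient-boosting (LightGBM-style) hyperparameter
#' fixture for users who attach an external trainer to the exported model
#' matrices.  Model training itself is outside this package's scope.
#'
#' @return named list of hyperparameters.
#' @export
boosting_config <- function() {
  yaml::read_yaml(system.file("extdata", "lightgbm_config.yaml",
                              package = "toposcreen", mustWork = TRUE))
}
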