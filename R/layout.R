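#' Chip layout: the TopoChip unit grid and design placement
#'
#' Builds the grid model of a TopoChip: an `n_rows` x `n_cols` array of
#' walled TopoUnits, each carrying one topography design.  With the default
#' geometry the chip holds 2176 unique designs, each present in duplicate,
#' plus 4 flat (unpatterned) units that double as the orientation landmark
#' in the lower-right corner of the chip.
#'
#' Replicate placement: the physical chip fixes where each design sits, but
#' only "duplicates spread across the chip" is knowable from the outside, so
#' the layout is generated by a seeded convention.  Non-flat positions are
#' ranked by column (ties shuffled under the seed); the first copy of every
#' design is drawn from the low-column half of that ranking and the second
#' copy from the high-column half, guaranteeing the two replicates of a
#' design sit in different regions of the chip.
#'
#' @param n_designs number of unique non-flat designs (default 2176).
#' @param n_rows,n_cols grid dimensions (default 66 x 66).
#' @param flat_count number of flat units (default 4).
#' @param seed integer seed controlling replicate placement.
#' @param flat_positions optional 2-column matrix/data.frame of (row, col)
#'   positions for the flat units; default is the lower-right 2x2 block
#'   (extended row-major if `flat_count` > 4).
#'
#' @return An object of class `chip_layout`: a list with `n_rows`, `n_cols`,
#'   `design_at` (character matrix of design ids, `"FLAT"` on flat units),
#'   `flat_positions` (data.frame of row/col), `n_designs` and `seed`.
#' @examples
#' lay <- chip_layout(n_designs = 6, n_rows = 4, n_cols = 4, flat_count = 4, seed = 7)
#' table(lay$design_at)
#' @export
chip_layout <- function(n_designs = 2176, n_rows = 66, n_cols = 66,
                        flat_count = 4, seed = 1, flat_positions = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_designs >= 0, flat_count >= 0)
  n_pos <- n_rows * n_cols
  if (2L * n_designs + flat_count != n_pos) {
    stop(sprintf(
      "layout arity mismatch: 2 x %d designs + %d flat units = %d, but the grid has %d x %d = %d positions",
      n_designs, flat_count, 2 * n_designs + flat_count, n_rows, n_cols, n_pos
    ), call. = FALSE)
  }

  if (is.null(flat_positions)) {
    flat_positions <- default_flat_block(n_rows, n_cols, flat_count)
  } else {
    flat_positions <- as.data.frame(flat_positions)
    names(flat_positions) <- c("row", "col")
    if (nrow(flat_positions) != flat_count)
      stop("flat_positions must have exactly flat_count rows", call. = FALSE)
    if (any(flat_positions$row < 1 | flat_positions$row > n_rows |
            flat_positions$col < 1 | flat_positions$col > n_cols))
      stop("flat_positions outside the grid", call. = FALSE)
  }

  design_at <- matrix(NA_character_, nrow = n_rows, ncol = n_cols)
  if (flat_count > 0)
    design_at[cbind(flat_positions$row, flat_positions$col)] <- "FLAT"

  if (n_designs > 0) {
    ids <- design_ids(n_designs)
    free <- which(is.na(design_at), arr.ind = TRUE)  # row, col of non-flat slots
    rng <- local_rng(seed)
    # rank free slots by column with a seeded shuffle breaking ties
    ord <- order(free[, "col"], rng$runif(nrow(free)))
    free <- free[ord, , drop = FALSE]
    half <- nrow(free) %/% 2L
    left  <- free[seq_len(n_designs), , drop = FALSE]
    right <- free[nrow(free) - n_designs + seq_len(n_designs), , drop = FALSE]
    left  <- left[rng$sample(n_designs), , drop = FALSE]
    right <- right[rng$sample(n_designs), , drop = FALSE]
    design_at[left]  <- ids
    design_at[right] <- ids
    stopifnot(half >= n_designs || nrow(free) == 2 * n_designs)
  }

  structure(
    list(n_rows = n_rows, n_cols = n_cols, design_at = design_at,
         flat_positions = flat_positions, n_designs = n_designs, seed = seed),
    class = "chip_layout"
  )
}

default_flat_block <- function(n_rows, n_cols, flat_count) {
  if (flat_count == 0) return(data.frame(row = integer(), col = integer()))
  # lower-right block, filled right-to-left then bottom-up
  side <- max(2L, ceiling(sqrt(flat_count)))
  side_r <- min(side, n_rows); side_c <- min(side, n_cols)
  rows <- rev(seq(n_rows - side_r + 1L, n_rows))
  cols <- rev(seq(n_cols - side_c + 1L, n_cols))
  grid <- expand.grid(col = cols, row = rows)[seq_len(flat_count), ]
  data.frame(row = grid$row, col = grid$col)
}

design_ids <- function(n) {
  sprintf(paste0("D%0", max(4L, nchar(n)), "d"), seq_len(n))
}

# Seeded RNG confined to a closure so package functions never disturb the
# caller's global random state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    runif  = function(n, ...) with_state(stats::runif(n, ...)),
    rnorm  = function(n, ...) with_state(stats::rnorm(n, ...)),
    rbinom = function(n, ...) with_state(stats::rbinom(n, ...)),
    rlnorm = function(n, ...) with_state(stats::rlnorm(n, ...)),
    sample = function(x, size = if (length(x) == 1 && is.numeric(x)) x else length(x), replace = FALSE)
      with_state(sample(x, size = size, replace = replace)),
    mvnorm2 = function(n, r) {
      # standard bivariate normal with correlation r
      z1 <- with_state(stats::rnorm(n)); z2 <- with_state(stats::rnorm(n))
      cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
    }
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("TopoChip layout: %d x %d grid, %d designs in duplicate, %d flat unit(s)\n",
              x$n_rows, x$n_cols, x$n_designs, nrow(x$flat_positions)))
  cat(sprintf("flat/orientation block at rows %s, cols %s (seed %s)\n",
              paste(range(x$flat_positions$row), collapse = "-"),
              paste(range(x$flat_positions$col), collapse = "-"),
              format(x$seed)))
  invisible(x)
}

#' @export
as.data.frame.chip_layout <- function(x, ...) {
  data.frame(
    row = rep(seq_len(x$n_rows), times = x$n_cols),
    col = rep(seq_len(x$n_cols), each = x$n_rows),
    design_id = as.vector(x$design_at),
    stringsAsFactors = FALSE
  )
}

#' Look up the design at one or more grid positions
#'
#' @param layout a [chip_layout()].
#' @param row,col 1-based grid indices (vectorized).
#' @return character vector of design ids (`"FLAT"` for flat units).
#' @export
design_at <- function(layout, row, col) {
  stopifnot(inherits(layout, "chip_layout"))
  if (any(row < 1 | row > layout$n_rows | col < 1 | col > layout$n_cols))
    stop("position outside the layout grid", call. = FALSE)
  layout$design_at[cbind(row, col)]
}

#' Serialize / load a chip layout as CSV
#'
#' The CSV holds one row per grid position (`row`, `col`, `design_id`);
#' flat units carry the reserved id `FLAT`.
#'
#' @param layout a [chip_layout()].
#' @param path file path.
#' @return `write_layout_csv` returns `path` invisibly; `read_layout_csv`
#'   returns a `chip_layout`.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "design_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("layout CSV missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  n_rows <- max(df$row); n_cols <- max(df$col)
  if (nrow(df) != n_rows * n_cols || anyNA(df$design_id))
    stop("layout CSV does not cover the full grid", call. = FALSE)
  design_at <- matrix(NA_character_, n_rows, n_cols)
  design_at[cbind(df$row, df$col)] <- df$design_id
  flat <- df[df$design_id == "FLAT", c("row", "col")]
  ids <- unique(df$design_id[df$design_id != "FLAT"])
  structure(
    list(n_rows = n_rows, n_cols = n_cols, design_at = design_at,
         flat_positions = flat, n_designs = length(ids), seed = NA_integer_),
    class = "chip_layout"
  )
}

#' Read / write a topography-design-descriptor (TDD) table
#'
#' One row per unique design; the first column is `design_id`, the remaining
#' columns are numeric descriptors of the pillar pattern (pillar length,
#' circularity, asymmetry, roughness, ...).  Missing values are rejected:
#' downstream model matrices require complete descriptor vectors.
#'
#' @param path CSV file path.
#' @param tdds a data.frame with a `design_id` column and numeric descriptors.
#' @return `read_design_table` returns the validated data.frame.
#' @export
read_design_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_design_table(df)
  df
}

#' @rdname read_design_table
#' @export
write_design_table <- function(tdds, path) {
  validate_design_table(tdds)
  utils::write.csv(tdds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_design_table <- function(df) {
  if (!"design_id" %in% names(df)) stop("design table must have a design_id column", call. = FALSE)
  if (anyDuplicated(df$design_id)) stop("design table has duplicated design_id rows", call. = FALSE)
  desc <- df[setdiff(names(df), "design_id")]
  if (!length(desc)) stop("design table has no descriptor columns", call. = FALSE)
  if (!all(vapply(desc, is.numeric, logical(1)))) stop("all TDD descriptors must be numeric", call. = FALSE)
  if (anyNA(desc)) stop("design table contains missing descriptor values", call. = FALSE)
  invisible(df)
}
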