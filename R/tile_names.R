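#' Tile filename grammar
#'
#' Every cropped TopoUnit tile is named
#' `[Channel]_[ChipID]_Col[ColumnNumber]_Row[RowNumber]_Seq[SequenceNumber]_[Stain].tif`
#' so that the chip, grid position, acquisition order and stain are all
#' recoverable from the filename alone.  `parse_tile_name()` and
#' `format_tile_name()` are exact inverses on valid names: numeric fields are
#' zero-padded on output (columns/rows to 2 digits, sequence to 4 by default,
#' so lexicographic order equals grid order) but any width is accepted on
#' input.
#'
#' @param name a tile filename.
#' @return `parse_tile_name` returns an object of class `tile_name`: a list
#'   with `channel`, `chip_id`, `col`, `row`, `seq`, `stain`.
#' @examples
#' t <- parse_tile_name("DAPI_chip9_Col12_Row03_Seq0795_DNA.tif")
#' format_tile_name(t$channel, t$chip_id, t$col, t$row, t$seq, t$stain)
#' @export
parse_tile_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  fail <- function(token) {
    stop(sprintf("malformed tile name %s: invalid token '%s'", sQuote(name), token),
         call. = FALSE)
  }
  if (!grepl("\\.tif$", name)) fail("extension")
  base <- sub("\\.tif$", "", name)
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) != 6) fail(sprintf("expected 6 '_'-separated fields, got %d", length(parts)))
  if (!nzchar(parts[1])) fail("channel")
  if (!nzchar(parts[2])) fail("chip_id")
  if (!grepl("^Col[0-9]+$", parts[3])) fail(paste0("Col: '", parts[3], "'"))
  if (!grepl("^Row[0-9]+$", parts[4])) fail(paste0("Row: '", parts[4], "'"))
  if (!grepl("^Seq[0-9]+$", parts[5])) fail(paste0("Seq: '", parts[5], "'"))
  if (!nzchar(parts[6])) fail("stain")
  col <- as.integer(sub("^Col", "", parts[3]))
  row <- as.integer(sub("^Row", "", parts[4]))
  seq <- as.integer(sub("^Seq", "", parts[5]))
  if (col < 1) fail("Col (1-based)")
  if (row < 1) fail("Row (1-based)")
  if (seq < 1) fail("Seq (1-based)")
  structure(
    list(channel = parts[1], chip_id = parts[2], col = col, row = row,
         seq = seq, stain = parts[6]),
    class = "tile_name"
  )
}

#' @rdname parse_tile_name
#' @param channel,chip_id,stain name tokens (must not contain `_`).
#' @param col,row 1-based grid position.
#' @param seq 1-based acquisition sequence index.
#' @param pad zero-pad widths for col, row, seq; longer numbers are kept whole.
#' @param n_rows,n_cols optional grid bounds; when given, `row`/`col` outside
#'   `[1, n_rows]` / `[1, n_cols]` are rejected.
#' @export
format_tile_name <- function(channel, chip_id, col, row, seq, stain,
                             pad = c(col = 2, row = 2, seq = 4),
                             n_rows = NULL, n_cols = NULL) {
  for (tok in list(channel = channel, chip_id = chip_id, stain = stain)) {
    if (!is.character(tok) || length(tok) != 1 || !nzchar(tok) || grepl("_", tok))
      stop("name tokens must be non-empty strings without '_'", call. = FALSE)
  }
  col <- as.integer(col); row <- as.integer(row); seq <- as.integer(seq)
  if (is.na(col) || col < 1 || (!is.null(n_cols) && col > n_cols))
    stop(sprintf("col %s out of range [1, %s]", col, if (is.null(n_cols)) "Inf" else n_cols), call. = FALSE)
  if (is.na(row) || row < 1 || (!is.null(n_rows) && row > n_rows))
    stop(sprintf("row %s out of range [1, %s]", row, if (is.null(n_rows)) "Inf" else n_rows), call. = FALSE)
  if (is.na(seq) || seq < 1) stop("seq must be a positive integer", call. = FALSE)
  sprintf("%s_%s_Col%0*d_Row%0*d_Seq%0*d_%s.tif",
          channel, chip_id, pad[["col"]], col, pad[["row"]], row, pad[["seq"]], seq, stain)
}

#' @export
format.tile_name <- function(x, ...) {
  format_tile_name(x$channel, x$chip_id, x$col, x$row, x$seq, x$stain, ...)
}

#' @export
print.tile_name <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Enumerate every tile name of a screen
#'
#' Expands the full naming grid for a set of chips and channel/stain pairs,
#' with the acquisition sequence index following row-major order
#' (`seq = (row - 1) * n_cols + col`).  With the default chip geometry, one
#' chip and one channel yield 4356 names; a 10-chip, 3-stain screen yields
#' 130,680.
#'
#' @param layout a [chip_layout()].
#' @param chip_ids character vector of chip identifiers.
#' @param channels,stains parallel character vectors: each channel is paired
#'   with the stain at the same index.
#' @return data.frame with columns `name`, `chip_id`, `channel`, `stain`,
#'   `row`, `col`, `seq`, `design_id`.
#' @export
enumerate_tile_names <- function(layout, chip_ids, channels, stains) {
  stopifnot(inherits(layout, "chip_layout"), length(channels) == length(stains))
  grid <- as.data.frame(layout)
  grid$seq <- (grid$row - 1L) * layout$n_cols + grid$col
  out <- vector("list", length(chip_ids) * length(channels))
  k <- 0L
  for (chip in chip_ids) {
    for (i in seq_along(channels)) {
      k <- k + 1L
      g <- grid
      g$chip_id <- chip; g$channel <- channels[i]; g$stain <- stains[i]
      out[[k]] <- g
    }
  }
  df <- do.call(rbind, out)
  df$name <- sprintf("%s_%s_Col%02d_Row%02d_Seq%04d_%s.tif",
                     df$channel, df$chip_id, df$col, df$row, df$seq, df$stain)
  df[c("name", "chip_id", "channel", "stain", "row", "col", "seq", "design_id")]
}
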