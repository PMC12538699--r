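#' Project a z-stack to a single image
#'
#' Maximum intensity projection keeps, at every pixel, the highest value
#' across planes (the choice that preserves the smallest bright puncta);
#' average projection takes the pixelwise arithmetic mean.  On integer
#' matrices the average is rounded half-up so the bit depth is preserved.
#'
#' @param stack list of plane matrices, all the same shape.
#' @param method `"max"` or `"average"`.
#' @return a single matrix of the common plane shape.
#' @examples
#' project_zstack(list(matrix(0:3, 2), matrix(3:0, 2)), "max")
#' @export
project_zstack <- function(stack, method = c("max", "average")) {
  method <- match.arg(method)
  stopifnot(is.list(stack), length(stack) >= 1)
  dims <- lapply(stack, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all planes in the stack must have the same shape", call. = FALSE)
  if (method == "max") {
    out <- Reduce(pmax, stack)
  } else {
    out <- Reduce(`+`, lapply(stack, as.numeric)) / length(stack)
    out <- matrix(out, nrow(stack[[1]]), ncol(stack[[1]]))
    if (all(vapply(stack, is.integer, logical(1))))
      out <- matrix(as.integer(floor(out + 0.5)), nrow(out), ncol(out))
  }
  out
}

#' Rotate an image by a multiple of 90 degrees
#'
#' @param img matrix.
#' @param degrees clockwise rotation, one of 0, 90, 180, 270.
#' @return the rotated matrix.
#' @export
rotate_image <- function(img, degrees) {
  degrees <- as.integer(degrees) %% 360L
  if (!degrees %in% c(0L, 90L, 180L, 270L))
    stop("rotation must be a multiple of 90 degrees", call. = FALSE)
  k <- degrees %/% 90L
  for (i in seq_len(k)) img <- t(img[nrow(img):1, , drop = FALSE])
  img
}

#' Canonicalize chip orientation using the flat-unit landmark
#'
#' The flat units lack pillar texture, so the block of lowest per-unit
#' texture variance marks them.  The image is tested in all four 90-degree
#' orientations; the orientation that puts the low-variance flat block in
#' its expected lower-right position wins.  If no orientation (landmark
#' erased) or more than one orientation (ambiguous landmark) qualifies, no
#' rotation is applied and the report carries the error.
#'
#' @param img grayscale matrix whose dimensions are exact multiples of the
#'   layout grid.
#' @param layout a [chip_layout()]; its `flat_positions` define where the
#'   landmark must sit after canonicalization.
#' @param landmark_detector function `(img, layout) -> matrix` of per-unit
#'   texture scores (lower = flatter); the default is per-tile variance.
#' @param detect_ratio a candidate orientation's flat-block score must be
#'   below `detect_ratio` times the chip-wide median unit score to count as
#'   "landmark found" (default 0.25).
#' @return list with `image` (canonical orientation, or the input on
#'   error), `rotation` (clockwise degrees applied, or `NA`), and `error`
#'   (`NULL` or a message).
#' @export
orient_chip <- function(img, layout, landmark_detector = unit_texture_variance,
                        detect_ratio = 0.25) {
  stopifnot(inherits(layout, "chip_layout"))
  check_divisible(img, layout)
  flat_idx <- cbind(layout$flat_positions$row, layout$flat_positions$col)
  if (!nrow(flat_idx)) stop("layout has no flat landmark units", call. = FALSE)

  rotations <- c(0L, 90L, 180L, 270L)
  scores <- vapply(rotations, function(k) {
    rot <- rotate_image(img, k)
    tex <- landmark_detector(rot, layout)
    mean(tex[flat_idx]) / stats::median(tex)
  }, numeric(1))
  found <- which(scores < detect_ratio)

  if (length(found) != 1L) {
    msg <- if (length(found) == 0L)
      "orientation landmark not found in any rotation"
    else sprintf("orientation ambiguous: landmark detected at rotations %s",
                 paste(rotations[found], collapse = ", "))
    return(list(image = img, rotation = NA_integer_, error = msg))
  }
  k <- rotations[found]
  list(image = rotate_image(img, k), rotation = k, error = NULL)
}

#' @rdname orient_chip
#' @export
unit_texture_variance <- function(img, layout) {
  ppu_r <- nrow(img) %/% layout$n_rows
  ppu_c <- ncol(img) %/% layout$n_cols
  out <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  for (i in seq_len(layout$n_rows)) {
    rows <- (i - 1L) * ppu_r + seq_len(ppu_r)
    # drop the 1-px walls so the score reflects interior texture only
    rows <- rows[-c(1L, length(rows))]
    for (j in seq_len(layout$n_cols)) {
      cols <- (j - 1L) * ppu_c + seq_len(ppu_c)
      cols <- cols[-c(1L, length(cols))]
      out[i, j] <- stats::var(as.vector(img[rows, cols]))
    }
  }
  out
}

#' Bilinear tilt map over unit centers
#'
#' Interpolates four corner focal-plane heights (measured on the corner
#' TopoUnits while setting up autofocus) over the whole unit grid.  The
#' map is diagnostic: it visualizes chip tilt, it does not warp images.
#'
#' @param corner_values numeric length 4: heights at the top-left,
#'   top-right, bottom-left, bottom-right corner units.
#' @param n_rows,n_cols grid dimensions.
#' @return object of class `tilt_map`: list with `corner_values`, `values`
#'   (an `n_rows x n_cols` matrix), `n_rows`, `n_cols`.
#' @examples
#' tm <- tilt_map(c(0, 1, 0, 1), 3, 3)
#' tm$values[, 2]  # middle column, halfway between the corner planes
#' @export
tilt_map <- function(corner_values, n_rows, n_cols) {
  if (length(corner_values) != 4 || !all(is.finite(corner_values)))
    stop("corner_values must be 4 finite heights (TL, TR, BL, BR)", call. = FALSE)
  u <- if (n_rows > 1) (seq_len(n_rows) - 1) / (n_rows - 1) else 0
  v <- if (n_cols > 1) (seq_len(n_cols) - 1) / (n_cols - 1) else 0
  tl <- corner_values[1]; tr <- corner_values[2]
  bl <- corner_values[3]; br <- corner_values[4]
  vals <- outer(1 - u, 1 - v) * tl + outer(1 - u, v) * tr +
    outer(u, 1 - v) * bl + outer(u, v) * br
  structure(list(corner_values = corner_values, values = vals,
                 n_rows = n_rows, n_cols = n_cols),
            class = "tilt_map")
}

#' @export
print.tilt_map <- function(x, ...) {
  cat(sprintf("tilt map over %d x %d units; corner heights TL %.3g TR %.3g BL %.3g BR %.3g\n",
              x$n_rows, x$n_cols, x$corner_values[1], x$corner_values[2],
              x$corner_values[3], x$corner_values[4]))
  cat(sprintf("range %.3g .. %.3g\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.tilt_map <- function(x, ...) {
  graphics::image(t(x$values)[, x$n_rows:1], main = "tilt heatmap",
                  xlab = "column", ylab = "row", ...)
  invisible(x)
}

#' @rdname tilt_map
#' @param x a `tilt_map`.
#' @param path CSV output path for the interpolated height matrix.
#' @export
write_tilt_csv <- function(x, path) {
  stopifnot(inherits(x, "tilt_map"))
  utils::write.table(x$values, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_divisible <- function(img, layout) {
  if (nrow(img) %% layout$n_rows != 0 || ncol(img) %% layout$n_cols != 0) {
    pad_r <- (layout$n_rows - nrow(img) %% layout$n_rows) %% layout$n_rows
    pad_c <- (layout$n_cols - ncol(img) %% layout$n_cols) %% layout$n_cols
    stop(sprintf(
      "image (%d x %d) does not partition into the %d x %d unit grid; pad by %d row(s) and %d column(s) or crop",
      nrow(img), ncol(img), layout$n_rows, layout$n_cols, pad_r, pad_c), call. = FALSE)
  }
  invisible(TRUE)
}

#' Crop a stitched chip image into named TopoUnit tiles
#'
#' Splits the image into the layout's unit grid and names every tile by
#' the screen's filename grammar (see [format_tile_name()]), with the
#' sequence index in row-major acquisition order.  Cropping is lossless:
#' [reassemble_tiles()] on the result reproduces the input exactly.
#'
#' @param img grayscale matrix; dimensions must be exact multiples of the
#'   grid (strict, with the required padding reported otherwise).
#' @param layout a [chip_layout()].
#' @param chip_id,channel,stain name tokens for the tile files.
#' @param out_dir optional directory: when given, every tile is written as
#'   a 16-bit grayscale TIFF and the manifest gains an md5 checksum column.
#' @return object of class `tile_set`: list with `tiles` (named list of
#'   matrices, in manifest order) and `manifest` (data.frame: `name`,
#'   `row`, `col`, `seq`, `design_id`, `checksum`).
#' @export
crop_units <- function(img, layout, chip_id, channel, stain, out_dir = NULL) {
  stopifnot(inherits(layout, "chip_layout"))
  check_divisible(img, layout)
  ppu_r <- nrow(img) %/% layout$n_rows
  ppu_c <- ncol(img) %/% layout$n_cols

  man <- enumerate_tile_names(layout, chip_id, channel, stain)
  tiles <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rows <- (man$row[i] - 1L) * ppu_r + seq_len(ppu_r)
    cols <- (man$col[i] - 1L) * ppu_c + seq_len(ppu_c)
    tiles[[i]] <- img[rows, cols, drop = FALSE]
  }
  names(tiles) <- man$name
  man$checksum <- NA_character_

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, man$name)
    for (i in seq_along(tiles)) write_tile_tiff(tiles[[i]], paths[i])
    man$checksum <- unname(tools::md5sum(paths))
  }
  structure(list(tiles = tiles,
                 manifest = man[c("name", "row", "col", "seq", "design_id", "checksum")]),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile set: %d tiles of %d x %d px\n", length(x$tiles),
              nrow(x$tiles[[1]]), ncol(x$tiles[[1]])))
  invisible(x)
}

#' @rdname crop_units
#' @param tile_set a `tile_set` from [crop_units()].
#' @export
reassemble_tiles <- function(tile_set, layout) {
  stopifnot(inherits(tile_set, "tile_set"), inherits(layout, "chip_layout"))
  man <- tile_set$manifest
  ppu_r <- nrow(tile_set$tiles[[1]])
  ppu_c <- ncol(tile_set$tiles[[1]])
  img <- matrix(NA_real_, layout$n_rows * ppu_r, layout$n_cols * ppu_c)
  for (i in seq_len(nrow(man))) {
    rows <- (man$row[i] - 1L) * ppu_r + seq_len(ppu_r)
    cols <- (man$col[i] - 1L) * ppu_c + seq_len(ppu_c)
    img[rows, cols] <- tile_set$tiles[[i]]
  }
  img
}

#' Read / write 16-bit grayscale TIFF tiles
#'
#' Values are kept in `[0, 1]` in memory and quantized to 16 bits on disk;
#' `read_tile_tiff(write_tile_tiff(x))` is exact for any image already on
#' the 16-bit grid (as all package-generated images are after one write).
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @export
write_tile_tiff <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_tile_tiff
#' @export
read_tile_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
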