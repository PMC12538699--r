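#' Render a synthetic stitched chip image with ground-truth mask
#'
#' Draws a grayscale chip image (values in `[0, 1]`) laid out as the
#' layout's unit grid: bright 1-px walls around every unit (the vertical
#' walls that stop cells migrating between TopoUnits), a dim pillar-dot
#' lattice inside every patterned unit, no lattice inside flat units (which
#' is what makes the flat block detectable as the orientation landmark),
#' and elliptical "nuclei" at seeded positions for the supplied cells.
#' A label mask of the same size is returned, with background 0 and each
#' nucleus labelled 1..n in drawing order.
#'
#' @param layout a [chip_layout()].
#' @param px_per_unit tile edge in pixels (>= 16).
#' @param cells optional data.frame with `row`, `col` (and, if available,
#'   `nuclear_area` used to scale the drawn nuclei); one drawn nucleus per
#'   row.  Positions outside the layout are rejected.
#' @param seed integer seed for nucleus placement.
#' @return list with `image` and `mask` matrices of size
#'   `(n_rows * px_per_unit) x (n_cols * px_per_unit)`.
#' @export
generate_stitched_image <- function(layout, px_per_unit = 32, cells = NULL, seed = 1L) {
  stopifnot(inherits(layout, "chip_layout"))
  if (px_per_unit < 16) stop("px_per_unit must be at least 16", call. = FALSE)
  nr <- layout$n_rows * px_per_unit
  nc <- layout$n_cols * px_per_unit
  img <- matrix(0.05, nr, nc)
  mask <- matrix(0L, nr, nc)

  # pillar lattice in patterned units, drawn chip-wide then erased on flats
  lattice <- seq(3, px_per_unit - 2, by = 4)
  py <- as.vector(outer(lattice, (seq_len(layout$n_rows) - 1L) * px_per_unit, `+`))
  px <- as.vector(outer(lattice, (seq_len(layout$n_cols) - 1L) * px_per_unit, `+`))
  img[py, px] <- 0.35
  if (nrow(layout$flat_positions)) {
    for (i in seq_len(nrow(layout$flat_positions))) {
      r0 <- (layout$flat_positions$row[i] - 1L) * px_per_unit
      c0 <- (layout$flat_positions$col[i] - 1L) * px_per_unit
      img[r0 + seq_len(px_per_unit), c0 + seq_len(px_per_unit)] <- 0.05
    }
  }

  # unit walls: first/last pixel row and column of every tile
  wall_r <- sort(c((seq_len(layout$n_rows) - 1L) * px_per_unit + 1L,
                   seq_len(layout$n_rows) * px_per_unit))
  wall_c <- sort(c((seq_len(layout$n_cols) - 1L) * px_per_unit + 1L,
                   seq_len(layout$n_cols) * px_per_unit))
  img[wall_r, ] <- 0.7
  img[, wall_c] <- 0.7

  if (!is.null(cells) && nrow(cells)) {
    if (any(cells$row < 1 | cells$row > layout$n_rows |
            cells$col < 1 | cells$col > layout$n_cols))
      stop("cells reference positions outside the layout", call. = FALSE)
    rng <- local_rng(seed)
    base_r <- px_per_unit / 8
    scale <- if ("nuclear_area" %in% names(cells))
      sqrt(pmax(cells$nuclear_area, 1) / 737) else rep(1, nrow(cells))
    margin <- ceiling(base_r * 2) + 2L
    for (i in seq_len(nrow(cells))) {
      cy <- (cells$row[i] - 1L) * px_per_unit + margin +
        rng$runif(1) * (px_per_unit - 2 * margin)
      cx <- (cells$col[i] - 1L) * px_per_unit + margin +
        rng$runif(1) * (px_per_unit - 2 * margin)
      r <- base_r * min(scale[i], 1.6)
      ar <- 0.7 + rng$runif(1) * 0.6
      ry <- r * ar; rx <- r / ar
      ys <- max(1L, floor(cy - ry)):min(nr, ceiling(cy + ry))
      xs <- max(1L, floor(cx - rx)):min(nc, ceiling(cx + rx))
      d <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`)
      hit <- d <= 1
      img[ys, xs][hit] <- 0.95
      mask[ys, xs][hit] <- i
    }
  }
  list(image = img, mask = mask)
}

#' Simulate a z-stack from an in-focus base image
#'
#' Emulates the acquisition protocol of stepping the focal plane through
#' the sample (a 16 um range at 4 um steps gives 5 planes): each plane is
#' the base image blurred with a per-plane Gaussian radius plus seeded
#' sensor noise.  A blur radius of 0 leaves the plane identical to the base
#' (the in-focus plane).
#'
#' @param base numeric matrix in `[0, 1]`.
#' @param blur_profile numeric vector of per-plane Gaussian sigmas (pixels);
#'   its length sets the number of planes.  Negative values are rejected.
#' @param noise_sd SD of additive Gaussian noise (default 0).
#' @param seed integer seed for the noise.
#' @return list of plane matrices, in `blur_profile` order.
#' @export
generate_zstack <- function(base, blur_profile, noise_sd = 0, seed = 1L) {
  stopifnot(is.matrix(base), length(blur_profile) >= 1)
  if (any(blur_profile < 0)) stop("blur radii must be non-negative", call. = FALSE)
  rng <- local_rng(seed)
  lapply(blur_profile, function(sig) {
    plane <- if (sig > 0) gaussian_blur(base, sig) else base
    if (noise_sd > 0)
      plane <- plane + rng$rnorm(length(plane), 0, noise_sd)
    pmin(pmax(plane, 0), 1)
  })
}

gaussian_blur <- function(img, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = sigma)))
}
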