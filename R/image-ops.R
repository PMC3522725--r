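## Binary mask operations backed by the compiled kernels in src/.
## Masks are logical matrices, 0-based pixel geometry, row-major display
## convention (row = y), areas in px unless a pixel size converts to um^2.

#' Disc structuring element offsets
#'
#' Row/column offsets of a discrete disc of the given radius, used as the
#' structuring element for [mask_dilate()], [mask_erode()] and [mask_close()].
#'
#' @param radius_px disc radius in pixels (`>= 0`); radius 0 is the single
#'   centre pixel (identity element).
#' @return integer matrix with columns (row offset, col offset).
#' @keywords internal
disc_offsets <- function(radius_px) {
  stopifnot(is.numeric(radius_px), length(radius_px) == 1L, radius_px >= 0)
  r <- floor(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius_px^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

as_mask <- function(x) {
  if (inherits(x, "roi_mask")) x <- x$mask
  if (!is.matrix(x) || !is.logical(x)) stop("mask must be a logical matrix")
  x
}

#' Binary dilation by a disc
#' @param mask logical matrix.
#' @param radius_px disc radius in pixels.
#' @return logical matrix of the same shape.
#' @export
mask_dilate <- function(mask, radius_px) {
  mask <- as_mask(mask)
  if (radius_px <= 0) return(mask)
  m <- cpp_dilate(mask, disc_offsets(radius_px))
  dimnames(m) <- dimnames(mask)
  m
}

#' Binary erosion by a disc
#' @inheritParams mask_dilate
#' @export
mask_erode <- function(mask, radius_px) {
  mask <- as_mask(mask)
  if (radius_px <= 0) return(mask)
  m <- cpp_erode(mask, disc_offsets(radius_px))
  dimnames(m) <- dimnames(mask)
  m
}

#' Morphological closing (dilation then erosion) by a disc
#'
#' The erosion step treats out-of-frame pixels as foreground so that closing
#' is extensive (never removes an original pixel) even at the frame border.
#' @inheritParams mask_dilate
#' @export
mask_close <- function(mask, radius_px) {
  mask <- as_mask(mask)
  if (radius_px <= 0) return(mask)
  m <- cpp_erode(cpp_dilate(mask, disc_offsets(radius_px)),
                 disc_offsets(radius_px), pad_foreground = TRUE)
  dimnames(m) <- dimnames(mask)
  m
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' converted to foreground.
#' @param mask logical matrix.
#' @export
mask_fill_holes <- function(mask) {
  mask <- as_mask(mask)
  m <- cpp_fill_holes(mask)
  dimnames(m) <- dimnames(mask)
  m
}

#' Label connected components (8-connectivity)
#' @param mask logical matrix.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
mask_label <- function(mask) {
  mask <- as_mask(mask)
  m <- cpp_label(mask)
  dimnames(m) <- dimnames(mask)
  m
}

#' Retain the largest connected component of a mask
#'
#' Ties on size are broken by the lower label (scan order). An all-FALSE mask
#' is returned unchanged.
#' @param mask logical matrix.
#' @export
mask_largest_component <- function(mask) {
  mask <- as_mask(mask)
  lab <- cpp_label(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  m <- lab == keep
  dimnames(m) <- dimnames(mask)
  m
}
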