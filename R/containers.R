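## Core containers for image quantification. Plain S3 lists, mirroring how
## field packages wrap pixel data: a named set of registered channel matrices
## plus the physical pixel size that converts px counts to um^2.

#' Multichannel image
#'
#' A set of registered single-channel intensity images sharing one shape and
#' pixel size. All segmentation and integrated-density operations act on these.
#'
#' @param channels named list of numeric matrices (AFU), identical dimensions,
#'   all values `>= 0`.
#' @param pixel_size pixel edge length in micrometres per pixel.
#' @param bit_depth nominal acquisition bit depth (metadata only).
#' @return an object of class `mc_image`.
#' @export
multichannel_image <- function(channels, pixel_size, bit_depth = 16L) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("every channel must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channels must share the same shape")
  if (any(vapply(channels, function(ch) any(ch < 0 | !is.finite(ch)), logical(1))))
    stop("channel intensities must be finite and >= 0")
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  structure(list(channels = channels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth)),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %dx%d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Get one channel of a multichannel image
#' @param image an `mc_image`.
#' @param channel channel name.
#' @return numeric matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "mc_image"))
  if (!channel %in% names(image$channels))
    stop("no channel '", channel, "' (have: ",
         paste(names(image$channels), collapse = ", "), ")")
  image$channels[[channel]]
}

#' Image z-stack
#'
#' Ordered focal planes (each a [multichannel_image()]) with a z spacing.
#'
#' @param planes list of `mc_image`, all the same shape and channel set.
#' @param z_spacing plane spacing in micrometres.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(planes, z_spacing = 0.5) {
  if (!is.list(planes) || length(planes) < 1L) stop("stack needs >= 1 plane")
  if (!all(vapply(planes, inherits, logical(1), "mc_image")))
    stop("planes must be mc_image objects")
  shp <- vapply(planes, function(p) paste(dim(p$channels[[1]]), collapse = "x"),
                character(1))
  if (length(unique(shp)) != 1L) stop("all planes must share the same shape")
  stopifnot(z_spacing > 0)
  structure(list(planes = planes, z_spacing = z_spacing), class = "image_stack")
}

#' Region-of-interest mask
#'
#' @param mask logical matrix, same shape as the image it indexes.
#' @param label short identifier used to pair measurements.
#' @param provenance one of `"manual"`, `"threshold"`, `"geometry"`.
#' @param allow_empty allow an all-FALSE mask (e.g. a forced sub-threshold ROI).
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi", provenance = c("manual", "threshold", "geometry"),
                     allow_empty = FALSE) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (!allow_empty && !any(mask)) stop("ROI '", label, "' is empty")
  structure(list(mask = mask, label = label, provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s), %d px\n", x$label, x$provenance, sum(x$mask)))
  invisible(x)
}

roi_logical <- function(roi, image = NULL) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!is.matrix(m) || !is.logical(m)) stop("roi must be a roi_mask or logical matrix")
  if (!is.null(image) && !identical(dim(m), dim(image)))
    stop("ROI shape ", paste(dim(m), collapse = "x"),
         " does not match image shape ", paste(dim(image), collapse = "x"))
  m
}
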