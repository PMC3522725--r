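## AID quantification: integrated density above a histogram-derived positive
## cutoff within a region of interest, the Tyr-MT/Glu-MT ratio with
## below-detection handling, focal-plane selection and MT-network area.

#' Integrated density over a region of interest
#'
#' Sum of the pixel values inside the ROI; identically equal to the product of
#' the ROI area and the mean gray value.
#'
#' @param image numeric intensity matrix (AFU).
#' @param roi a [roi_mask()] or logical matrix of the same shape.
#' @return total intensity (AFU).
#' @export
integrated_density <- function(image, roi) {
  m <- roi_logical(roi, image)
  if (!any(m)) stop("empty ROI: integrated density undefined")
  sum(image[m])
}

#' Histogram-derived positive cutoff
#'
#' Selects the intensity above which a pixel counts as positively stained,
#' from the ROI's intensity histogram. `"otsu"` maximizes the between-class
#' variance over 256 histogram bins (parameter-free, the default);
#' `"background_k_mad"` uses the robust background estimate
#' `median + k * MAD`. If `control_background` is supplied (autofluorescence
#' measured from a control slide), the returned cutoff is never below it, so
#' no pixel at or below the control background is ever counted positive.
#'
#' @param image numeric intensity matrix.
#' @param roi ROI over which the histogram is formed.
#' @param method `"otsu"` or `"background_k_mad"`.
#' @param control_background optional floor for the cutoff (AFU, `>= 0`).
#' @param k MAD multiplier for `"background_k_mad"`.
#' @return cutoff intensity in AFU.
#' @export
positive_cutoff <- function(image, roi = NULL,
                            method = c("otsu", "background_k_mad"),
                            control_background = NULL, k = 3) {
  method <- match.arg(method)
  m <- if (is.null(roi)) matrix(TRUE, nrow(image), ncol(image))
       else roi_logical(roi, image)
  if (!any(m)) stop("empty ROI: cannot form an intensity histogram")
  v <- image[m]
  if (!is.null(control_background))
    stopifnot(length(control_background) == 1L, control_background >= 0)
  rng <- range(v)
  if (diff(rng) == 0)
    stop(sprintf("degenerate histogram: ROI is constant at %.6g", rng[1]))
  cutoff <- if (method == "otsu") otsu_threshold(v) else
    median(v) + k * mad(v)
  if (!is.null(control_background)) cutoff <- max(cutoff, control_background)
  cutoff
}

# Otsu's criterion on a 256-bin histogram: exhaustive maximization of the
# between-class variance w0*w1*(mu0-mu1)^2 over all bin boundaries. Returns
# the intensity at the selected boundary (upper edge of the lower class).
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(cnt)
  w1 <- sum(cnt) - w0
  s0 <- cumsum(cnt * mids)
  mu0 <- s0 / w0
  mu1 <- (s0[n_bins] - s0) / w1
  crit <- w0 * w1 * (mu0 - mu1)^2
  crit[w0 == 0 | w1 == 0] <- -Inf
  br[which.max(crit) + 1L]
}

#' Measure AID above a positive cutoff
#'
#' The positive mask is the ROI restricted to pixels strictly above the
#' cutoff; AID is the integrated density over that mask. When the positive
#' area is a smaller fraction of the ROI than `min_positive_fraction`, the
#' staining is flagged below detection (all-or-nothing colchicine regime) and
#' must not enter ratio statistics.
#'
#' @param image numeric intensity matrix.
#' @param roi a [roi_mask()] or logical matrix.
#' @param cutoff positive cutoff (AFU), e.g. from [positive_cutoff()].
#' @param min_positive_fraction below-detection rule: minimum positive-area
#'   fraction of the ROI (default 0.5%).
#' @param pixel_size optional um/px for the area in um^2.
#' @param channel channel label carried into the measurement.
#' @return object of class `aid_measurement` with fields `channel`, `cutoff`,
#'   `positive_area_px`, `positive_area_um2`, `aid`, `mean_gray`,
#'   `below_detection`, `roi_label`.
#' @export
aid_measure <- function(image, roi, cutoff, min_positive_fraction = 0.005,
                        pixel_size = NULL, channel = NA_character_) {
  m <- roi_logical(roi, image)
  if (!any(m)) stop("empty ROI: AID undefined")
  stopifnot(is.finite(cutoff))
  pos <- m & image > cutoff
  area <- sum(pos)
  aid <- if (area > 0) sum(image[pos]) else 0
  structure(list(
    channel = channel,
    cutoff = cutoff,
    positive_area_px = area,
    positive_area_um2 = if (is.null(pixel_size)) NA_real_ else area * pixel_size^2,
    aid = aid,
    mean_gray = if (area > 0) aid / area else NA_real_,
    below_detection = area / sum(m) < min_positive_fraction,
    roi_label = if (inherits(roi, "roi_mask")) roi$label else NA_character_),
    class = "aid_measurement")
}

#' @export
print.aid_measurement <- function(x, ...) {
  cat(sprintf("<aid_measurement> %s: AID %.4g over %d px (cutoff %.4g)%s\n",
              x$channel, x$aid, x$positive_area_px, x$cutoff,
              if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' Tyr-MT / Glu-MT fluorescence intensity ratio
#'
#' The ratio is only defined when both measurements are above detection and
#' the Glu AID is positive; otherwise the result is flagged undefined (never
#' 0, never infinite) and refuses to propagate into group statistics.
#' Measurements must come from the same ROI (matched by `roi_label`).
#'
#' @param tyr,glu [aid_measure()] results for the Tyr and Glu channels.
#' @return object of class `ratio_measurement` with fields `tyr_aid`,
#'   `glu_aid`, `ratio`, `defined`.
#' @export
tyr_glu_ratio <- function(tyr, glu) {
  stopifnot(inherits(tyr, "aid_measurement"), inherits(glu, "aid_measurement"))
  if (!is.na(tyr$roi_label) && !is.na(glu$roi_label) &&
      !identical(tyr$roi_label, glu$roi_label))
    stop("pairing error: measurements come from different ROIs ('",
         tyr$roi_label, "' vs '", glu$roi_label, "')")
  defined <- !tyr$below_detection && !glu$below_detection && glu$aid > 0
  structure(list(tyr_aid = tyr$aid, glu_aid = glu$aid,
                 ratio = if (defined) tyr$aid / glu$aid else NA_real_,
                 defined = defined),
            class = "ratio_measurement")
}

#' @export
print.ratio_measurement <- function(x, ...) {
  if (x$defined) cat(sprintf("<ratio_measurement> Tyr/Glu = %.4g\n", x$ratio))
  else cat("<ratio_measurement> undefined (below detection or zero Glu AID)\n")
  invisible(x)
}

#' Select the focal plane with maximal thresholded-positive area
#'
#' For each plane the channel is thresholded ([positive_cutoff()], with the
#' robust `median + 3 MAD` background floor) and the plane maximizing the
#' positive area is chosen; ties go to the lower index.
#'
#' @param stack an [image_stack()].
#' @param channel channel name to threshold.
#' @param cutoff_method passed to [positive_cutoff()].
#' @param roi optional ROI restricting the measurement.
#' @return 1-based plane index.
#' @export
select_focal_plane <- function(stack, channel = "glu",
                               cutoff_method = "otsu", roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$planes) == 0L) stop("empty stack")
  areas <- vapply(stack$planes, function(pl) {
    img <- get_channel(pl, channel)
    floor_bg <- median(img) + 3 * mad(img)
    cut <- positive_cutoff(img, roi, method = cutoff_method,
                           control_background = floor_bg)
    m <- if (is.null(roi)) img > cut else roi_logical(roi, img) & img > cut
    sum(m)
  }, numeric(1))
  which.max(areas)
}

#' Microtubule network area from the outer boundaries of the network
#'
#' Threshold, morphological closing (disc of `closing_radius_px`), hole
#' filling, then the largest connected component; the reported area is the
#' filled component's pixel count (and um^2). Closing + hole-fill rather than
#' a convex hull, because hulls overestimate star-shaped cells. Area is
#' monotonically non-decreasing in the closing radius.
#'
#' @param image numeric intensity matrix (the MT channel).
#' @param cutoff positive cutoff in AFU.
#' @param closing_radius_px closing disc radius (`>= 0`, default 5).
#' @param pixel_size um/px.
#' @param plane_index optional plane bookkeeping (from [select_focal_plane()]).
#' @return object of class `network_area_result` with fields `plane_index`,
#'   `area_px`, `area_um2`, `boundary_mask` (a [roi_mask()]), `below_detection`.
#' @export
mt_network_area <- function(image, cutoff, closing_radius_px = 5,
                            pixel_size = 1, plane_index = NA_integer_) {
  stopifnot(closing_radius_px >= 0)
  pos <- image > cutoff
  if (!any(pos)) {
    return(structure(list(plane_index = plane_index, area_px = 0,
                          area_um2 = 0,
                          boundary_mask = roi_mask(pos, "network",
                                                   provenance = "threshold",
                                                   allow_empty = TRUE),
                          below_detection = TRUE),
                     class = "network_area_result"))
  }
  m <- mask_largest_component(mask_fill_holes(mask_close(pos, closing_radius_px)))
  structure(list(plane_index = plane_index, area_px = sum(m),
                 area_um2 = sum(m) * pixel_size^2,
                 boundary_mask = roi_mask(m, "network", provenance = "threshold"),
                 below_detection = FALSE),
            class = "network_area_result")
}

#' In-cell-western normalization to the nuclear stain
#'
#' Divides each well's fluorescent signal by its Hoechst signal (a proxy for
#' the relative cell amount per well). Wells with non-positive or missing
#' Hoechst signal are excluded with a warning naming them.
#'
#' @param table a plate table (data frame with `signal_afu`, `hoechst_afu`).
#' @return the table with a `normalized_fau` column, excluded wells dropped.
#' @export
icw_normalize <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("signal_afu", "hoechst_afu") %in% names(table)))
  bad <- !is.finite(table$hoechst_afu) | table$hoechst_afu <= 0
  if (all(bad)) stop("all wells excluded: no positive Hoechst signal")
  if (any(bad)) {
    ids <- if ("well" %in% names(table)) table$well[bad] else which(bad)
    warning("excluding ", sum(bad), " well(s) with non-positive Hoechst signal: ",
            paste(ids, collapse = ", "))
    table <- table[!bad, , drop = FALSE]
  }
  table$normalized_fau <- table$signal_afu / table$hoechst_afu
  table
}

#' Quantify one Tyr/Glu cell image
#'
#' Convenience wrapper tying the AID steps together the way the pipeline runs
#' them: per-channel Otsu cutoff with a robust background floor
#' (`median + 3 MAD` of the ROI, standing in for the control-slide
#' autofluorescence), AID measurement, and the Tyr/Glu ratio.
#'
#' @param image an [multichannel_image()] with `tyr` and `glu` channels.
#' @param roi cell ROI ([roi_mask()]).
#' @param min_positive_fraction below-detection rule (fraction of ROI).
#' @param cutoff_method passed to [positive_cutoff()].
#' @return list with `tyr`, `glu` ([aid_measure()] results) and `ratio`
#'   (a [tyr_glu_ratio()] result).
#' @export
quantify_cell <- function(image, roi, min_positive_fraction = 0.005,
                          cutoff_method = "otsu") {
  stopifnot(inherits(image, "mc_image"))
  meas <- lapply(c(tyr = "tyr", glu = "glu"), function(ch) {
    img <- get_channel(image, ch)
    floor_bg <- median(img[roi_logical(roi, img)]) +
      3 * mad(img[roi_logical(roi, img)])
    cut <- positive_cutoff(img, roi, method = cutoff_method,
                           control_background = floor_bg)
    aid_measure(img, roi, cut, min_positive_fraction,
                pixel_size = image$pixel_size, channel = ch)
  })
  list(tyr = meas$tyr, glu = meas$glu,
       ratio = tyr_glu_ratio(meas$tyr, meas$glu))
}
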