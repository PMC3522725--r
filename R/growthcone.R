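## Growth-cone domain segmentation and Tyr-MT invasion scoring.
## T  = total cone area (actin + membrane), Pgc = proximal Glu-occupied area,
## ROI = T \ Pgc (peripheral region, A_tyr), invasion = Tyr-positive inside ROI.

#' Total growth-cone area (T)
#'
#' Union of the actin-positive and membrane-positive masks, morphologically
#' closed, hole-filled, largest connected component retained.
#'
#' @param actin,membrane registered intensity matrices.
#' @param cutoffs list with elements `actin` and `membrane` (AFU); computed by
#'   [positive_cutoff()] per channel when omitted.
#' @param closing_radius_px closing disc radius; the default 2 px bridges
#'   sub-resolution gaps (about twice the rendering line-spread sigma) without
#'   sealing the pockets between filopodia into the cone area.
#' @return a [roi_mask()] labelled `"T"` (provenance `"threshold"`).
#' @export
growthcone_total_area <- function(actin, membrane, cutoffs = NULL,
                                  closing_radius_px = 2) {
  stopifnot(identical(dim(actin), dim(membrane)))
  if (is.null(cutoffs))
    cutoffs <- list(actin = positive_cutoff(actin),
                    membrane = positive_cutoff(membrane))
  pos <- (actin > cutoffs$actin) | (membrane > cutoffs$membrane)
  if (!any(pos))
    stop("empty cone: both channels fully sub-threshold")
  m <- mask_largest_component(mask_fill_holes(mask_close(pos, closing_radius_px)))
  roi_mask(m, label = "T", provenance = "threshold")
}

#' Proximal (Glu-occupied) growth-cone area (Pgc)
#'
#' The Glu-positive mask dilated by `dilation_px` (absorbing the transitional
#' band), intersected with T and hole-filled. An empty Glu mask yields an
#' empty Pgc, making the peripheral ROI equal to T.
#'
#' @param glu Glu-MT intensity matrix.
#' @param cutoff Glu positive cutoff (AFU).
#' @param dilation_px dilation radius (default 3).
#' @param total the T mask from [growthcone_total_area()].
#' @return a [roi_mask()] labelled `"Pgc"` (possibly empty).
#' @export
proximal_area <- function(glu, cutoff, dilation_px = 3, total) {
  tm <- roi_logical(total, glu)
  if (!any(tm)) stop("T must be non-empty")
  pos <- glu > cutoff
  m <- mask_dilate(pos, dilation_px) & tm
  m <- mask_fill_holes(m) & tm
  roi_mask(m, label = "Pgc", provenance = "threshold", allow_empty = TRUE)
}

#' Peripheral region of interest (ROI = T \ Pgc)
#'
#' Pixelwise set difference; Pgc is intersected with T first so the partition
#' `area(Pgc) + area(ROI) = area(T)` holds exactly.
#'
#' @param total T mask.
#' @param proximal Pgc mask.
#' @return a [roi_mask()] labelled `"ROI"`.
#' @export
peripheral_roi <- function(total, proximal) {
  tm <- roi_logical(total)
  pm <- roi_logical(proximal) & tm
  m <- tm & !pm
  if (!any(m))
    stop("empty peripheral ROI: Glu-occupied area covers the whole cone, ",
         "invasion not computable")
  roi_mask(m, label = "ROI", provenance = "geometry")
}

#' Percentage of the peripheral ROI invaded by Tyr-MT
#'
#' `100 * |Tyr-positive intersect ROI| / |ROI|`, with the domain areas carried
#' along in um^2.
#'
#' @param tyr Tyr-MT intensity matrix.
#' @param cutoff Tyr positive cutoff (AFU).
#' @param roi the peripheral ROI from [peripheral_roi()].
#' @param pixel_size um/px.
#' @param total,proximal optional T and Pgc masks for area bookkeeping.
#' @return object of class `invasion_result` with fields `percent_invaded`,
#'   `area_T_um2`, `area_Pgc_um2`, `area_ROI_um2`, `invasion_mask`.
#' @export
invasion_percent <- function(tyr, cutoff, roi, pixel_size = 1,
                             total = NULL, proximal = NULL) {
  rm_ <- roi_logical(roi, tyr)
  if (!any(rm_)) stop("empty ROI: invasion undefined")
  inv <- (tyr > cutoff) & rm_
  px2 <- pixel_size^2
  structure(list(
    percent_invaded = 100 * sum(inv) / sum(rm_),
    area_T_um2 = if (is.null(total)) NA_real_ else sum(roi_logical(total)) * px2,
    area_Pgc_um2 = if (is.null(proximal)) NA_real_ else
      sum(roi_logical(proximal)) * px2,
    area_ROI_um2 = sum(rm_) * px2,
    invasion_mask = roi_mask(inv, "invasion", provenance = "threshold",
                             allow_empty = TRUE)),
    class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("<invasion_result> %.2f%% of ROI (%.1f um^2) invaded by Tyr-MT\n",
              x$percent_invaded, x$area_ROI_um2))
  invisible(x)
}

#' Segment a growth-cone image into its quantification domains
#'
#' Runs the full chain on one image: per-channel cutoffs (same method as the
#' cell quantification for consistency), T, Pgc and ROI masks.
#'
#' @param image an [multichannel_image()] with channels `tyr`, `glu`, `actin`,
#'   `memb`.
#' @param dilation_px Glu dilation absorbing the transitional band.
#' @param closing_radius_px closing radius for T.
#' @return list of class `growthcone_domains` with `T`, `Pgc`, `ROI`
#'   ([roi_mask()]s) and the per-channel `cutoffs`.
#' @export
growthcone_domains <- function(image, dilation_px = 3, closing_radius_px = 2) {
  stopifnot(inherits(image, "mc_image"))
  cuts <- lapply(image$channels, positive_cutoff)
  T_ <- growthcone_total_area(get_channel(image, "actin"),
                              get_channel(image, "memb"),
                              cutoffs = list(actin = cuts$actin,
                                             membrane = cuts$memb),
                              closing_radius_px = closing_radius_px)
  Pgc <- proximal_area(get_channel(image, "glu"), cuts$glu, dilation_px, T_)
  ROI <- peripheral_roi(T_, Pgc)
  structure(list(T = T_, Pgc = Pgc, ROI = ROI, cutoffs = cuts),
            class = "growthcone_domains")
}

#' Quantify Tyr-MT invasion for one growth-cone image
#'
#' @param image an [multichannel_image()] (channels `tyr`, `glu`, `actin`,
#'   `memb`).
#' @param ... passed to [growthcone_domains()].
#' @return an [invasion_percent()] result.
#' @export
quantify_growthcone <- function(image, ...) {
  dom <- growthcone_domains(image, ...)
  invasion_percent(get_channel(image, "tyr"), dom$cutoffs$tyr, dom$ROI,
                   pixel_size = image$pixel_size,
                   total = dom$T, proximal = dom$Pgc)
}

#' Simulate a cohort of growth cones and measure their invasion
#'
#' Cohort-level helper mirroring a per-treatment-group design: each cone draws
#' its own true invasion fraction around the group mean (lognormal-like jitter
#' with coefficient of variation `cone_cv`, clamped to `[0, 1]`), is rendered,
#' and quantified with [quantify_growthcone()].
#'
#' @param n number of cones.
#' @param mean_fraction group-mean true invasion fraction.
#' @param params base [growthcone_params()].
#' @param seed integer seed (per-cone sub-seeds derived by [derive_seed()]).
#' @param cone_cv between-cone coefficient of variation of the true fraction.
#' @return data frame with per-cone `true_fraction`, `rendered_fraction`,
#'   `percent_invaded`.
#' @export
simulate_cone_cohort <- function(n, mean_fraction, params = growthcone_params(),
                                 seed = 1L, cone_cv = 0.1) {
  set.seed(as.integer(seed))
  fr <- pmin(pmax(mean_fraction * (1 + rnorm(n, 0, cone_cv)), 0), 1)
  rows <- lapply(seq_len(n), function(i) {
    p <- params
    p$true_invasion_fraction <- fr[i]
    fx <- make_growthcone_image(p, derive_seed(seed, i),
                                fixture_id = sprintf("cone_%03d", i))
    res <- quantify_growthcone(fx$image)
    data.frame(true_fraction = fr[i],
               rendered_fraction = unname(fx$truth$values["rendered_invasion_fraction"]),
               percent_invaded = res$percent_invaded)
  })
  do.call(rbind, rows)
}
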