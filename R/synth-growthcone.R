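#' Parameters for a synthetic growth-cone image
#'
#' A fan-shaped growth cone: actin and a membrane dye fill the whole fan (plus
#' thin filopodia protruding from the leading edge), stable Glu-MT filaments
#' are confined to the central disc (radius `central_radius`), and dynamic
#' Tyr-MT filaments extend from the central domain into the peripheral band to
#' cover a controlled fraction of it.
#'
#' @param image_size c(height, width) px.
#' @param pixel_size um per px.
#' @param fan_angle full opening angle of the fan, degrees.
#' @param central_radius radius of the central (Glu-occupied) domain, px.
#' @param peripheral_width radial width of the peripheral band, px (`> 0`).
#' @param true_invasion_fraction target fraction of the peripheral region
#'   covered by Tyr filaments, in `[0, 1]`.
#' @param filopodia_count number of filopodia beyond the leading edge.
#' @param filament_intensity,background_level,poisson_noise,read_noise_sd,psf_sigma
#'   as in [cell_image_params()].
#' @return validated list of class `growthcone_params`.
#' @export
growthcone_params <- function(image_size = c(128L, 128L),
                              pixel_size = 0.1,
                              fan_angle = 100,
                              central_radius = 24,
                              peripheral_width = 28,
                              true_invasion_fraction = 0.1,
                              filopodia_count = 6L,
                              filament_intensity = 3000,
                              background_level = 60,
                              poisson_noise = TRUE,
                              read_noise_sd = 15,
                              psf_sigma = 1) {
  p <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
            fan_angle = fan_angle, central_radius = central_radius,
            peripheral_width = peripheral_width,
            true_invasion_fraction = true_invasion_fraction,
            filopodia_count = as.integer(filopodia_count),
            filament_intensity = filament_intensity,
            background_level = background_level,
            poisson_noise = isTRUE(poisson_noise),
            read_noise_sd = read_noise_sd, psf_sigma = psf_sigma)
  if (p$peripheral_width <= 0) stop("peripheral_width must be > 0")
  if (p$true_invasion_fraction < 0 || p$true_invasion_fraction > 1)
    stop("true_invasion_fraction must be in [0, 1]")
  if (p$fan_angle <= 0 || p$fan_angle > 180) stop("fan_angle must be in (0, 180]")
  if (p$central_radius <= 0) stop("central_radius must be > 0")
  tot <- p$central_radius + p$peripheral_width
  if (tot + 24 > min(p$image_size)) stop("fan does not fit in the frame")
  class(p) <- "growthcone_params"
  p
}

#' Generate a synthetic growth-cone image with known peripheral invasion
#'
#' Four registered channels (`tyr`, `glu`, `actin`, `membrane`). Glu filaments
#' are rendered only inside the central disc; Tyr filaments additionally invade
#' the peripheral band until the rendered coverage reaches the requested
#' fraction (exact empty/full coverage at the 0 and 1 boundaries). The
#' rendered (not merely requested) invasion fraction is recorded in the
#' ground truth, together with the reference areas.
#'
#' @param params a [growthcone_params()].
#' @param seed integer seed.
#' @param fixture_id id recorded in the ground truth.
#' @return list with `image` ([multichannel_image()]), `truth`
#'   ([ground_truth()]) and reference masks `fan_mask`, `central_mask`,
#'   `peripheral_mask` (logical matrices).
#' @export
make_growthcone_image <- function(params = growthcone_params(), seed = 1L,
                                  fixture_id = "cone") {
  stopifnot(inherits(params, "growthcone_params"))
  set.seed(as.integer(seed))
  p <- params
  h <- p$image_size[1]; w <- p$image_size[2]
  amp <- p$filament_intensity
  apex <- c(h - 12, w / 2)
  half <- p$fan_angle / 2 * pi / 180
  r_tot <- p$central_radius + p$peripheral_width
  ii <- matrix(seq_len(h), h, w); jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- apex[1] - ii; dx <- jj - apex[2]
  rr <- sqrt(dy^2 + dx^2)
  ang <- atan2(dx, dy)                       # 0 = straight up the frame
  in_wedge <- abs(ang) <= half & dy >= -2
  fan <- in_wedge & rr <= r_tot
  central <- fan & rr <= p$central_radius
  band <- fan & rr > p$central_radius

  # filopodia: thin straight protrusions beyond the leading edge
  filo_pts <- NULL
  for (k in seq_len(p$filopodia_count)) {
    a <- runif(1, -half * 0.9, half * 0.9)
    len <- runif(1, 8, 16)
    filo_pts <- rbind(filo_pts, radial_segment(apex, a, r_tot - 2, r_tot + len))
  }
  filo <- stamp_gaussian(h, w, filo_pts, 0.7)
  filo_mask <- filo > 0.4

  # actin + membrane fill the full fan; soft edges come from the blur the
  # Gaussian stamps give filopodia, the fan itself keeps a hard edge
  actin_clean <- 0.55 * amp * fan + 0.9 * amp * filo
  memb_clean <- 0.7 * amp * (fan | filo_mask)

  # Filaments are rendered as saturated binary ribbons (a stamped Gaussian
  # accumulator cut at a fixed level), so the rendered coverage mask is
  # threshold-invariant: any cutoff between background and the filament
  # plateau recovers exactly the rendered pixels.
  ribbon <- function(pts, sigma = 0.8 * p$psf_sigma)
    stamp_gaussian(h, w, pts, sigma) > 0.3

  # central MT bundle: radial Glu (and coextensive Tyr) filaments ending far
  # enough inside the central disc that the ribbon support (~1.6 px past the
  # segment end at the 0.3 cut) cannot leak into the band, while the dilated
  # Pgc mask still reaches approximately the central radius
  r_in <- max(2, p$central_radius - 3.8 * p$psf_sigma)
  central_pts <- NULL
  for (k in seq_len(14L)) {
    a <- runif(1, -half * 0.95, half * 0.95)
    central_pts <- rbind(central_pts, radial_segment(apex, a, runif(1, 2, 8), r_in))
  }
  glu_mask <- ribbon(central_pts, p$psf_sigma)
  tyr_mask <- glu_mask                    # dynamic MTs coexist centrally

  # peripheral invasion: add radial Tyr ribbons until the rendered coverage
  # of the peripheral reference region (band + filopodia) reaches the target
  periph_ref <- band | (filo_mask & !fan)
  ref_px <- sum(periph_ref)
  f_target <- p$true_invasion_fraction
  if (f_target >= 1) {
    # fill the entire cone support (with margin covering downstream closing)
    tyr_mask <- tyr_mask | mask_dilate(fan | filo_mask, 4)
  } else if (f_target > 0) {
    guard <- 0L
    repeat {
      cov <- sum(tyr_mask & periph_ref) / ref_px
      deficit <- f_target - cov
      if (deficit <= 0 || guard > 400L) break
      guard <- guard + 1L
      a <- runif(1, -half * 0.92, half * 0.92)
      # a ribbon covers ~2.5 px per unit length; trim segments to the deficit
      full_len <- p$peripheral_width - 1
      len <- min(full_len, max(2, deficit * ref_px / 2.5))
      r0 <- p$central_radius + 1
      r1 <- min(r0 + len, r_tot - 1)
      tyr_mask <- tyr_mask | ribbon(radial_segment(apex, a, r0, r1))
    }
  }
  tyr_clean <- amp * tyr_mask
  glu_clean <- amp * glu_mask

  rendered <- sum(tyr_mask & periph_ref) / ref_px
  if (f_target >= 1) rendered <- 1
  noisify <- function(sig) apply_noise(sig + p$background_level,
                                       p$poisson_noise, p$read_noise_sd)
  img <- multichannel_image(
    channels = list(tyr = noisify(tyr_clean), glu = noisify(glu_clean),
                    actin = noisify(actin_clean), memb = noisify(memb_clean)),
    pixel_size = p$pixel_size)
  truth <- ground_truth(fixture_id, seed, c(
    requested_invasion_fraction = f_target,
    rendered_invasion_fraction = rendered,
    fan_area_px = sum(fan | filo_mask),
    central_area_px = sum(central),
    peripheral_area_px = ref_px))
  list(image = img, truth = truth, fan_mask = fan | filo_mask,
       central_mask = central, peripheral_mask = periph_ref)
}
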