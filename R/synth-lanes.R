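#' Lane densitometry profile
#'
#' One gel lane reduced to a 1D intensity profile, with the band position
#' declared in the metadata (band windows are declared, not auto-detected, to
#' keep quantification auditable).
#'
#' @param analyte one of `"tubulin"`, `"tau"`, `"actin"`, `"beta3-tubulin"`.
#' @param compartment `"P"` (polymerized), `"S"` (soluble) or `"whole"`.
#' @param profile numeric vector of intensities (AFU vs position), `>= 0`.
#' @param band_window integer c(first, last) profile indices of the band.
#' @return object of class `lane_densitometry`.
#' @export
lane_densitometry <- function(analyte, compartment = c("P", "S", "whole"),
                              profile, band_window) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(analyte), length(analyte) == 1L)
  if (any(profile < 0 | !is.finite(profile))) stop("profile must be finite and >= 0")
  band_window <- as.integer(band_window)
  if (length(band_window) != 2L || band_window[1] > band_window[2] ||
      band_window[1] < 1L || band_window[2] > length(profile))
    stop("band_window must lie inside the profile support")
  structure(list(analyte = analyte, compartment = compartment,
                 profile = profile, band_window = band_window),
            class = "lane_densitometry")
}

#' Parameters for paired polymerized/soluble lane profiles
#'
#' @param true_polymer_fraction named numeric vector, fraction of each analyte
#'   in the polymerized compartment, each in `[0, 1]`. Defaults reflect a
#'   resting cell: ~50% of tubulin polymerized, nearly all tau
#'   microtubule-bound, actin split evenly.
#' @param total_amount total band-integrated signal per analyte (AFU).
#' @param profile_length profile support length (positions).
#' @param band_center band centre position.
#' @param band_width half-width of the band window, px; the band itself is a
#'   Gaussian of sd `band_width / 3` truncated to (and normalized over) the
#'   window, so noise-free P + S band integrals conserve `total_amount` exactly.
#' @param background_offset,background_slope linear background (AFU, AFU/pos).
#' @param noise_sigma additive Gaussian noise sd (AFU).
#' @return validated list of class `lane_params`.
#' @export
lane_params <- function(true_polymer_fraction = c(tubulin = 0.5, tau = 0.95,
                                                  actin = 0.5),
                        total_amount = 20000,
                        profile_length = 200L,
                        band_center = 100L,
                        band_width = 18L,
                        background_offset = 50,
                        background_slope = 0.8,
                        noise_sigma = 8) {
  p <- list(true_polymer_fraction = true_polymer_fraction,
            total_amount = total_amount,
            profile_length = as.integer(profile_length),
            band_center = as.integer(band_center),
            band_width = as.integer(band_width),
            background_offset = background_offset,
            background_slope = background_slope,
            noise_sigma = noise_sigma)
  if (is.null(names(p$true_polymer_fraction)) ||
      any(names(p$true_polymer_fraction) == ""))
    stop("true_polymer_fraction must be a named vector (one entry per analyte)")
  if (any(p$true_polymer_fraction < 0 | p$true_polymer_fraction > 1))
    stop("true_polymer_fraction values must be in [0, 1]")
  if (p$band_center - p$band_width < 1L ||
      p$band_center + p$band_width > p$profile_length)
    stop("band window must lie fully inside the profile support")
  if (p$total_amount <= 0 || p$noise_sigma < 0) stop("invalid amounts/noise")
  class(p) <- "lane_params"
  p
}

#' Generate paired P/S lane profiles with known polymer fractions
#'
#' For each analyte, two profiles (P and S lane) whose background-free band
#' integrals are `total_amount * fraction` and `total_amount * (1 - fraction)`
#' exactly (before noise), on a sloped linear background.
#'
#' @param params a [lane_params()].
#' @param seed integer seed.
#' @param fixture_id id recorded in the ground truth.
#' @return list with `lanes` (list of [lane_densitometry()], P and S per
#'   analyte) and `truth` (a [ground_truth()]).
#' @export
make_lane_profiles <- function(params = lane_params(), seed = 1L,
                               fixture_id = "lanes") {
  stopifnot(inherits(params, "lane_params"))
  set.seed(as.integer(seed))
  p <- params
  L <- p$profile_length
  win <- c(p$band_center - p$band_width, p$band_center + p$band_width)
  x <- seq_len(L)
  gshape <- rep(0, L)
  idx <- win[1]:win[2]
  g <- dnorm(idx, p$band_center, p$band_width / 3)
  gshape[idx] <- g / sum(g)                # unit band integral, fully in window
  bg <- p$background_offset + p$background_slope * (x - 1)
  lanes <- list()
  tv <- c()
  for (an in names(p$true_polymer_fraction)) {
    f <- p$true_polymer_fraction[[an]]
    for (cp in c("P", "S")) {
      amount <- p$total_amount * if (cp == "P") f else 1 - f
      prof <- bg + amount * gshape +
        if (p$noise_sigma > 0) rnorm(L, 0, p$noise_sigma) else 0
      lanes[[paste(an, cp, sep = "_")]] <-
        lane_densitometry(an, cp, pmax(prof, 0), win)
    }
    tv[paste0("true_fraction_", an)] <- f
    tv[paste0("true_p_", an)] <- p$total_amount * f
    tv[paste0("true_s_", an)] <- p$total_amount * (1 - f)
  }
  tv["total_amount"] <- p$total_amount
  list(lanes = lanes, truth = ground_truth(fixture_id, seed, tv))
}
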