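## Lane/band densitometry and the polymerized fraction P/(P+S).

# Rolling-minimum (grayscale opening: erosion then dilation with a flat
# structuring element) of a 1D profile; exact on linear backgrounds away from
# the support edges.
rolling_opening <- function(profile, halfwidth) {
  n <- length(profile)
  win_min <- function(v) vapply(seq_len(n), function(i)
    min(v[max(1, i - halfwidth):min(n, i + halfwidth)]), numeric(1))
  win_max <- function(v) vapply(seq_len(n), function(i)
    max(v[max(1, i - halfwidth):min(n, i + halfwidth)]), numeric(1))
  win_max(win_min(profile))
}

#' Background-subtracted band density
#'
#' Integrates the lane profile over the declared band window after subtracting
#' an estimated background. `"linear_baseline"` (default) fits a straight line
#' through the profile values at the window edges (mean of the 3 outermost
#' positions each side). `"rolling_min"` estimates the background by a
#' rolling-minimum opening on the band flanks and interpolates it linearly
#' beneath the band (the baseline under a band is not observable). Negative
#' integrals are clipped to 0 with a warning.
#'
#' @param lane a [lane_densitometry()].
#' @param background `"linear_baseline"` or `"rolling_min"`.
#' @return background-subtracted band integral (AFU), `>= 0`.
#' @export
band_density <- function(lane, background = c("linear_baseline", "rolling_min")) {
  stopifnot(inherits(lane, "lane_densitometry"))
  background <- match.arg(background)
  prof <- lane$profile
  win <- lane$band_window
  idx <- win[1]:win[2]
  n <- length(prof)
  edge_k <- 3L
  if (background == "linear_baseline") {
    # flank positions strictly outside the band window, so a declared window
    # that truly contains the whole band gives an unbiased (noise-free: exact)
    # baseline; fall back to the window edge when flush with the support
    li <- max(1L, win[1] - edge_k):max(1L, win[1] - 1L)
    ri <- min(n, win[2] + 1L):min(n, win[2] + edge_k)
    x <- c(li, ri); y <- prof[x]
    fit <- lm(y ~ x)
    base <- coef(fit)[1] + coef(fit)[2] * idx
  } else {
    hw <- length(idx)                       # opening wider than the band
    op <- rolling_opening(prof, hw)
    x0 <- max(1L, win[1] - 2L); x1 <- min(n, win[2] + 2L)
    base <- op[x0] + (op[x1] - op[x0]) * (idx - x0) / (x1 - x0)
  }
  dens <- sum(prof[idx] - base)
  if (dens < 0) {
    # warn only for genuinely negative integrals, not floating-point dust
    if (dens < -1e-9 * (sum(abs(prof[idx])) + 1))
      warning("negative band density clipped to 0 (", lane$analyte, " ",
              lane$compartment, ")")
    dens <- 0
  }
  dens
}

#' Percent polymerized from paired P and S densities
#'
#' `100 * P / (P + S)`: the polymerized density divided by the total (sum of
#' soluble and polymerized), as a percentage.
#'
#' @param p,s non-negative band densities (AFU); `p + s` must be positive.
#' @return percentage in `[0, 100]`.
#' @export
percent_polymerized <- function(p, s) {
  stopifnot(is.numeric(p), is.numeric(s), length(p) == length(s))
  if (any(p < 0 | s < 0)) stop("densities must be >= 0")
  if (any(p + s <= 0)) stop("undefined fraction: p + s must be > 0")
  100 * p / (p + s)
}

#' Polymerized-fraction table over analytes
#'
#' Pairs each analyte's P and S lanes, quantifies both bands and computes the
#' percent polymerized. Unpaired or duplicated compartments are errors naming
#' the analyte, never silently dropped.
#'
#' @param lanes list of [lane_densitometry()] objects, exactly one P and one
#'   S lane per analyte.
#' @param background background method passed to [band_density()].
#' @return data frame (class `fraction_table`) with columns `analyte`,
#'   `p_density`, `s_density`, `percent_polymerized`.
#' @export
analyte_fraction_table <- function(lanes,
                                   background = c("linear_baseline", "rolling_min")) {
  background <- match.arg(background)
  stopifnot(is.list(lanes),
            all(vapply(lanes, inherits, logical(1), "lane_densitometry")))
  ans <- unique(vapply(lanes, function(l) l$analyte, character(1)))
  rows <- lapply(ans, function(an) {
    sub <- Filter(function(l) l$analyte == an, lanes)
    cps <- vapply(sub, function(l) l$compartment, character(1))
    for (cp in c("P", "S")) {
      k <- sum(cps == cp)
      if (k == 0L) stop("pairing error: analyte '", an, "' has no ", cp, " lane")
      if (k > 1L) stop("pairing error: analyte '", an, "' has ", k, " ", cp, " lanes")
    }
    pd <- band_density(sub[[which(cps == "P")]], background)
    sd_ <- band_density(sub[[which(cps == "S")]], background)
    data.frame(analyte = an, p_density = pd, s_density = sd_,
               percent_polymerized = percent_polymerized(pd, sd_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fraction_table", "data.frame")
  out
}

#' Normalize a band to its loading control
#'
#' @param band band density (AFU).
#' @param loading loading-control density (AFU, `> 0`).
#' @return dimensionless ratio `band / loading`.
#' @export
normalize_to_loading <- function(band, loading) {
  stopifnot(is.numeric(band), is.numeric(loading))
  if (any(loading <= 0)) stop("loading density must be > 0")
  band / loading
}
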