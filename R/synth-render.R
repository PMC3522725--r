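## Shared rendering primitives for the synthetic-image generators.
## Filaments are smooth random-walk polylines stamped with a Gaussian
## line-spread; this is the simplest model that preserves the area and
## intensity statistics the quantification pipeline measures.

# Accumulate unit Gaussian stamps (sd sigma, truncated at 3 sigma) at the given
# (row, col) points into an H x W intensity matrix. Peak of one isolated stamp
# is ~1; overlapping stamps add.
stamp_gaussian <- function(h, w, pts, sigma = 1) {
  if (is.null(pts) || nrow(pts) == 0L) return(matrix(0, h, w))
  k <- ceiling(3 * sigma)
  off <- expand.grid(di = -k:k, dj = -k:k)
  wts <- exp(-(off$di^2 + off$dj^2) / (2 * sigma^2))
  pi0 <- round(pts[, 1]); pj0 <- round(pts[, 2])
  n <- length(pi0); m <- nrow(off)
  ii <- rep(pi0, each = m) + rep(off$di, n)
  jj <- rep(pj0, each = m) + rep(off$dj, n)
  xx <- rep(wts, n)
  keep <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
  idx <- ii[keep] + (jj[keep] - 1L) * h
  sums <- rowsum(xx[keep], idx, reorder = FALSE)
  acc <- matrix(0, h, w)
  acc[as.integer(rownames(sums))] <- sums
  acc
}

# One smooth random-walk polyline: unit steps, Gaussian heading increments,
# stopped when it leaves `inside` (logical matrix) or reaches `len` steps.
# Returns a matrix of (row, col) points (possibly 0 rows).
walk_polyline <- function(start, len, inside, curvature_sd = 0.15) {
  h <- nrow(inside); w <- ncol(inside)
  pts <- matrix(NA_real_, nrow = len, ncol = 2L)
  i <- start[1]; j <- start[2]
  theta <- runif(1, 0, 2 * pi)
  n <- 0L
  for (s in seq_len(len)) {
    ii <- round(i); jj <- round(j)
    if (ii < 1 || ii > h || jj < 1 || jj > w || !inside[ii, jj]) break
    n <- n + 1L
    pts[n, ] <- c(i, j)
    theta <- theta + rnorm(1, 0, curvature_sd)
    i <- i + sin(theta); j <- j + cos(theta)
  }
  pts[seq_len(n), , drop = FALSE]
}

# Straight radial segment in polar coordinates about an apex, returned as
# (row, col) points at ~unit spacing. Angles in radians, 0 = straight "up"
# (decreasing row index).
radial_segment <- function(apex, angle, r0, r1) {
  rr <- seq(r0, r1, by = 1)
  cbind(apex[1] - rr * cos(angle), apex[2] + rr * sin(angle))
}

# Apply the acquisition noise model: Poisson shot noise on the expected signal
# (gain 1 count/AFU) plus additive Gaussian read noise, clamped to the 16-bit
# range and rounded, matching what a camera would deliver.
apply_noise <- function(clean, poisson_noise = TRUE, read_noise_sd = 15) {
  x <- clean
  if (poisson_noise) x <- rpois(length(x), lambda = pmax(x, 0))
  if (read_noise_sd > 0) x <- x + rnorm(length(x), 0, read_noise_sd)
  m <- matrix(pmin(pmax(round(x), 0), 65535), nrow = nrow(clean))
  m
}

# Elliptical mask centred in an h x w frame with semi-axes (a, b) in px.
ellipse_mask <- function(h, w, a, b, centre = c((h + 1) / 2, (w + 1) / 2)) {
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((ii - centre[1]) / a)^2 + ((jj - centre[2]) / b)^2 <= 1
}
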