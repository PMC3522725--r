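# Independent oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (per-pixel loops, exhaustive sweeps) and
# never call the code paths they check.

# Per-pixel loop sum over a masked image.
loop_integrated_density <- function(image, mask) {
  s <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image)))
    if (mask[i, j]) s <- s + image[i, j]
  s
}

# Exhaustive Otsu: maximize between-class variance over every candidate
# threshold lying between observed integer levels.
brute_otsu <- function(v) {
  lv <- sort(unique(v))
  cand <- (lv[-1] + lv[-length(lv)]) / 2
  best <- -Inf; best_t <- cand[1]
  n <- length(v); mu <- mean(v)
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / n; w1 <- 1 - w0
    crit <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}

# Naive binary dilation with a disc, by scanning every pixel pair.
loop_dilate <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) if (mask[i, j])
    for (di in -r:r) for (dj in -r:r)
      if (di^2 + dj^2 <= r^2) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- TRUE
      }
  out
}

# Solid disc mask.
disc_mask <- function(h, w, ci, cj, r) {
  ii <- matrix(seq_len(h), h, w); jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  (ii - ci)^2 + (jj - cj)^2 <= r^2
}

# Quick noiseless lane pair with a known fraction.
quiet_lane_params <- function(fraction, analyte = "tubulin") {
  lane_params(true_polymer_fraction = stats::setNames(fraction, analyte),
              noise_sigma = 0)
}

# Fast low-noise cell params for tests that only need geometry.
quick_cell_params <- function(...) {
  cell_image_params(image_size = c(96L, 96L), n_filaments = 25L,
                    filament_length_range = c(20L, 60L), ...)
}
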