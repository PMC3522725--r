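#' Parameters for a synthetic two-channel microtubule cell image
#'
#' Describes one imaging regime: a single cell (elliptical mask) whose
#' microtubule network is rendered as curved filaments, with the filament
#' signal split between a Tyr-tubulin and a Glu-tubulin channel by
#' `tyr_glu_partition`, plus a nuclear stain channel. The colchicine-like
#' regime (`below_detection = TRUE`) forces every filament pixel below
#' `background_level + detection_margin`, emulating a depolymerized network
#' that falls under the detection threshold.
#'
#' @param image_size integer c(height, width) in px, each `>= 64`.
#' @param pixel_size um per px (63x confocal default 0.2).
#' @param n_filaments maximum number of filaments rendered.
#' @param filament_length_range c(min, max) filament length in px.
#' @param filament_intensity peak filament intensity in AFU.
#' @param tyr_glu_partition fraction of filament signal in the Tyr channel
#'   (the rest goes to the Glu channel); in `[0, 1]`.
#' @param network_extent target fraction of the cell mask covered by filaments;
#'   filaments are added until this coverage (or `n_filaments`) is reached.
#' @param background_level uniform background in AFU.
#' @param poisson_noise apply Poisson shot noise (gain 1 count/AFU)?
#' @param read_noise_sd Gaussian read-noise sigma in AFU (0 disables).
#' @param psf_sigma Gaussian line-spread sigma of rendered filaments, px.
#' @param n_nuclei number of nuclei rendered in the nucleus channel.
#' @param below_detection colchicine-like regime flag.
#' @param detection_margin AFU margin defining "below detection" (filament
#'   pixels are scaled under it when `below_detection = TRUE`).
#' @return validated parameter list of class `cell_image_params`.
#' @export
cell_image_params <- function(image_size = c(192L, 192L),
                              pixel_size = 0.2,
                              n_filaments = 70L,
                              filament_length_range = c(40L, 140L),
                              filament_intensity = 3000,
                              tyr_glu_partition = 0.5,
                              network_extent = 0.4,
                              background_level = 60,
                              poisson_noise = TRUE,
                              read_noise_sd = 15,
                              psf_sigma = 1,
                              n_nuclei = 1L,
                              below_detection = FALSE,
                              detection_margin = 30) {
  p <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
            n_filaments = as.integer(n_filaments),
            filament_length_range = as.integer(filament_length_range),
            filament_intensity = filament_intensity,
            tyr_glu_partition = tyr_glu_partition,
            network_extent = network_extent,
            background_level = background_level,
            poisson_noise = isTRUE(poisson_noise),
            read_noise_sd = read_noise_sd, psf_sigma = psf_sigma,
            n_nuclei = as.integer(n_nuclei),
            below_detection = isTRUE(below_detection),
            detection_margin = detection_margin)
  if (length(p$image_size) != 2L || any(p$image_size < 64L))
    stop("image_size must be at least 64x64")
  if (p$tyr_glu_partition < 0 || p$tyr_glu_partition > 1)
    stop("tyr_glu_partition must be in [0, 1]")
  if (p$filament_intensity < 0 || p$background_level < 0 || p$read_noise_sd < 0 ||
      p$detection_margin < 0)
    stop("intensities and noise levels must be >= 0")
  if (p$network_extent <= 0 || p$network_extent > 1)
    stop("network_extent must be in (0, 1]")
  if (diff(p$filament_length_range) < 0 || p$filament_length_range[1] < 2)
    stop("invalid filament_length_range")
  class(p) <- "cell_image_params"
  p
}

# Render the noise-free filament field for one cell; returns the clean signal
# matrix (peak ~ filament_intensity), the cell mask and bookkeeping.
render_filament_field <- function(p) {
  h <- p$image_size[1]; w <- p$image_size[2]
  cell <- ellipse_mask(h, w, 0.42 * h, 0.36 * w)
  seed_region <- mask_erode(cell, 4)
  seed_idx <- which(seed_region)
  target_px <- p$network_extent * sum(cell)
  # line density of unit stamps at sigma along a unit-step polyline
  line_gain <- sqrt(2 * pi) * p$psf_sigma
  acc <- matrix(0, h, w)
  nf <- 0L
  repeat {
    if (nf >= p$n_filaments) break
    cover <- sum(acc > 0.3 * line_gain)
    if (cover >= target_px) break
    start_lin <- seed_idx[sample.int(length(seed_idx), 1L)]
    start <- c((start_lin - 1L) %% h + 1L, (start_lin - 1L) %/% h + 1L)
    len <- sample(seq(p$filament_length_range[1], p$filament_length_range[2]), 1L)
    pts <- walk_polyline(start, len, cell)
    if (nrow(pts) < 4L) next
    acc <- acc + stamp_gaussian(h, w, pts, p$psf_sigma)
    nf <- nf + 1L
  }
  clean <- p$filament_intensity * acc / line_gain
  list(clean = clean, cell = cell, n_filaments = nf,
       coverage = sum(acc > 0.3 * line_gain) / sum(cell))
}

#' Generate a synthetic Tyr/Glu microtubule cell image
#'
#' Renders curved filaments inside an elliptical cell mask, splits the signal
#' between Tyr and Glu channels by the partition parameter, adds a nucleus
#' channel and the configured noise, and records the true rendered signals in
#' a [ground_truth()] record. Deterministic for a fixed `(params, seed)` pair.
#'
#' @param params a [cell_image_params()] object.
#' @param seed integer seed.
#' @param fixture_id id recorded in the ground truth.
#' @return list with elements `image` (an [multichannel_image()] with channels
#'   `tyr`, `glu`, `nucleus`), `truth` (a [ground_truth()]) and `cell_mask`
#'   (the generator's cell [roi_mask()], provenance `"manual"`).
#' @export
make_cell_image <- function(params = cell_image_params(), seed = 1L,
                            fixture_id = "cell") {
  stopifnot(inherits(params, "cell_image_params"))
  set.seed(as.integer(seed))
  p <- params
  h <- p$image_size[1]; w <- p$image_size[2]
  fld <- render_filament_field(p)
  clean <- fld$clean
  if (p$below_detection && max(clean) > 0) {
    # force every filament pixel strictly under background + margin
    clean <- clean * (0.9 * p$detection_margin / max(clean))
  }
  tyr_clean <- p$tyr_glu_partition * clean
  glu_clean <- (1 - p$tyr_glu_partition) * clean
  # nucleus channel: broad Gaussian blobs
  nuc_clean <- matrix(0, h, w)
  for (k in seq_len(p$n_nuclei)) {
    ci <- runif(1, 0.35 * h, 0.65 * h); cj <- runif(1, 0.35 * w, 0.65 * w)
    ii <- matrix(seq_len(h), h, w); jj <- matrix(seq_len(w), h, w, byrow = TRUE)
    nuc_clean <- nuc_clean + 2000 * exp(-((ii - ci)^2 + (jj - cj)^2) / (2 * 9^2))
  }
  noisify <- function(sig) apply_noise(sig + p$background_level,
                                       p$poisson_noise, p$read_noise_sd)
  img <- multichannel_image(
    channels = list(tyr = noisify(tyr_clean), glu = noisify(glu_clean),
                    nucleus = noisify(nuc_clean)),
    pixel_size = p$pixel_size)
  net_mask <- clean > 0.3 * p$filament_intensity
  net_area <- sum(mask_largest_component(mask_fill_holes(mask_close(net_mask, 5))))
  truth <- ground_truth(fixture_id, seed, c(
    true_tyr_signal = sum(tyr_clean),
    true_glu_signal = sum(glu_clean),
    true_ratio = if (p$tyr_glu_partition < 1)
      p$tyr_glu_partition / (1 - p$tyr_glu_partition) else Inf,
    tyr_glu_partition = p$tyr_glu_partition,
    coverage_fraction = fld$coverage,
    network_area_px = net_area,
    n_filaments_rendered = fld$n_filaments,
    background_level = p$background_level,
    below_detection = as.numeric(p$below_detection)))
  list(image = img, truth = truth,
       cell_mask = roi_mask(fld$cell, label = fixture_id, provenance = "manual"))
}

#' Generate a synthetic z-stack with a declared plane of maximal network area
#'
#' Each focal plane is rendered independently with a network extent that is
#' strictly maximal at `plane_of_max_area` (1-based index) and falls off
#' linearly with z distance, emulating a cell drifting out of focus.
#'
#' @param n_planes number of focal planes (`>= 1`).
#' @param plane_of_max_area 1-based index of the plane with maximal extent.
#' @param params a [cell_image_params()]; `network_extent` is the extent at
#'   the maximal plane.
#' @param seed integer seed.
#' @param fixture_id id recorded in the ground truth.
#' @return list with `stack` (an [image_stack()]), `truth` and `cell_mask`.
#' @export
make_zstack <- function(n_planes, plane_of_max_area, params = cell_image_params(),
                        seed = 1L, fixture_id = "zstack") {
  stopifnot(inherits(params, "cell_image_params"))
  n_planes <- as.integer(n_planes)
  plane_of_max_area <- as.integer(plane_of_max_area)
  if (n_planes < 1L) stop("n_planes must be >= 1")
  if (plane_of_max_area < 1L || plane_of_max_area > n_planes)
    stop("plane_of_max_area out of range [1, ", n_planes, "]")
  extents <- pmax(0.3, 1 - 0.18 * abs(seq_len(n_planes) - plane_of_max_area)) *
    params$network_extent
  planes <- vector("list", n_planes)
  cm <- NULL
  for (i in seq_len(n_planes)) {
    pi <- params
    pi$network_extent <- extents[i]
    fx <- make_cell_image(pi, derive_seed(seed, i), fixture_id = fixture_id)
    planes[[i]] <- fx$image
    if (i == plane_of_max_area) cm <- fx$cell_mask
  }
  truth <- ground_truth(fixture_id, seed, c(
    n_planes = n_planes, plane_of_max_area = plane_of_max_area,
    stats::setNames(extents, paste0("extent_plane_", seq_len(n_planes)))))
  list(stack = image_stack(planes), truth = truth, cell_mask = cm)
}
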