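#' Parameters for a synthetic in-cell-western plate table
#'
#' Emulates a concentration-response plate: each well's raw fluorescent signal
#' is (per-well cell factor) x (condition effect) x (base signal) plus noise,
#' and the nucleus-stain (Hoechst) column is (per-well cell factor) x (base
#' Hoechst) plus noise, so dividing by Hoechst removes the cell-count
#' variation. Condition effects follow the declared shape.
#'
#' @param concentrations strictly increasing molar concentrations (the vehicle
#'   group at 0 M is always added). Default: `10^seq(-18, -6, 3)` M.
#' @param shape `"bimodal"` (effect only at `peak_locations`), `"sigmoid"`
#'   (Hill curve with midpoint `ec50`), or `"null"` (no effect anywhere).
#' @param peak_locations molar locations of the bimodal peaks.
#' @param effect_size fold-change over vehicle at full effect (`> 0`).
#' @param wells_per_condition replicate wells per condition (`>= 2`).
#' @param cell_count_cv coefficient of variation of the per-well cell factor.
#' @param noise_sigma additive Gaussian noise sd on both columns (AFU).
#' @param base_signal vehicle-level expected raw signal (AFU).
#' @param base_hoechst expected Hoechst signal at cell factor 1 (AFU).
#' @param ec50,hill sigmoid midpoint (M) and Hill coefficient.
#' @return validated list of class `plate_params`.
#' @export
plate_params <- function(concentrations = 10^seq(-18, -6, by = 3),
                         shape = c("bimodal", "sigmoid", "null"),
                         peak_locations = c(1e-15, 1e-9),
                         effect_size = 1.5,
                         wells_per_condition = 9L,
                         cell_count_cv = 0.2,
                         noise_sigma = 30,
                         base_signal = 1000,
                         base_hoechst = 500,
                         ec50 = 1e-12,
                         hill = 1) {
  shape <- match.arg(shape)
  p <- list(concentrations = concentrations, shape = shape,
            peak_locations = peak_locations, effect_size = effect_size,
            wells_per_condition = as.integer(wells_per_condition),
            cell_count_cv = cell_count_cv, noise_sigma = noise_sigma,
            base_signal = base_signal, base_hoechst = base_hoechst,
            ec50 = ec50, hill = hill)
  if (any(diff(p$concentrations) <= 0) || any(p$concentrations <= 0))
    stop("concentrations must be positive and strictly increasing")
  if (p$wells_per_condition < 2L) stop("wells_per_condition must be >= 2")
  if (p$effect_size <= 0) stop("effect_size must be > 0")
  if (p$cell_count_cv < 0 || p$noise_sigma < 0) stop("invalid variation parameters")
  if (shape == "bimodal" &&
      !all(vapply(p$peak_locations, function(pk)
        any(abs(log10(p$concentrations) - log10(pk)) < 0.01), logical(1))))
    stop("every bimodal peak must coincide with a tested concentration")
  class(p) <- "plate_params"
  p
}

condition_effect <- function(p, conc) {
  switch(p$shape,
         null = rep(1, length(conc)),
         bimodal = ifelse(vapply(conc, function(cc)
           cc > 0 && any(abs(log10(cc) - log10(p$peak_locations)) < 0.01),
           logical(1)), p$effect_size, 1),
         sigmoid = ifelse(conc > 0,
                          1 + (p$effect_size - 1) / (1 + (p$ec50 / conc)^p$hill),
                          1))
}

#' Generate a synthetic in-cell-western plate table
#'
#' @param params a [plate_params()].
#' @param seed integer seed.
#' @param fixture_id id recorded in the ground truth.
#' @return list with `plate` (a `plate_table` data frame: `well`, `condition`,
#'   `concentration_M`, `signal_afu`, `hoechst_afu`) and `truth`
#'   (a [ground_truth()] recording the per-concentration true effects).
#' @export
make_plate_table <- function(params = plate_params(), seed = 1L,
                             fixture_id = "plate") {
  stopifnot(inherits(params, "plate_params"))
  set.seed(as.integer(seed))
  p <- params
  conc <- c(0, p$concentrations)
  cond <- c("vehicle", formatC(p$concentrations, format = "e", digits = 0))
  eff <- condition_effect(p, conc)
  nw <- p$wells_per_condition
  rows <- vector("list", length(conc))
  for (g in seq_along(conc)) {
    cellf <- pmax(0.1, 1 + rnorm(nw, 0, p$cell_count_cv))
    sig <- cellf * p$base_signal * eff[g] +
      if (p$noise_sigma > 0) rnorm(nw, 0, p$noise_sigma) else 0
    hoe <- cellf * p$base_hoechst +
      if (p$noise_sigma > 0) rnorm(nw, 0, p$noise_sigma) else 0
    rows[[g]] <- data.frame(
      well = sprintf("%s%02d", LETTERS[g], seq_len(nw)),
      condition = cond[g], concentration_M = conc[g],
      signal_afu = pmax(sig, 0), hoechst_afu = hoe,
      stringsAsFactors = FALSE)
  }
  plate <- do.call(rbind, rows)
  class(plate) <- c("plate_table", "data.frame")
  shape_code <- match(p$shape, c("null", "sigmoid", "bimodal")) - 1
  tv <- c(shape_code = shape_code, effect_size = p$effect_size,
          stats::setNames(eff, paste0("effect_", cond)))
  list(plate = plate, truth = ground_truth(fixture_id, seed, tv))
}
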