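## End-to-end runs: simulate -> quantify -> report, with a flat plain-text
## configuration, structured logging and CSV outputs. All randomness derives
## from the single master seed via derive_seed(), so identical (config, seed)
## runs are byte-identical.

run_config_defaults <- function() list(
  seed = 1, out_dir = "mtquant_run", in_dir = NA_character_,
  n_cells = 2, cell_partition = 0.5, cell_below_detection = 0,
  n_cones = 2, cone_fraction = 0.15,
  n_lane_sets = 1, n_plates = 1, plate_shape = "bimodal",
  cutoff_method = "otsu", min_positive_fraction = 0.005,
  closing_radius_px = 5, dilation_px = 3, alpha = 0.05,
  posthoc = "dunnett")

#' Build a validated run configuration
#'
#' Flat key/value configuration driving [run_simulate()] and [run_quantify()].
#' Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see [run_config_defaults] source for
#'   the full key list: fixture counts, generator knobs, cutoff method,
#'   morphology radii, `min_positive_fraction`, `alpha`, `posthoc`, `seed`,
#'   `out_dir`, `in_dir`).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$closing_radius_px < 0 || cfg$dilation_px < 0)
    stop("radii must be >= 0")
  if (!cfg$cutoff_method %in% c("otsu", "background_k_mad"))
    stop("cutoff_method must be otsu or background_k_mad")
  if (!cfg$posthoc %in% c("dunnett", "snk")) stop("posthoc must be dunnett or snk")
  if (!cfg$plate_shape %in% c("bimodal", "sigmoid", "null"))
    stop("plate_shape must be bimodal, sigmoid or null")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a plain-text key/value file
#'
#' One `key: value` pair per line; `#` starts a comment; numeric values are
#' parsed as numbers. The format round-trips losslessly through
#' [write_run_config()].
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  if (any(vapply(kv, length, integer(1)) != 3L))
    stop("malformed config line(s): ",
         paste(lines[vapply(kv, length, integer(1)) != 3L], collapse = "; "))
  vals <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 2)
  do.call(run_config, vals)
}

#' Write a run configuration as a plain-text key/value file
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keys <- names(config)[!vapply(config, function(v) is.na(v[1]), logical(1))]
  fmt <- vapply(keys, function(k) {
    v <- config[[k]]
    sprintf("%s: %s", k, if (is.numeric(v)) format(v, digits = 15) else as.character(v))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

config_hash <- function(config) {
  # FNV-1a 32-bit over the canonical serialized config text
  txt <- paste(vapply(names(config), function(k)
    sprintf("%s=%s", k, format(config[[k]], digits = 15)), character(1)),
    collapse = ";")
  # pure double arithmetic: R's bitwXor overflows above 2^31 - 1
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

log_stage <- function(stage, fixture, msg) {
  message(sprintf("[%s] %s: %s", stage, fixture, msg))
}

#' Simulate the full fixture set for a run
#'
#' Writes cell images, growth-cone images (16-bit grayscale TIFF, one file per
#' channel, `<fixture>_<channel>.tif`), lane profiles and plate tables (CSV),
#' plus `ground_truth.csv` and a `manifest.csv` naming every fixture.
#' Deterministic for a fixed master seed.
#'
#' @param config a [run_config()].
#' @return the fixture directory path, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$out_dir, "fixtures")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  manifest <- list(); truths <- list()
  ctr <- 0L
  add <- function(id, type, files) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      fixture_id = id, type = type, files = paste(files, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_cells)) {
    ctr <- ctr + 1L
    id <- sprintf("cell_%03d", i)
    p <- cell_image_params(tyr_glu_partition = config$cell_partition,
                           below_detection = config$cell_below_detection > 0)
    fx <- make_cell_image(p, derive_seed(config$seed, ctr), id)
    files <- c()
    for (ch in names(fx$image$channels)) {
      f <- file.path(dir, sprintf("%s_%s.tif", id, ch))
      write_gray_tiff(fx$image$channels[[ch]], f)
      files <- c(files, basename(f))
    }
    f <- file.path(dir, sprintf("%s_mask.tif", id))
    write_gray_tiff(fx$cell_mask$mask * 65535, f)
    files <- c(files, basename(f))
    truths[[id]] <- fx$truth
    add(id, "cell", files)
    log_stage("simulate", id, "written")
  }
  for (i in seq_len(config$n_cones)) {
    ctr <- ctr + 1L
    id <- sprintf("cone_%03d", i)
    p <- growthcone_params(true_invasion_fraction = config$cone_fraction)
    fx <- make_growthcone_image(p, derive_seed(config$seed, ctr), id)
    files <- c()
    for (ch in names(fx$image$channels)) {
      f <- file.path(dir, sprintf("%s_%s.tif", id, ch))
      write_gray_tiff(fx$image$channels[[ch]], f)
      files <- c(files, basename(f))
    }
    truths[[id]] <- fx$truth
    add(id, "cone", files)
    log_stage("simulate", id, "written")
  }
  for (i in seq_len(config$n_lane_sets)) {
    ctr <- ctr + 1L
    id <- sprintf("lanes_%03d", i)
    fx <- make_lane_profiles(lane_params(), derive_seed(config$seed, ctr), id)
    rows <- do.call(rbind, lapply(fx$lanes, function(l) data.frame(
      analyte = l$analyte, compartment = l$compartment,
      position = seq_along(l$profile), intensity_afu = l$profile,
      band_start = l$band_window[1], band_end = l$band_window[2],
      stringsAsFactors = FALSE)))
    f <- file.path(dir, paste0(id, ".csv"))
    write.csv(rows, f, row.names = FALSE)
    truths[[id]] <- fx$truth
    add(id, "lanes", basename(f))
    log_stage("simulate", id, "written")
  }
  for (i in seq_len(config$n_plates)) {
    ctr <- ctr + 1L
    id <- sprintf("plate_%03d", i)
    fx <- make_plate_table(plate_params(shape = config$plate_shape),
                           derive_seed(config$seed, ctr), id)
    f <- file.path(dir, paste0(id, ".csv"))
    write.csv(fx$plate, f, row.names = FALSE)
    truths[[id]] <- fx$truth
    add(id, "plate", basename(f))
    log_stage("simulate", id, "written")
  }
  mdf <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(fixture_id = character(), type = character(),
               files = character(), stringsAsFactors = FALSE)
  write.csv(mdf, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (length(truths)) write_ground_truth(truths, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

read_lane_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, paste(df$analyte, df$compartment)), function(d) {
    d <- d[order(d$position), ]
    lane_densitometry(d$analyte[1], d$compartment[1], d$intensity_afu,
                      c(d$band_start[1], d$band_end[1]))
  })
}

quantify_one <- function(row, dir, config) {
  files <- strsplit(row$files, ";")[[1]]
  id <- row$fixture_id
  if (row$type == "cell") {
    chs <- lapply(c(tyr = "tyr", glu = "glu", nucleus = "nucleus"), function(ch)
      read_gray_tiff(file.path(dir, sprintf("%s_%s.tif", id, ch))))
    mask <- read_gray_tiff(file.path(dir, sprintf("%s_mask.tif", id))) > 0
    img <- multichannel_image(chs, pixel_size = 0.2)
    roi <- roi_mask(mask, label = id, provenance = "manual")
    qc <- quantify_cell(img, roi, config$min_positive_fraction,
                        config$cutoff_method)
    net <- mt_network_area(chs$tyr + chs$glu,
                           positive_cutoff(chs$tyr + chs$glu, roi),
                           config$closing_radius_px, pixel_size = 0.2)
    rows <- data.frame(
      fixture_id = id, roi = id,
      channel = c("tyr", "glu", "tyr/glu", "tyr+glu"),
      metric = c("aid", "aid", "ratio", "network_area_um2"),
      value = c(qc$tyr$aid, qc$glu$aid,
                if (qc$ratio$defined) qc$ratio$ratio else NA_real_,
                net$area_um2),
      unit = c("AFU", "AFU", "dimensionless", "um2"),
      stringsAsFactors = FALSE)
    if (!qc$ratio$defined)
      log_stage("quantify", id, "ratio undefined (below detection); excluded")
    return(rows)
  }
  if (row$type == "cone") {
    chs <- lapply(c(tyr = "tyr", glu = "glu", actin = "actin", memb = "memb"),
                  function(ch)
                    read_gray_tiff(file.path(dir, sprintf("%s_%s.tif", id, ch))))
    img <- multichannel_image(chs, pixel_size = 0.1)
    res <- quantify_growthcone(img, dilation_px = config$dilation_px)
    return(data.frame(
      fixture_id = id, roi = "ROI",
      channel = c("tyr", "all", "glu", "all"),
      metric = c("percent_invaded", "area_T_um2", "area_Pgc_um2", "area_ROI_um2"),
      value = c(res$percent_invaded, res$area_T_um2, res$area_Pgc_um2,
                res$area_ROI_um2),
      unit = c("percent", "um2", "um2", "um2"), stringsAsFactors = FALSE))
  }
  if (row$type == "lanes") {
    lanes <- read_lane_csv(file.path(dir, files[1]))
    tab <- analyte_fraction_table(lanes)
    return(data.frame(
      fixture_id = id, roi = tab$analyte, channel = "densitometry",
      metric = "percent_polymerized", value = tab$percent_polymerized,
      unit = "percent", stringsAsFactors = FALSE))
  }
  if (row$type == "plate") {
    plate <- read.csv(file.path(dir, files[1]), stringsAsFactors = FALSE)
    drs <- dose_response_summary(plate, alpha = config$alpha)
    rows <- data.frame(
      fixture_id = id, roi = drs$table$condition, channel = "icw",
      metric = "normalized_fau_mean", value = drs$table$mean,
      unit = "FAU/Hoechst", stringsAsFactors = FALSE)
    attr(rows, "drs") <- drs
    return(rows)
  }
  stop("unknown fixture type: ", row$type)
}

#' Quantify a simulated (or externally supplied) fixture directory
#'
#' Dispatches every manifest entry to the matching quantification stage (cell
#' images -> AID/ratio/network area; growth cones -> invasion; lanes ->
#' polymer fractions; plates -> dose-response summary) and writes
#' `measurements.csv` (long format), `group_summary.csv`, `tests.csv` and a
#' human-readable `report.txt` with a provenance block (config hash, seed,
#' package version). Unreadable fixtures are reported as failures and the run
#' continues.
#'
#' @param config a [run_config()]; fixtures are read from `in_dir` if set,
#'   else from `out_dir/fixtures`.
#' @return list with `measurements`, `group_summary`, `tests`, `failures`,
#'   `report_path` (class `run_report`).
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- if (!is.na(config$in_dir)) config$in_dir
         else file.path(config$out_dir, "fixtures")
  man_path <- file.path(dir, "manifest.csv")
  out_dir <- file.path(config$out_dir, "results")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  empty <- data.frame(fixture_id = character(), roi = character(),
                      channel = character(), metric = character(),
                      value = numeric(), unit = character(),
                      stringsAsFactors = FALSE)
  if (!file.exists(man_path)) {
    warning("no manifest at ", man_path, "; writing an empty report")
    man <- data.frame(fixture_id = character(), type = character(),
                      files = character(), stringsAsFactors = FALSE)
  } else man <- read.csv(man_path, stringsAsFactors = FALSE)
  meas <- list(); failures <- character(); drs_list <- list()
  for (r in seq_len(nrow(man))) {
    row <- man[r, ]
    res <- tryCatch(quantify_one(row, dir, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", row$fixture_id, conditionMessage(res)))
      log_stage("quantify", row$fixture_id, paste("FAILED:", conditionMessage(res)))
      next
    }
    if (!is.null(attr(res, "drs"))) drs_list[[row$fixture_id]] <- attr(res, "drs")
    meas[[length(meas) + 1L]] <- as.data.frame(res)
    log_stage("quantify", row$fixture_id, "quantified")
  }
  measurements <- if (length(meas)) do.call(rbind, meas) else empty
  group_summary <- if (length(drs_list)) do.call(rbind, lapply(
    names(drs_list), function(id) cbind(fixture_id = id, drs_list[[id]]$table,
                                        shape = drs_list[[id]]$shape))) else
    data.frame()
  tests <- if (length(drs_list)) do.call(rbind, lapply(
    names(drs_list), function(id) cbind(fixture_id = id,
                                        drs_list[[id]]$test$comparisons))) else
    data.frame()
  write.csv(measurements, file.path(out_dir, "measurements.csv"), row.names = FALSE)
  write.csv(group_summary, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
  report_path <- write_run_report(config, measurements, group_summary, tests,
                                  failures, out_dir)
  structure(list(measurements = measurements, group_summary = group_summary,
                 tests = tests, failures = failures, report_path = report_path),
            class = "run_report")
}

write_run_report <- function(config, measurements, group_summary, tests,
                             failures, out_dir) {
  path <- file.path(out_dir, "report.txt")
  lines <- c(
    "mtquant run report",
    "==================",
    "",
    "[provenance]",
    sprintf("package_version: %s", as.character(utils::packageVersion("mtquant"))),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("master_seed: %s", format(config$seed)),
    vapply(names(config), function(k)
      sprintf("config %s: %s", k, format(config[[k]], digits = 15)), character(1)),
    "",
    sprintf("[measurements] %d rows over %d fixture(s)",
            nrow(measurements), length(unique(measurements$fixture_id))))
  if (nrow(measurements)) {
    lines <- c(lines, utils::capture.output(print(measurements, digits = 5)))
  }
  if (is.data.frame(group_summary) && nrow(group_summary)) {
    lines <- c(lines, "", "[dose-response]",
               utils::capture.output(print(group_summary, digits = 5)))
  }
  if (length(failures)) {
    lines <- c(lines, "", "[failures]", failures)
  } else lines <- c(lines, "", "[failures] none")
  writeLines(lines, path)
  path
}
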