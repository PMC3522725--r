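test_that("band density: rectangle arithmetic and exact linear-baseline cancellation", {
  prof <- rep(0, 60); prof[20:24] <- 10
  lane <- lane_densitometry("tubulin", "P", prof, c(15, 30))
  expect_equal(band_density(lane), 50)
  # pure linear baseline, no band -> 0 for both methods
  lin <- 5 + 0.7 * (0:99)
  lane_lin <- lane_densitometry("tubulin", "P", lin, c(40, 60))
  expect_equal(band_density(lane_lin), 0, tolerance = 1e-10)
  expect_equal(band_density(lane_lin, "rolling_min"), 0, tolerance = 1e-10)
  expect_error(lane_densitometry("tubulin", "P", prof, c(50, 70)), "support")
})

test_that("Gaussian band on sloped background recovered within 5%; methods agree within 1%", {
  fx <- make_lane_profiles(lane_params(true_polymer_fraction = c(tubulin = 0.6)),
                           seed = 14)
  for (cp in c("P", "S")) {
    lane <- fx$lanes[[paste0("tubulin_", cp)]]
    truth <- fx$truth$values[[if (cp == "P") "true_p_tubulin" else "true_s_tubulin"]]
    d_lin <- band_density(lane, "linear_baseline")
    expect_lt(abs(d_lin - truth) / truth, 0.05)
  }
  # background-method invariance on the noise-free linear-background fixture
  fx0 <- make_lane_profiles(quiet_lane_params(0.6), seed = 14)
  for (lane in fx0$lanes) {
    a <- band_density(lane, "linear_baseline")
    b <- band_density(lane, "rolling_min")
    expect_lt(abs(a - b) / a, 0.01)
  }
})

test_that("percent_polymerized: symmetry, boundaries, complementarity, errors", {
  expect_equal(percent_polymerized(3, 3), 50)
  expect_equal(percent_polymerized(5, 0), 100)
  expect_error(percent_polymerized(0, 0), "undefined")
  expect_error(percent_polymerized(-1, 2), ">= 0")
  set.seed(4)
  for (rep in 1:25) {
    p <- runif(1, 0, 100); s <- runif(1, 0, 100)
    if (p + s == 0) next
    expect_equal(percent_polymerized(p, s) + percent_polymerized(s, p), 100)
  }
})

test_that("analyte_fraction_table pairs lanes and reports pairing errors by name", {
  fx <- make_lane_profiles(quiet_lane_params(0.8), seed = 2)
  tab <- analyte_fraction_table(fx$lanes)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$percent_polymerized, 80, tolerance = 1e-9)
  expect_error(analyte_fraction_table(fx$lanes["tubulin_P"]),
               "pairing error.*tubulin.*no S")
  expect_error(analyte_fraction_table(c(fx$lanes, fx$lanes["tubulin_P"])),
               "pairing error.*2 P")
})

test_that("tau fixture: nearly all tau rides with the polymerized fraction", {
  fx <- make_lane_profiles(lane_params(), seed = 8)   # default tau fraction 0.95
  tab <- analyte_fraction_table(fx$lanes)
  expect_gt(tab$percent_polymerized[tab$analyte == "tau"], 90)
})

test_that("three-analyte recovery within 3 points of truth", {
  fr <- c(tubulin = 0.5, tau = 0.95, actin = 0.5)
  fx <- make_lane_profiles(lane_params(true_polymer_fraction = fr), seed = 19)
  tab <- analyte_fraction_table(fx$lanes)
  expect_true(all(abs(tab$percent_polymerized - 100 * fr[tab$analyte]) < 3))
})

test_that("normalize_to_loading: arithmetic, scale invariance, error on bad loading", {
  expect_equal(normalize_to_loading(120, 60), 2)
  expect_equal(normalize_to_loading(120 * 3.3, 60 * 3.3), 2)
  expect_error(normalize_to_loading(1, 0), "> 0")
})

test_that("loading-normalized expression ratio 1.8 recovered over 20 replicates", {
  # control blot: beta3 at 0.5 x total, actin loading at 0.5 x total -> 1.0;
  # treated blot: beta3 at 0.9 x total, same loading -> 1.8-fold over control
  est <- vapply(1:20, function(s) {
    ctl <- make_lane_profiles(
      lane_params(true_polymer_fraction = c(`beta3-tubulin` = 0.5, actin = 0.5)),
      seed = s)
    trt <- make_lane_profiles(
      lane_params(true_polymer_fraction = c(`beta3-tubulin` = 0.9, actin = 0.5)),
      seed = s + 1000)
    nc <- normalize_to_loading(band_density(ctl$lanes[["beta3-tubulin_P"]]),
                               band_density(ctl$lanes[["actin_P"]]))
    nt <- normalize_to_loading(band_density(trt$lanes[["beta3-tubulin_P"]]),
                               band_density(trt$lanes[["actin_P"]]))
    nt / nc
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.8), 0.1)
})
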