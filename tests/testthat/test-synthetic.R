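test_that("generators are deterministic: same (params, seed) -> identical fixtures", {
  p <- quick_cell_params()
  a <- make_cell_image(p, seed = 77)
  b <- make_cell_image(p, seed = 77)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$values, b$truth$values)
  gp <- growthcone_params(true_invasion_fraction = 0.2)
  expect_identical(make_growthcone_image(gp, 5)$image$channels,
                   make_growthcone_image(gp, 5)$image$channels)
  expect_identical(make_lane_profiles(lane_params(), 9)$lanes,
                   make_lane_profiles(lane_params(), 9)$lanes)
  expect_identical(make_plate_table(plate_params(), 4)$plate,
                   make_plate_table(plate_params(), 4)$plate)
  # and a different seed actually changes the noise realization
  expect_false(identical(make_cell_image(p, 77)$image$channels$tyr,
                         make_cell_image(p, 78)$image$channels$tyr))
})

test_that("parameter invariants are enforced", {
  expect_error(cell_image_params(image_size = c(32, 128)), "64x64")
  expect_error(cell_image_params(tyr_glu_partition = 1.2), "partition")
  expect_error(cell_image_params(filament_intensity = -5), ">= 0")
  expect_error(growthcone_params(peripheral_width = 0), "peripheral_width")
  expect_error(growthcone_params(true_invasion_fraction = -0.1), "invasion")
  expect_error(lane_params(true_polymer_fraction = c(tubulin = 1.4)), "\\[0, 1\\]")
  expect_error(lane_params(band_center = 5, band_width = 18), "support")
  expect_error(plate_params(concentrations = c(1e-9, 1e-9)), "increasing")
  expect_error(plate_params(wells_per_condition = 1), ">= 2")
  expect_error(plate_params(effect_size = 0), "effect_size")
  expect_error(make_zstack(7, 9), "out of range")
  expect_error(make_zstack(0, 0), ">= 1")
})

test_that("partition 0.5 without noise gives equal true channel signals", {
  p <- quick_cell_params(tyr_glu_partition = 0.5, poisson_noise = FALSE,
                         read_noise_sd = 0)
  fx <- make_cell_image(p, seed = 3)
  expect_equal(fx$truth$values[["true_tyr_signal"]],
               fx$truth$values[["true_glu_signal"]])
  expect_identical(fx$image$channels$tyr, fx$image$channels$glu)
})

test_that("below-detection regime keeps every filament pixel under the margin", {
  p <- quick_cell_params(below_detection = TRUE, poisson_noise = FALSE,
                         read_noise_sd = 0)
  fx <- make_cell_image(p, seed = 11)
  for (ch in c("tyr", "glu"))
    expect_lt(max(fx$image$channels[[ch]]),
              p$background_level + p$detection_margin)
})

test_that("growth-cone geometry: Glu never enters the peripheral band; boundaries exact", {
  fx0 <- make_growthcone_image(growthcone_params(true_invasion_fraction = 0), 21)
  glu_pos <- fx0$image$channels$glu > 1000
  expect_false(any(glu_pos & fx0$peripheral_mask))
  tyr_pos <- fx0$image$channels$tyr > 1000
  expect_false(any(tyr_pos & fx0$peripheral_mask))   # empty invasion
  fx1 <- make_growthcone_image(growthcone_params(true_invasion_fraction = 1), 21)
  expect_true(all(fx1$image$channels$tyr[fx1$peripheral_mask] > 1000))
  expect_equal(fx1$truth$values[["rendered_invasion_fraction"]], 1)
})

test_that("lane conservation: noise-free P + S band integrals equal total_amount", {
  for (f in c(0.25, 0.6, 0.95)) {
    fx <- make_lane_profiles(quiet_lane_params(f), seed = 2)
    tot <- sum(vapply(fx$lanes, band_density, numeric(1)))
    expect_equal(tot, 20000, tolerance = 1e-6)
  }
})

test_that("plate generator: null shape has equal effects; cv=0 noiseless plates are constant", {
  fx <- make_plate_table(plate_params(shape = "null"), 1)
  eff <- fx$truth$values[grep("^effect_(vehicle|[0-9])", names(fx$truth$values))]
  expect_true(all(eff == 1))
  fx2 <- make_plate_table(plate_params(shape = "sigmoid", cell_count_cv = 0,
                                       noise_sigma = 0), 1)
  norm <- icw_normalize(fx2$plate)
  spread <- tapply(norm$normalized_fau, norm$condition, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("z-stack: network extent is strictly maximal at the declared plane", {
  zs <- make_zstack(5, 3, quick_cell_params(), seed = 6)
  ext <- zs$truth$values[grep("^extent_plane_", names(zs$truth$values))]
  expect_equal(unname(which.max(ext)), 3)
  expect_true(all(ext[3] > ext[-3]))
  one <- make_zstack(1, 1, quick_cell_params(), seed = 6)
  expect_equal(select_focal_plane(one$stack, "glu"), 1L)
})

test_that("ground truth round-trips through CSV unchanged", {
  gt1 <- ground_truth("fx_a", 42L, c(alpha = 1 / 3, beta = 2.5e-17, n = 7))
  gt2 <- ground_truth("fx_b", 7L, c(gamma = pi))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(list(gt1, gt2), f)
  back <- read_ground_truth(f)
  expect_identical(back$fx_a$values, gt1$values)
  expect_identical(back$fx_b$values, gt2$values)
  expect_identical(back$fx_a$seed, 42L)
})

test_that("derived sub-seeds are distinct, reproducible and in integer range", {
  s <- vapply(0:500, function(k) derive_seed(123456, k), integer(1))
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_identical(derive_seed(99, 5), derive_seed(99, 5))
})
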