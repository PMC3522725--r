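test_that("total cone area: union identity and subset behaviour", {
  d <- disc_mask(64, 64, 32, 32, 15)
  memb <- matrix(10, 64, 64); memb[d] <- 500
  actin_empty <- matrix(10, 64, 64)
  T1 <- growthcone_total_area(actin_empty, memb,
                              cutoffs = list(actin = 1000, membrane = 100),
                              closing_radius_px = 0)
  expect_identical(T1$mask, d)
  # actin strictly inside the membrane mask adds nothing
  actin_sub <- matrix(10, 64, 64); actin_sub[disc_mask(64, 64, 32, 32, 8)] <- 500
  T2 <- growthcone_total_area(actin_sub, memb,
                              cutoffs = list(actin = 100, membrane = 100),
                              closing_radius_px = 0)
  expect_identical(T2$mask, d)
  expect_error(growthcone_total_area(actin_empty, actin_empty,
                                     cutoffs = list(actin = 1e5, membrane = 1e5)),
               "empty cone")
})

test_that("proximal area and peripheral ROI: boundary cases and exact partition", {
  d <- disc_mask(48, 48, 24, 24, 14)
  T_ <- roi_mask(d, "T", provenance = "threshold")
  glu0 <- matrix(0, 48, 48)
  Pgc0 <- proximal_area(glu0, 10, 3, T_)
  expect_false(any(Pgc0$mask))
  roi0 <- peripheral_roi(T_, Pgc0)
  expect_identical(roi0$mask, d)                       # no Glu -> ROI = T
  gluAll <- matrix(100, 48, 48)
  PgcAll <- proximal_area(gluAll, 10, 0, T_)
  expect_error(peripheral_roi(T_, PgcAll), "whole cone")  # Glu covers all of T
})

test_that("peripheral ROI equals the brute-force per-pixel difference; partition holds", {
  set.seed(9)
  for (rep in 1:8) {
    tm <- disc_mask(40, 40, 20, 20, sample(10:16, 1))
    pm <- matrix(runif(1600) < 0.3, 40, 40)   # arbitrary, not nested
    T_ <- roi_mask(tm, "T", provenance = "geometry")
    P_ <- roi_mask(pm, "Pgc", provenance = "geometry", allow_empty = TRUE)
    roi <- peripheral_roi(T_, P_)
    brute <- matrix(FALSE, 40, 40)
    for (i in 1:40) for (j in 1:40) brute[i, j] <- tm[i, j] && !pm[i, j]
    expect_identical(roi$mask, brute)
    expect_equal(sum(pm & tm) + sum(roi$mask), sum(tm))  # exact partition
  }
})

test_that("invasion percent: arithmetic and sub-threshold zero", {
  roi <- roi_mask(disc_mask(30, 30, 15, 15, 8), "ROI", provenance = "geometry")
  tyr <- matrix(0, 30, 30)
  inside <- which(roi$mask, arr.ind = TRUE)
  k <- round(sum(roi$mask) / 5)
  tyr[inside[seq_len(k), ]] <- 100
  res <- invasion_percent(tyr, 50, roi)
  expect_equal(res$percent_invaded, 100 * k / sum(roi$mask))
  expect_equal(invasion_percent(matrix(0, 30, 30), 50, roi)$percent_invaded, 0)
  expect_error(invasion_percent(tyr, 50,
                                roi_mask(matrix(FALSE, 30, 30), "ROI",
                                         provenance = "geometry",
                                         allow_empty = TRUE)),
               "empty ROI")
})

test_that("segmentation recovers the rendered fan and central-disc areas within 5%", {
  fx <- make_growthcone_image(growthcone_params(true_invasion_fraction = 0.15),
                              seed = 13)
  dom <- growthcone_domains(fx$image)
  fan_true <- sum(fx$fan_mask)
  expect_lt(abs(sum(dom$T$mask) - fan_true) / fan_true, 0.05)
  cen_true <- sum(fx$central_mask)
  expect_lt(abs(sum(dom$Pgc$mask) - cen_true) / cen_true, 0.05)
  # partition identity on the real segmentation
  expect_equal(sum(dom$Pgc$mask) + sum(dom$ROI$mask), sum(dom$T$mask))
})

test_that("raising the Tyr cutoff never increases percent invaded", {
  fx <- make_growthcone_image(growthcone_params(true_invasion_fraction = 0.3),
                              seed = 17)
  dom <- growthcone_domains(fx$image)
  tyr <- get_channel(fx$image, "tyr")
  cuts <- seq(dom$cutoffs$tyr * 0.5, dom$cutoffs$tyr * 2, length.out = 8)
  pct <- vapply(cuts, function(ct)
    invasion_percent(tyr, ct, dom$ROI)$percent_invaded, numeric(1))
  expect_true(all(diff(pct) <= 0))
})
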