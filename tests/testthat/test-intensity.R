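test_that("integrated density: arithmetic, identity, and loop oracle", {
  img <- matrix(5, 8, 8)
  roi <- matrix(FALSE, 8, 8); roi[2:3, 1:5] <- TRUE
  expect_equal(integrated_density(img, roi), 50)
  full <- matrix(TRUE, 8, 8)
  expect_equal(integrated_density(img, full), sum(img))
  expect_error(integrated_density(img, matrix(FALSE, 8, 8)), "empty ROI")
  expect_error(integrated_density(img, matrix(TRUE, 4, 4)), "shape")
  set.seed(12)
  for (rep in 1:10) {
    im <- matrix(runif(32 * 32, 0, 4096), 32, 32)
    mk <- matrix(runif(32 * 32) < 0.4, 32, 32)
    if (!any(mk)) next
    expect_equal(integrated_density(im, mk), loop_integrated_density(im, mk))
  }
})

test_that("positive cutoff separates two-valued images and matches brute-force Otsu", {
  img <- matrix(10, 16, 16); img[5:12, 5:12] <- 200
  cut <- positive_cutoff(img)
  expect_gt(cut, 10); expect_lt(cut, 200)
  # exhaustive between-class-variance maximization on a bimodal mixture
  set.seed(5)
  v <- round(c(rnorm(600, 80, 12), rnorm(300, 700, 60)))
  im <- matrix(v, 30, 30)
  cut_pkg <- positive_cutoff(im)
  cut_brute <- brute_otsu(as.vector(im))
  # both must classify the pixels identically
  expect_identical(im > cut_pkg, im > cut_brute)
  expect_error(positive_cutoff(matrix(7, 4, 4)), "degenerate.*7")
})

test_that("control background floors the cutoff; sub-threshold images give zero area", {
  img <- matrix(runif(400, 0, 240), 20, 20)
  cut <- positive_cutoff(img, control_background = 250)
  expect_gte(cut, 250)
  m <- aid_measure(img, matrix(TRUE, 20, 20), cut)
  expect_equal(m$positive_area_px, 0)
  expect_equal(m$aid, 0)
  expect_true(m$below_detection)
})

test_that("aid_measure: identity at zero cutoff, below-detection rule, px/um2 areas", {
  set.seed(8)
  img <- matrix(runif(100, 1, 10), 10, 10)
  roi <- matrix(TRUE, 10, 10)
  m <- aid_measure(img, roi, 0, pixel_size = 0.5)
  expect_equal(m$aid, integrated_density(img, roi))
  expect_equal(m$positive_area_px, 100)
  expect_equal(m$positive_area_um2, 25)
  expect_equal(m$aid, m$positive_area_px * m$mean_gray)   # AID = area x mean gray
  expect_false(m$below_detection)
  expect_error(aid_measure(img, matrix(FALSE, 10, 10), 0), "empty ROI")
})

test_that("tyr_glu_ratio: identity, undefined propagation, pairing error", {
  img <- matrix(c(rep(1, 50), rep(100, 50)), 10, 10)
  roi <- roi_mask(matrix(TRUE, 10, 10), label = "cell1")
  t1 <- aid_measure(img, roi, 50, channel = "tyr")
  g1 <- aid_measure(img, roi, 50, channel = "glu")
  r <- tyr_glu_ratio(t1, g1)
  expect_true(r$defined)
  expect_equal(r$ratio, 1)
  # below detection on either side -> undefined, ratio is NA (not 0, not Inf)
  gb <- aid_measure(img, roi, 1e6, channel = "glu")
  rb <- tyr_glu_ratio(t1, gb)
  expect_false(rb$defined)
  expect_true(is.na(rb$ratio))
  roi2 <- roi_mask(matrix(TRUE, 10, 10), label = "cell2")
  g2 <- aid_measure(img, roi2, 50, channel = "glu")
  expect_error(tyr_glu_ratio(t1, g2), "pairing error")
})

test_that("mt_network_area: disc geometry, monotone in closing radius, empty case", {
  img <- matrix(0, 64, 64)
  d <- disc_mask(64, 64, 32, 32, 12)
  img[d] <- 100
  res0 <- mt_network_area(img, 50, closing_radius_px = 0, pixel_size = 0.2)
  expect_equal(res0$area_px, sum(d))
  expect_equal(res0$area_um2, sum(d) * 0.04)
  res5 <- mt_network_area(img, 50, closing_radius_px = 5, pixel_size = 0.2)
  expect_gte(res5$area_px, res0$area_px)
  dark <- mt_network_area(matrix(1, 16, 16), 50)
  expect_true(dark$below_detection)
  expect_equal(dark$area_px, 0)
})

test_that("mt_network_area recovers the generator's rendered network area", {
  fx <- make_cell_image(cell_image_params(network_extent = 0.4), seed = 31)
  img <- fx$image$channels$tyr + fx$image$channels$glu
  cut <- positive_cutoff(img, fx$cell_mask)
  res <- mt_network_area(img, cut, closing_radius_px = 5, pixel_size = 0.2)
  truth_px <- fx$truth$values[["network_area_px"]]
  expect_lt(abs(res$area_px - truth_px) / truth_px, 0.10)
})

test_that("icw_normalize: arithmetic, scale invariance, exclusions", {
  tab <- data.frame(well = c("A1", "A2"), signal_afu = c(200, 300),
                    hoechst_afu = c(100, 150))
  n1 <- icw_normalize(tab)
  expect_equal(n1$normalized_fau, c(2, 2))
  tab2 <- tab; tab2$signal_afu <- tab2$signal_afu * 7
  tab2$hoechst_afu <- tab2$hoechst_afu * 7
  expect_equal(icw_normalize(tab2)$normalized_fau, n1$normalized_fau)
  tab3 <- rbind(tab, data.frame(well = "A3", signal_afu = 5, hoechst_afu = 0))
  expect_warning(n3 <- icw_normalize(tab3), "A3")
  expect_equal(nrow(n3), 2)
  tab4 <- data.frame(well = "A1", signal_afu = 1, hoechst_afu = -2)
  expect_error(icw_normalize(tab4), "all wells excluded")
})

test_that("focal plane selection prefers the larger network and breaks ties low", {
  # constructed stack: plane 2 has a strictly larger bright disc
  mk <- function(r) {
    img <- matrix(10, 96, 96); img[disc_mask(96, 96, 48, 48, r)] <- 2000
    multichannel_image(list(glu = img), pixel_size = 0.2)
  }
  st <- image_stack(list(mk(10), mk(25), mk(10)))
  expect_equal(select_focal_plane(st, "glu"), 2L)
  tie <- image_stack(list(mk(20), mk(20)))
  expect_equal(select_focal_plane(tie, "glu"), 1L)
})
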