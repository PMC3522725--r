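test_that("dilation and erosion match the per-pixel loop oracle", {
  set.seed(101)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 24) < 0.15, 20, 24)
    r <- sample(1:3, 1)
    expect_identical(mask_dilate(m, r), loop_dilate(m, r))
    # erosion by duality on the complement (with a border guard: duality only
    # holds away from the frame edge under the zero-padding convention)
    er <- mask_erode(m, r)
    dual <- !loop_dilate(!m, r)
    inner <- matrix(FALSE, 20, 24)
    inner[(r + 1):(20 - r), (r + 1):(24 - r)] <- TRUE
    expect_identical(er[inner], dual[inner])
  }
})

test_that("hole filling and largest component behave on known geometry", {
  ring <- disc_mask(31, 31, 16, 16, 10) & !disc_mask(31, 31, 16, 16, 6)
  filled <- mask_fill_holes(ring)
  expect_identical(filled, disc_mask(31, 31, 16, 16, 10))
  two <- disc_mask(40, 40, 10, 10, 4) | disc_mask(40, 40, 30, 30, 7)
  expect_identical(mask_largest_component(two), disc_mask(40, 40, 30, 30, 7))
  expect_equal(max(mask_label(two)), 2L)
  # all-FALSE mask passes through unchanged
  empty <- matrix(FALSE, 5, 5)
  expect_identical(mask_largest_component(empty), empty)
  expect_identical(mask_fill_holes(empty), empty)
})

test_that("closing is extensive and monotone in the radius", {
  set.seed(7)
  m <- matrix(runif(40 * 40) < 0.1, 40, 40)
  c0 <- mask_close(m, 0); c2 <- mask_close(m, 2); c4 <- mask_close(m, 4)
  expect_identical(c0, m)
  expect_true(all(m <= c2))          # closing never removes pixels
  expect_true(sum(c2) <= sum(c4))
})
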