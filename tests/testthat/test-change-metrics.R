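test_that("delta_volume is the signed difference and antisymmetric", {
  expect_identical(delta_volume(50, 50), 0)
  expect_equal(delta_volume(10, 13.4), 3.4)
  set.seed(3)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(delta_volume(a, b), -delta_volume(b, a))
  expect_error(delta_volume(-1, 2))
})

test_that("LSC correction hits the significance boundary exactly and is scale invariant", {
  # change equal to the least significant change maps to exactly 1
  expect_identical(as.numeric(lsc_correct(0.352 * 10, 10, 0.352)), 1)
  expect_equal(as.numeric(lsc_correct(3.4, 10, 0.352)), 3.4 / 3.52)
  expect_equal(round(as.numeric(lsc_correct(3.4, 10, 0.352)), 4), 0.9659)
  set.seed(4)
  d <- rnorm(20); b <- runif(20, 1, 50); cc <- runif(20, 0.5, 4)
  expect_equal(as.numeric(lsc_correct(d * cc, b * cc, 0.144)),
               as.numeric(lsc_correct(d, b, 0.144)))
})

test_that("zero baselines are floored and flagged, pair-mean reference works", {
  out <- lsc_correct(1, 0, 0.352, floor_ml = 0.5)
  expect_true(attr(out, "floored"))
  expect_equal(as.numeric(out), 1 / (0.352 * 0.5))
  out2 <- lsc_correct(2, 10, 0.144, followup = 30, reference = "mean")
  expect_false(attr(out2, "floored"))
  expect_equal(as.numeric(out2), 2 / (0.144 * 20))
})

test_that("regional subtraction is the follow-up-minus-baseline voxel set", {
  set.seed(5)
  m <- random_mask(c(16, 16, 16))
  same <- regional_subtraction(m, m)
  expect_identical(same$volume_ml, 0)
  expect_identical(sum(same$mask$grid), 0L)
  # disjoint masks: subtraction volume is the full follow-up volume
  a <- binary_mask(array(FALSE, c(8, 8, 8))); a$grid[1:2, , ] <- TRUE
  b <- binary_mask(array(FALSE, c(8, 8, 8))); b$grid[5:6, , ] <- TRUE
  expect_equal(regional_subtraction(a, b)$volume_ml, mask_volume_ml(b))
  expect_error(regional_subtraction(a, random_mask(c(4, 4, 4))), "grids")
})

test_that("mask-algebra conservation holds exactly with nested-mask consistency", {
  set.seed(6)
  for (i in 1:25) {
    base <- random_mask(c(16, 16, 16), p = runif(1, 0.1, 0.5))
    fup <- random_mask(c(16, 16, 16), p = runif(1, 0.1, 0.5))
    rs <- regional_subtraction(base, fup)
    expect_identical(sum(fup$grid), rs$overlap_vox + rs$volume_vox)
    expect_equal(mask_volume_ml(fup), rs$overlap_ml + rs$volume_ml,
                 tolerance = 1e-14)
    # growth-only pairs: subtraction equals the volume delta
    grown <- binary_mask(base$grid | fup$grid, base$voxel_size)
    rs2 <- regional_subtraction(base, grown)
    expect_equal(rs2$volume_ml,
                 delta_volume(mask_volume_ml(base), mask_volume_ml(grown)),
                 tolerance = 1e-14)
    expect_identical(rs2$regressed_vox, 0L)
  }
})

test_that("change_records pairs consecutive scans with both determinants", {
  scans <- data.frame(
    patient_id = rep("P01", 3), scan_index = 1:3,
    cv_ml = c(10, 2, 4), fv_ml = c(50, 30, 36),
    scv_ml = c(NA, 1, 2.5), sfv_ml = c(NA, 5, 8),
    rating = c(0L, 1L, 5L))
  rec <- change_records(scans, lsc_params())
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$dcv_ml, c(-8, 2))
  expect_equal(rec$dcv, c(-8 / (0.352 * 10), 2 / (0.352 * 2)))
  expect_equal(rec$dfv, c(-20 / (0.144 * 50), 6 / (0.144 * 30)))
  expect_equal(rec$scv, c(1, 2.5))
  expect_identical(rec$rating, c(1L, 5L))
})
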