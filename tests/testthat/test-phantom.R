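test_that("phantom spec validates its parameters", {
  expect_error(phantom_spec(scans_per_patient = c(2, 5)))
  expect_error(phantom_spec(cv_baseline_sdlog = 0))
  expect_error(phantom_spec(progression_prob = 1.5))
  expect_error(phantom_spec(grid_shape = c(300, 300, 300)))
})

test_that("identical spec and seed reproduce the cohort bit for bit", {
  a <- simulate_cohort_table(phantom_spec(seed = 14, n_patients = 6))
  b <- simulate_cohort_table(phantom_spec(seed = 14, n_patients = 6))
  expect_identical(a$scans, b$scans)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$mc_sources, b$mc_sources)
  c2 <- simulate_cohort_table(phantom_spec(seed = 15, n_patients = 6))
  expect_false(identical(a$scans$cv_ml, c2$scans$cv_ml))
})

test_that("cohort structure mirrors the study design", {
  co <- simulate_cohort_table(phantom_spec(seed = 16))
  s <- co$scans
  counts <- table(s$patient_id)
  expect_identical(length(counts), 30L)
  expect_true(all(counts >= 3 & counts <= 12))
  # scan 1 initial diagnosis, scan 2 postoperative, with the volume collapse
  first <- s[s$scan_index == 1, ]; second <- s[s$scan_index == 2, ]
  expect_true(all(first$rating == 0))
  expect_true(all(second$rating == 1))
  expect_true(all(second$cv_ml < first$cv_ml))
  expect_true(all(s$fv_ml >= s$cv_ml))
  expect_true(all(s$scv_ml[!is.na(s$scv_ml)] >= 0))
  # progression labels exist exactly for follow-up scans
  expect_true(all(is.na(s$progression[s$scan_index == 1])))
  expect_true(all(!is.na(s$progression[s$scan_index >= 2])))
})

test_that("null generator decouples progression labels from volume change", {
  co <- simulate_cohort_table(phantom_spec(seed = 17, growth_effect = 1))
  rec <- label_records(change_records(co$scans), co$mc_sources)
  rec <- rec[!is.na(rec$progression), ]
  expect_lt(abs(cor(rec$dcv, rec$progression)), 0.2)
})

test_that("rendered masks satisfy containment and label consistency", {
  co <- simulate_cohort_table(small_image_spec(seed = 18))
  p <- render_phantom_images(co, "P01", scan_indices = c(2, 3))
  for (scan in p) {
    expect_true(all(scan$fv_mask$grid[scan$cv_mask$grid]))
    expect_identical(mask_volume_ml(scan$cv_mask), scan$cv_true_ml)
    expect_identical(mask_volume_ml(scan$fv_mask), scan$fv_true_ml)
    vox <- prod(scan$cv_mask$voxel_size) / 1000
    expect_equal(scan$cv_true_ml, sum(scan$cv_mask$grid) * vox)
  }
  # rendered volumes track the tabular trajectory up to discretisation
  rows <- co$scans[co$scans$patient_id == "P01" & co$scans$scan_index %in% 2:3, ]
  expect_equal(p[[1]]$cv_true_ml, rows$cv_ml[1], tolerance = 0.06)
  expect_equal(p[[2]]$fv_true_ml, rows$fv_ml[2], tolerance = 0.06)
})

test_that("noiseless rendering recovers the truth mask by midpoint thresholding", {
  co <- simulate_cohort_table(small_image_spec(seed = 19, noise_sd = 0,
                                               misregistration_sd = 0))
  p <- render_phantom_images(co, "P01", scan_indices = 3)
  scan <- p[[1]]
  expect_identical(scan$mprage$data > 60, scan$cv_mask$grid)
  expect_identical(scan$flair$data > 60, scan$fv_mask$grid)
})

test_that("consecutive rendered scans differ by the stored rigid transform", {
  co <- simulate_cohort_table(phantom_spec(
    seed = 20, n_patients = 1, noise_sd = 0, growth_effect = 1,
    progression_prob = 0, stable_sdlog = 0.011, fv_noise_sdlog = 0.011,
    misregistration_sd = 2))
  p <- render_phantom_images(co, "P01", scan_indices = c(3, 4))
  moved <- resample_mask(p[[2]]$cv_mask,
                         invert_transform(p[[2]]$transform_from_prev),
                         target = p[[1]]$cv_mask)
  expect_gt(dice_overlap(moved, p[[1]]$cv_mask), 0.9)
  # without the transform the masks visibly disagree
  expect_lt(dice_overlap(p[[2]]$cv_mask, p[[1]]$cv_mask),
            dice_overlap(moved, p[[1]]$cv_mask))
})

test_that("oversized tumors fail rendering with a clear error", {
  co <- simulate_cohort_table(phantom_spec(seed = 21, n_patients = 1,
                                           grid_shape = c(24L, 24L, 24L)))
  co$scans$fv_ml[co$scans$patient_id == "P01" & co$scans$scan_index == 1] <- 140
  expect_error(render_phantom_images(co, "P01", scan_indices = 1),
               "larger than the phantom grid")
})

test_that("cohort CSV export writes the documented schema", {
  co <- simulate_cohort_table(phantom_spec(seed = 22, n_patients = 4))
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir)
  s <- read.csv(paths["scans"])
  expect_true(all(c("patient_id", "scan_index", "cv_ml", "fv_ml",
                    "scv_ml", "sfv_ml", "rating", "progression") %in% names(s)))
  expect_identical(nrow(s), nrow(co$scans))
})
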