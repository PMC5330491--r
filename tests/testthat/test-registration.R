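test_that("rigid transforms compose, invert and serialize consistently", {
  tf <- rigid_transform(c(3, -2, 5), c(1.5, -0.7, 2.2), center = c(10, 10, 10))
  M <- transform_matrix(tf)
  expect_equal(compose_transforms(tf, invert_transform(tf)), diag(4),
               tolerance = 1e-10)
  R <- M[1:3, 1:3]
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)  # orthonormal
  pts <- matrix(rnorm(30), ncol = 3)
  there_back <- transform_points(invert_transform(tf), transform_points(tf, pts))
  expect_equal(there_back, pts, tolerance = 1e-10)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_transform(tf, tmp)
  expect_equal(read_transform(tmp), M, tolerance = 1e-6)
})

test_that("registering a volume to itself returns identity at maximal score", {
  co <- simulate_cohort_table(small_image_spec(seed = 2, noise_sd = 0,
                                               misregistration_sd = 0))
  p <- render_phantom_images(co, "P01", scan_indices = 3)
  img <- p[[1]]$mprage
  set.seed(1)
  reg <- register_rigid(img, img, n_starts = 0, maxit = 200)
  expect_true(reg$registered)
  diff <- transform_difference(reg$transform, rigid_transform())
  expect_lt(diff["angle_deg"], 0.3)
  expect_lt(diff["trans_mm"], 0.3)
})

test_that("a known rigid offset is recovered within 0.5 mm and 0.5 degrees", {
  co <- simulate_cohort_table(small_image_spec(seed = 3, noise_sd = 0,
                                               misregistration_sd = 0))
  tfD <- rigid_transform(c(0, 2, 0), c(3, 0, 0))
  co$truth[["P01"]]$poses[[3]] <-
    compose_transforms(transform_matrix(tfD), co$truth[["P01"]]$poses[[2]])
  p <- render_phantom_images(co, "P01", scan_indices = c(2, 3))
  set.seed(1)
  reg <- register_rigid(p[[1]]$mprage, p[[2]]$mprage, n_starts = 1)
  truthT <- invert_transform(p[[2]]$transform_from_prev)
  diff <- transform_difference(reg$transform, truthT)
  expect_lt(diff["angle_deg"], 0.5)
  expect_lt(diff["trans_mm"], 0.5)
  expect_true(reg$registered)
})

test_that("inverse consistency: A->B and B->A registrations are mutual inverses", {
  co <- simulate_cohort_table(small_image_spec(seed = 5, noise_sd = 0,
                                               misregistration_sd = 1.5))
  p <- render_phantom_images(co, "P01", scan_indices = c(2, 3))
  set.seed(2)
  ab <- register_rigid(p[[1]]$mprage, p[[2]]$mprage, n_starts = 0)
  ba <- register_rigid(p[[2]]$mprage, p[[1]]$mprage, n_starts = 0)
  diff <- transform_difference(transform_matrix(ab$transform),
                               invert_transform(ba$transform))
  expect_lt(diff["angle_deg"], 1)
  expect_lt(diff["trans_mm"], 1)
})

test_that("pure-noise image pairs score below the acceptance gate", {
  set.seed(7)
  a <- image_volume(array(rnorm(40^3, 50, 12), c(40, 40, 40)))
  b <- image_volume(array(rnorm(40^3, 50, 12), c(40, 40, 40)))
  reg <- register_rigid(a, b, n_starts = 0, maxit = 60)
  expect_false(reg$registered)
})

test_that("nearest-neighbour resampling is exact for identity and unit shifts", {
  set.seed(8)
  m <- random_mask(c(10, 12, 14))
  id <- resample_mask(m, rigid_transform())
  expect_identical(id$grid, m$grid)
  # one-voxel translation on an axis-aligned grid shifts indices exactly
  sh <- resample_mask(m, rigid_transform(translation = c(1, 0, 0)))
  expect_identical(sh$grid[1:9, , ], m$grid[2:10, , ])
  expect_true(all(sh$grid %in% c(TRUE, FALSE)))
  expect_true(all(!sh$grid[10, , ]))
})

test_that("resampling through the true offset recovers baseline masks with high Dice", {
  # growth switched off so consecutive truth masks differ only by the
  # stored rigid pose: resampling through it must recover the baseline mask
  co <- simulate_cohort_table(phantom_spec(
    seed = 6, n_patients = 2, noise_sd = 0, growth_effect = 1,
    progression_prob = 0, stable_sdlog = 0.011, fv_noise_sdlog = 0.011))
  dices <- c()
  for (pid in c("P01", "P02")) {
    p <- render_phantom_images(co, pid, scan_indices = c(3, 4))
    if (p[[1]]$fv_true_ml < 1) next
    res <- resample_mask(p[[2]]$fv_mask,
                         invert_transform(p[[2]]$transform_from_prev),
                         target = p[[1]]$fv_mask)
    dices <- c(dices, dice_overlap(res, p[[1]]$fv_mask))
  }
  expect_gte(length(dices), 1)
  expect_true(all(dices >= 0.95))
})

test_that("a mask fully outside the target grid yields an empty mask with warning", {
  m <- random_mask(c(8, 8, 8), p = 0.5)
  expect_warning(
    out <- resample_mask(m, rigid_transform(translation = c(100, 0, 0))),
    "outside")
  expect_identical(sum(out$grid), 0L)
})
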