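test_that("noiseless sphere is segmented exactly with analytic volume", {
  sph <- make_sphere_image(radius = 8)
  seeds <- seeds_from_mask(sph$mask)
  m <- segment_semiauto(sph$image, seeds$axial, seeds$coronal)
  expect_identical(m$grid, sph$mask$grid)
  # discretised sphere volume within a voxel shell of (4/3) pi r^3
  analytic <- 4 / 3 * pi * 8^3 / 1000
  shell <- 4 * pi * 8^2 * 1 / 1000
  expect_lt(abs(mask_volume_ml(m) - analytic), shell)
})

test_that("growth respects connectivity: disjoint blobs are not merged", {
  dims <- c(40, 20, 20)
  img <- array(20, dims)
  img[5:12, 8:14, 8:14] <- 100    # blob A
  img[28:36, 8:14, 8:14] <- 100   # blob B, disconnected
  vol <- image_volume(img)
  region_a <- array(FALSE, dims[c(1, 2)]); region_a[6:10, 9:12] <- TRUE
  ax <- seed_contour("axial", 10, region_a)
  region_ac <- array(FALSE, dims[c(1, 3)]); region_ac[6:10, 9:12] <- TRUE
  co <- seed_contour("coronal", 10, region_ac)
  m <- segment_semiauto(vol, ax, co)
  expect_true(all(which(m$grid, arr.ind = TRUE)[, 1] <= 13))
  expect_identical(sum(m$grid), sum(img[1:13, , ] == 100))
})

test_that("vectorised flood fill equals the naive BFS oracle on small grids", {
  set.seed(11)
  for (rep in 1:5) {
    dims <- c(18, 16, 14)
    img <- array(stats::rnorm(prod(dims), 50, 25), dims)
    vol <- image_volume(img)
    # seed a random bright-ish blob away from all grid edges
    cx <- c(sample(4:14, 1), sample(4:12, 1), sample(4:10, 1))
    img[cx[1] + (-2:2), cx[2] + (-2:2), cx[3] + (-2:2)] <- 100
    vol$data <- img
    reg_ax <- array(FALSE, dims[1:2]); reg_ax[cx[1] + (-1:1), cx[2] + (-1:1)] <- TRUE
    reg_co <- array(FALSE, dims[c(1, 3)]); reg_co[cx[1] + (-1:1), cx[3] + (-1:1)] <- TRUE
    ax <- seed_contour("axial", cx[3], reg_ax)
    co <- seed_contour("coronal", cx[2], reg_co)
    m <- segment_semiauto(vol, ax, co, tolerance_k = 2, fill_holes = FALSE)
    seeds3 <- gliovol:::.seed_to_grid(ax, dims) | gliovol:::.seed_to_grid(co, dims)
    vals <- img[seeds3]
    band <- mean(vals) + c(-2, 2) * sd(vals)
    oracle <- bfs_region_grow(img, seeds3, band[1], band[2])
    expect_identical(m$grid, oracle)
  }
})

test_that("mask grows monotonically with tolerance and contains its seeds", {
  set.seed(12)
  sph <- make_sphere_image(radius = 7)
  img <- sph$image
  img$data <- img$data + stats::rnorm(length(img$data), sd = 10)
  seeds <- seeds_from_mask(sph$mask)
  seeds3 <- gliovol:::.seed_to_grid(seeds$axial, dim(img$data)) |
    gliovol:::.seed_to_grid(seeds$coronal, dim(img$data))
  vals <- img$data[seeds3]
  prev <- NULL
  for (k in c(1.5, 2.5, 3.5)) {
    m <- segment_semiauto(img, seeds$axial, seeds$coronal, tolerance_k = k,
                          fill_holes = FALSE)
    band <- mean(vals) + c(-k, k) * sd(vals)
    in_band_seeds <- seeds3 & img$data >= band[1] & img$data <= band[2]
    expect_true(all(m$grid[in_band_seeds]))
    if (!is.null(prev)) expect_true(all(m$grid[prev]))
    prev <- m$grid
  }
})

test_that("runaway growth beyond the volume cap raises an error", {
  sph <- make_sphere_image(radius = 6)
  img <- sph$image
  img$data[] <- 100  # uniform image: the band floods the whole grid
  seeds <- seeds_from_mask(sph$mask)
  expect_error(
    segment_semiauto(img, seeds$axial, seeds$coronal, volume_cap_ml = 0.01),
    "volume cap")
})

test_that("empty or out-of-bounds seeds are rejected", {
  expect_error(seed_contour("axial", 3, matrix(FALSE, 4, 4)), "empty")
  sph <- make_sphere_image()
  bad <- seed_contour("axial", 99, matrix(TRUE, 32, 32))
  ok <- seeds_from_mask(sph$mask)
  expect_error(segment_semiauto(sph$image, bad, ok$coronal), "bounds")
})
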