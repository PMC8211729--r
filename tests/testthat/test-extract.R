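test_that("gaussian smoothing preserves constants and kernel mass", {
  img <- array(3.7, dim = c(12, 12, 12))
  sm <- gaussian_smooth(img, 5, 1)
  expect_equal(sm, img, tolerance = 1e-12)

  # interior unit impulse: total mass preserved, center equals the mode of
  # the (discretized, normalized) separable kernel
  img <- array(0, dim = c(21, 21, 21))
  img[11, 11, 11] <- 1
  sm <- gaussian_smooth(img, 5, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  h <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-h:h) / sigma)^2); k <- k / sum(k)
  expect_equal(sm[11, 11, 11], max(k)^3, tolerance = 1e-10)
  # the discrete mode approximates the continuous 3-D normalizing constant
  expect_equal(sm[11, 11, 11], (2 * pi * sigma^2)^(-3 / 2), tolerance = 1e-3)
})

test_that("smoothing requires a derivable voxel size", {
  img <- array(0, dim = c(4, 4, 4))
  expect_bt_error(gaussian_smooth(img, 5, NA), "affine")
  expect_bt_error(gaussian_smooth(img, 5, -1), "affine")
})

test_that("sphere averaging matches a brute-force voxel scan", {
  grid <- grid_spec(origin = c(-10, -10, -10), dim = c(21, 21, 21))
  # independent oracle: exhaustive scan over every voxel center in the grid,
  # Euclidean distance to the sphere center <= radius (inclusive)
  centers <- as.matrix(expand.grid(i = 1:21, j = 1:21, k = 1:21))
  mm <- sweep(centers - 1, 2, c(10, 10, 10))  # voxel centers in mm
  for (ctr in list(c(0, 0, 0), c(0.4, -1.2, 0.7))) {
    for (rad in c(1, 2.5, 3.75)) {
      inside <- centers[rowSums(sweep(mm, 2, ctr)^2) <= rad^2 + 1e-9, , drop = FALSE]
      idx <- braintraits:::sphere_mask_indices(grid, ctr, rad)
      expect_equal(idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE],
                   unname(inside[order(inside[, 1], inside[, 2], inside[, 3]), ,
                                 drop = FALSE]),
                   ignore_attr = TRUE)
    }
  }
  # axis-aligned voxel-centered sphere of radius 1: the 7-voxel plus shape
  expect_equal(nrow(braintraits:::sphere_mask_indices(grid, c(0, 0, 0), 1)), 7L)

  # uniform image: every region volume equals the constant
  at <- mini_atlas_fix()
  grid2 <- grid_spec(origin = c(-25, 15, -45), dim = c(55, 55, 90))
  vc <- structure(list(images = list(array(2.5, grid2$dim)), grid = grid2,
                       participant_id = 1L), class = "voxel_cohort")
  rv <- extract_region_volumes(vc, at)
  expect_equal(unname(rv$values[1, ]), rep(2.5, 3), tolerance = 1e-9)
})

test_that("extraction errors on coordinates outside the grid", {
  at <- mini_atlas_fix()
  grid <- grid_spec(origin = c(0, 0, 0), dim = c(5, 5, 5))
  vc <- structure(list(images = list(array(0, grid$dim)), grid = grid,
                       participant_id = 1L), class = "voxel_cohort")
  expect_bt_error(extract_region_volumes(vc, at), "out_of_grid")
})

test_that("painting and extraction are inverse without smoothing or noise", {
  at <- mini_atlas_fix()
  at$smoothing_fwhm_mm <- 0
  sim <- simulate_cohort(4, 31, tt_fix(), generation_config(), atlas_fix())
  vol <- region_volume_matrix(matrix(rnorm(12), 4, 3),
                              at$regions$region_id)
  grid <- grid_spec(origin = c(-25, 15, -45), dim = c(55, 55, 90))
  vc <- simulate_voxel_cohort(sim, vol, at, grid, seed = 2, baseline = 0.4)
  rec <- extract_region_volumes(vc, at, smooth = FALSE)
  expect_equal(rec$values, vol$values + 0.4, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("voxel painting is deterministic and checks the grid margin", {
  at <- mini_atlas_fix()
  sim <- simulate_cohort(2, 31, tt_fix(), generation_config(), atlas_fix())
  vol <- region_volume_matrix(matrix(1:6, 2, 3), at$regions$region_id)
  grid <- grid_spec(origin = c(-25, 15, -45), dim = c(55, 55, 90))
  a <- simulate_voxel_cohort(sim, vol, at, grid, seed = 5, voxel_noise_sd = 0.3)
  b <- simulate_voxel_cohort(sim, vol, at, grid, seed = 5, voxel_noise_sd = 0.3)
  expect_identical(a$images, b$images)
  tight <- grid_spec(origin = c(-2, 40, -20), dim = c(10, 20, 35))
  expect_bt_error(simulate_voxel_cohort(sim, vol, at, tight, seed = 1),
                  "grid_too_small")
})

test_that("extraction is linear in the image", {
  at <- mini_atlas_fix()
  grid <- grid_spec(origin = c(-25, 15, -45), dim = c(55, 55, 90))
  set.seed(8)
  img <- array(rnorm(prod(grid$dim)), grid$dim)
  vc1 <- structure(list(images = list(img), grid = grid, participant_id = 1L),
                   class = "voxel_cohort")
  vc2 <- structure(list(images = list(2 + 3 * img), grid = grid,
                        participant_id = 1L), class = "voxel_cohort")
  r1 <- extract_region_volumes(vc1, at)
  r2 <- extract_region_volumes(vc2, at)
  expect_equal(r2$values, 2 + 3 * r1$values, tolerance = 1e-9)
})

test_that("small and large sphere diameters give near-identical volumes on smooth data", {
  at5 <- atlas_fix()
  sim <- simulate_cohort(40, 19, tt_fix(),
                         generation_config(network_loading = 0.3), atlas_fix())
  vol <- simulate_region_volumes(sim, sim$truth, at5, 19)
  mini <- mini_atlas_fix()
  grid <- grid_spec(origin = c(-25, 15, -45), dim = c(55, 55, 90))
  vc <- simulate_voxel_cohort(sim, subset_volumes(vol, mini), mini, grid,
                              seed = 3, voxel_noise_sd = 0.05)
  small <- mini; small$sphere_diameter_mm <- 2.5
  large <- mini; large$sphere_diameter_mm <- 7.5
  r_small <- extract_region_volumes(vc, small)
  r_large <- extract_region_volumes(vc, large)
  cors <- diag(cor(r_small$values, r_large$values))
  expect_true(all(cors > 0.9))
})

test_that("z-scoring uses the population convention and is idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5, 8), 3, 2, dimnames = list(NULL, c("a", "b")))
  z <- zscore_columns(m)
  expect_equal(z$values[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(z$standardized)
  z2 <- zscore_columns(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  m[, 2] <- 4
  expect_bt_error(zscore_columns(m), "degenerate_column")
})

test_that("NIfTI round trip preserves grids and voxel data", {
  at <- mini_atlas_fix()
  sim <- simulate_cohort(3, 23, tt_fix(), generation_config(), atlas_fix())
  vol <- region_volume_matrix(matrix(rnorm(9), 3, 3), at$regions$region_id)
  grid <- grid_spec(origin = c(-25, 15, -45), dim = c(55, 55, 90))
  vc <- simulate_voxel_cohort(sim, vol, at, grid, seed = 4, voxel_noise_sd = 0.1)
  dir <- withr::local_tempdir()
  write_voxel_cohort(vc, dir)
  back <- read_voxel_cohort(dir)
  expect_equal(back$grid$origin, grid$origin, tolerance = 1e-5)
  expect_equal(back$grid$dim, grid$dim)
  expect_equal(back$images[[2]], vc$images[[2]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$participant_id, 1:3)
})
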