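test_that("sphere mask equals brute-force voxel-center enumeration", {
  grid <- voxel_grid(c(20, 20, 16))
  center <- c(33, 33, 24)
  radius <- 8
  mask <- build_sphere_mask(center, radius, grid)

  # oracle: loop every voxel, measure distance to the snapped center
  ctr_idx <- round(drop(solve(grid$affine) %*% c(center, 1))[1:3])
  ctr_mm <- drop(grid$affine %*% c(ctr_idx, 1))[1:3]
  expected <- array(FALSE, dim = grid$shape)
  for (i in 0:(grid$shape[1] - 1)) for (j in 0:(grid$shape[2] - 1))
    for (k in 0:(grid$shape[3] - 1)) {
      mm <- drop(grid$affine %*% c(i, j, k, 1))[1:3]
      expected[i + 1, j + 1, k + 1] <- sqrt(sum((mm - ctr_mm)^2)) <= radius
    }
  expect_identical(mask, expected)
  expect_gt(sum(mask), 1)
})

test_that("cube mask equals brute-force enumeration and respects the edge", {
  grid <- voxel_grid(c(12, 12, 12))
  center <- c(18, 18, 18)
  edge <- 8
  mask <- build_cube_mask(center, edge, grid)
  ctr_idx <- round(drop(solve(grid$affine) %*% c(center, 1))[1:3])
  ctr_mm <- drop(grid$affine %*% c(ctr_idx, 1))[1:3]
  expected <- array(FALSE, dim = grid$shape)
  for (i in 0:11) for (j in 0:11) for (k in 0:11) {
    mm <- drop(grid$affine %*% c(i, j, k, 1))[1:3]
    expected[i + 1, j + 1, k + 1] <- all(abs(mm - ctr_mm) <= edge / 2)
  }
  expect_identical(mask, expected)
})

test_that("degenerate radii and out-of-grid centers behave as specified", {
  grid <- voxel_grid(c(10, 10, 10))
  tiny <- build_sphere_mask(c(16.6, 16.6, 15), 1e-6, grid)
  expect_equal(sum(tiny), 1)
  expect_true(tiny[6, 6, 6])  # voxel (5,5,5) 0-based contains that point

  huge <- build_sphere_mask(c(16.6, 16.6, 15), 1e4, grid)
  expect_true(all(huge))

  expect_error(build_sphere_mask(c(500, 500, 500), 5, grid), "outside")
  expect_error(build_cube_mask(c(500, 500, 500), 2, grid), "outside")
  expect_error(build_sphere_mask(c(16, 16, 15), -1, grid), "> 0")
})

test_that("sphere masks are symmetric under axis reflection on equal spacings", {
  grid <- voxel_grid(c(11, 11, 11), spacing = c(3, 3, 3))
  ctr <- drop(graspdecode:::voxel_to_mm(grid, c(5, 5, 5)))
  mask <- build_sphere_mask(ctr, 7, grid)
  expect_identical(mask, mask[11:1, , ])
  expect_identical(mask, mask[, 11:1, ])
  expect_identical(mask, aperm(mask, c(2, 1, 3)))
  # idempotence / determinism
  expect_identical(mask, build_sphere_mask(ctr, 7, grid))
})

test_that("extraction returns masked voxels in ascending linear order", {
  set.seed(42)
  dims <- c(4, 4, 3)
  n_t <- 6
  img <- array(rnorm(prod(dims) * n_t), dim = c(dims, n_t))
  mask <- array(FALSE, dims)
  mask[c(2, 17, 31)] <- TRUE  # linear indices
  ts <- extract_roi_timeseries(img, mask, run_labels = rep(1, n_t), tr = 2)
  expect_equal(ncol(ts$data), 3)
  flat <- matrix(img, ncol = n_t)
  expect_equal(ts$data, t(flat[c(2, 17, 31), ]), ignore_attr = TRUE)

  # single-voxel and full masks
  one <- array(FALSE, dims); one[3, 2, 1] <- TRUE
  ts1 <- extract_roi_timeseries(img, one, rep(1, n_t))
  expect_equal(drop(ts1$data), img[3, 2, 1, ])
  full <- array(TRUE, dims)
  expect_equal(ncol(extract_roi_timeseries(img, full, rep(1, n_t))$data),
               prod(dims))

  expect_error(extract_roi_timeseries(img, array(TRUE, c(2, 2, 2)),
                                      rep(1, n_t)), "grid")
  expect_error(extract_roi_timeseries(img, array(FALSE, dims), rep(1, n_t)),
               "Empty")
})

test_that("known per-voxel constants survive extraction unchanged", {
  dims <- c(3, 3, 3)
  n_t <- 4
  img <- array(0, dim = c(dims, n_t))
  for (v in seq_len(prod(dims))) {
    idx <- arrayInd(v, dims)
    img[idx[1], idx[2], idx[3], ] <- v
  }
  mask <- array(TRUE, dims)
  ts <- extract_roi_timeseries(img, mask, rep(1, n_t))
  expect_true(all(apply(ts$data, 2, function(col) length(unique(col)) == 1)))
  expect_equal(unname(ts$data[1, ]), seq_len(prod(dims)))
})

test_that("masks and images round-trip bit-exactly through NIfTI", {
  grid <- voxel_grid(c(8, 8, 6))
  mask <- build_sphere_mask(c(13.2, 13.2, 9), 6, grid)
  mpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(mask, grid, mpath)
  expect_identical(read_mask_nifti(mpath), mask)

  spec <- small_spec()
  ev <- generate_design(spec, seed = 2)
  pm <- pattern_model(sum(mask), spec$conditions)
  ts <- simulate_roi_timeseries(ev, spec, pm, seed = 9)
  img <- embed_roi_timeseries(ts, mask)
  ipath <- withr::local_tempfile(fileext = ".nii.gz")
  write_image_nifti(img, grid, ipath, tr = spec$tr)
  back <- extract_roi_timeseries(read_image_nifti(ipath), mask, ts$run,
                                 tr = spec$tr)
  expect_equal(back$data, ts$data, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("roi_spec validates its single geometric definition", {
  expect_error(roi_spec("x"), "Exactly one")
  expect_error(roi_spec("x", sphere = list(center = c(0, 0, 0), radius = 0)),
               "radius")
  sp <- roi_spec("SPOC", "L", sphere = list(center = c(-17, -72, 37),
                                            radius = 8),
                 space_label = "Talairach")
  grid <- voxel_grid(c(40, 40, 40), origin = c(-60, -90, -20))
  mask <- build_roi_mask(sp, grid)
  expect_identical(mask,
                   build_sphere_mask(c(-17, -72, 37), 8, grid))
})
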