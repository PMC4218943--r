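test_that("affine transforms act as matrices and compose by matrix product", {
  M1 <- diag(4); M1[1:3, 1:3] <- pmbrainvol:::rotation_matrix(c(0.1, -0.2, 0.3))
  M1[1:3, 4] <- c(1, -2, 0.5)
  M2 <- diag(4); M2[1, 1] <- 1.1; M2[2, 1] <- 0.05; M2[1:3, 4] <- c(-0.4, 0, 2)
  A <- tf_affine(M1); B <- tf_affine(M2)
  pts <- matrix(stats::rnorm(30), ncol = 3) * 5
  expect_equal(tf_apply(compose_transforms(A, B), pts),
               tf_apply(A, tf_apply(B, pts)), tolerance = 1e-12)
  direct <- pts %*% t((M1 %*% M2)[1:3, 1:3])
  direct <- sweep(direct, 2, (M1 %*% M2)[1:3, 4], `+`)
  expect_equal(tf_apply(compose_transforms(A, B), pts), direct,
               tolerance = 1e-12)
  expect_equal(tf_apply(compose_transforms(tf_identity(), A), pts),
               tf_apply(A, pts), tolerance = 1e-12)
  expect_equal(tf_apply(compose_transforms(A, tf_invert(A)), pts), pts,
               tolerance = 1e-10)
})

test_that("resampling through the identity on the same grid is exact", {
  ph <- phantom_clean32()
  out <- resample(ph$image, tf_identity(), ph$image)
  expect_equal(out$data, ph$image$data, tolerance = 1e-12)
})

test_that("label maps require nearest-neighbour interpolation", {
  ph <- phantom_clean32()
  expect_error(resample(ph$truth$label_map, tf_identity(), ph$image,
                        interpolation = "linear"),
               "nearest")
  ok <- resample(ph$truth$label_map, tf_identity(), ph$image,
                 interpolation = "nearest")
  expect_equal(as.integer(ok$data), as.integer(ph$truth$label_map$data))
})

test_that("resampled priors keep a per-voxel sum of at most one", {
  ph <- phantom_clean32()
  atl <- atlas_from_truth(list(ph$truth), smoothing_mm = 1.2)
  cp_dim <- pmbrainvol:::cpp_bspline_ncp(c(32L, 32L, 32L), 8)
  cp <- array(pmbrainvol:::with_seed(4, stats::rnorm(prod(cp_dim) * 3, sd = 0.8)),
              dim = c(cp_dim, 3))
  warp <- tf_bspline(cp, 8, c(32L, 32L, 32L), rep(0.6, 3))
  priors <- resample_priors(atl$priors, warp, ph$image)
  total <- Reduce(`+`, lapply(priors, function(p) p$data))
  expect_lte(max(total), 1 + 1e-10)
})

test_that("translation round trip preserves a smooth image (r > 0.99)", {
  ph <- phantom_default48()
  # smooth phantom: interpolation error concentrates at sharp edges, so the
  # round-trip guarantee is for smooth intensity profiles
  smooth <- with_data(ph$image, pmbrainvol:::cpp_gauss_smooth(
    as.numeric(ph$truth$clean_image$data), dim(ph$image$data), rep(2, 3)))
  M <- diag(4); M[1:3, 4] <- c(1.1, -0.7, 0.4)
  fwd <- resample(smooth, tf_affine(M), smooth)
  back <- resample(fwd, tf_invert(tf_affine(M)), smooth)
  inner <- ph$truth$head_mask$data > 0
  expect_gt(stats::cor(back$data[inner], smooth$data[inner]), 0.99)
})

test_that("registering an image to itself returns a near-identity transform", {
  ph <- phantom_default48()
  tf <- register(ph$image, ph$image, "rigid")
  expect_lt(max(abs(tf$matrix - diag(4))), 0.05)
})

test_that("a 3-voxel translation is recovered within 0.5 voxel", {
  ph <- generate_phantom(phantom_spec(grid_shape = 48, seed = 3,
                                      class_noise_sd = 20,
                                      bias_amplitude = 1))
  M <- diag(4); M[1:3, 4] <- c(3, 0, 0) * 0.6
  mov <- resample(ph$image, tf_affine(M), ph$image)
  tf <- register(ph$image, mov, "rigid")
  err_mm <- sqrt(sum((tf$matrix[1:3, 4] - c(-1.8, 0, 0))^2))
  expect_lt(err_mm / 0.6, 0.5)
})

test_that("a known smooth warp is recovered below 1 voxel mean error in the mask", {
  wf <- warp_fixture()
  tf <- suppressWarnings(register(wf$warped, wf$base$image, "bspline"))
  pts <- pmbrainvol:::grid_points_mm(wf$base$image)
  rec <- tf_apply(tf, pts)
  err_vox <- sqrt(rowSums((rec - (pts + wf$u))^2)) / 0.6
  before_vox <- sqrt(rowSums(wf$u^2)) / 0.6
  expect_lt(mean(err_vox[wf$mask]), 1)
  expect_lt(mean(err_vox[wf$mask]), 0.5 * mean(before_vox[wf$mask]))
})

test_that("the B-spline objective is non-decreasing over accepted iterations", {
  wf <- warp_fixture()
  tf <- suppressWarnings(register(wf$warped, wf$base$image, "bspline"))
  trace <- attr(tf, "trace")
  starts <- attr(tf, "stage_starts")
  bounds <- c(starts, length(trace) + 1L)
  for (s in seq_along(starts)) {
    seg <- trace[bounds[s]:(bounds[s + 1] - 1)]
    expect_false(is.unsorted(seg))
  }
})

test_that("empty overlap raises an error", {
  ph <- phantom_clean32()
  M <- diag(4); M[1:3, 4] <- c(1e5, 0, 0)
  expect_error(register(ph$image, ph$image, "affine", init = tf_affine(M)),
               "overlap")
})

test_that("transforms survive a JSON round trip", {
  M <- diag(4); M[1:3, 4] <- c(1, 2, 3); M[1, 2] <- 0.1
  path <- tempfile(fileext = ".json")
  write_transform(tf_affine(M), path)
  expect_equal(read_transform(path)$matrix, M, tolerance = 1e-15)
  cp_dim <- pmbrainvol:::cpp_bspline_ncp(c(16L, 16L, 16L), 4)
  cp <- array(stats::rnorm(prod(cp_dim) * 3), dim = c(cp_dim, 3))
  B <- tf_bspline(cp, 4, c(16L, 16L, 16L), rep(0.6, 3))
  comp <- compose_transforms(tf_affine(M), B)
  write_transform(comp, path)
  back <- read_transform(path)
  pts <- matrix(stats::runif(30, 0, 9), ncol = 3)
  expect_equal(tf_apply(back, pts), tf_apply(comp, pts), tolerance = 1e-12)
})
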