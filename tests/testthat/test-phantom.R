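test_that("noise-free, bias-free phantom is the piecewise-constant class image", {
  ph <- phantom_clean32()
  expect_identical(ph$image$data, ph$truth$clean_image$data)
  means <- phantom_spec(grid_shape = 32)$class_mean_intensities
  lab <- ph$truth$label_map$data
  for (k in seq_along(tissue_classes()))
    expect_true(all(ph$image$data[lab == k] ==
                      means[[tissue_classes()[k]]]))
  expect_true(all(ph$image$data[lab == 0] == 0))
})

test_that("discrete region volumes match analytic ellipsoid volumes", {
  # single cerebrum ellipsoid inside a head shell: no carving, so the
  # analytic 4/3 pi a b c volume applies directly
  semi <- c(0.55, 0.6, 0.5)
  geom <- list(
    list(name = "cerebrum", class = "cerebrum", priority = 1,
         center_frac = c(0, 0, 0), semiaxes_frac = semi),
    list(name = "head", class = "csf", priority = 2,
         center_frac = c(0, 0, 0), semiaxes_frac = c(0.9, 0.9, 0.9)))
  spec <- phantom_spec(grid_shape = 96, voxel_size_mm = 0.6,
                       region_geometry = geom, class_noise_sd = 0,
                       bias_amplitude = 1, deform_sd = 0)
  ph <- generate_phantom(spec)
  half <- (96 - 1) * 0.6 / 2
  ax <- semi * half
  analytic_mL <- 4 / 3 * pi * prod(ax) / 1000
  # tolerance: one voxel shell around the ellipsoid surface
  surface_mm2 <- 4 * pi * (prod(ax^1.6)^(1 / 3))^2  # Knud Thomsen approx via p=1.6
  shell_mL <- surface_mm2 * 0.6 / 1000
  expect_lt(abs(ph$truth$true_volumes_mL[["cerebrum"]] - analytic_mL),
            shell_mL)
})

test_that("identical specs give bit-identical phantoms; seeds only change noise", {
  spec <- phantom_spec(grid_shape = 24, seed = 9)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  c2 <- generate_phantom(phantom_spec(grid_shape = 24, seed = 10))
  expect_identical(a$truth$label_map$data, c2$truth$label_map$data)
  expect_false(identical(a$image$data, c2$image$data))
})

test_that("per-region volumes partition the head-mask volume", {
  tr <- phantom_default48()$truth
  v <- tr$true_volumes_mL
  expect_equal(sum(v[tissue_classes()]), v[["head"]], tolerance = 1e-12)
})

test_that("degenerate geometry is rejected with the region name", {
  geom <- default_region_geometry()
  geom[[5]]$semiaxes_frac <- c(2.5, 0.8, 0.68)   # cerebrum outside the grid
  expect_error(generate_phantom(phantom_spec(region_geometry = geom)),
               "cerebrum")
})

test_that("cohort: zero deformation duplicates the base; fixed seed reproduces", {
  spec0 <- phantom_spec(grid_shape = 24, deform_sd = 0, seed = 3)
  co <- generate_cohort(spec0, 3)
  expect_identical(co[[1]]$truth$label_map$data, co[[2]]$truth$label_map$data)
  expect_identical(co[[2]]$truth$label_map$data, co[[3]]$truth$label_map$data)
  spec1 <- phantom_spec(grid_shape = 24, deform_sd = 1.5, seed = 3)
  a <- generate_cohort(spec1, 2)
  b <- generate_cohort(spec1, 2)
  expect_identical(a[[2]]$image$data, b[[2]]$image$data)
  expect_false(identical(a[[1]]$truth$label_map$data,
                         a[[2]]$truth$label_map$data))
})

test_that("cohort volume spread grows with deformation magnitude", {
  cov_of <- function(sd_mm) {
    co <- generate_cohort(phantom_spec(grid_shape = 32, deform_sd = sd_mm,
                                       seed = 21), 6)
    v <- vapply(co, function(s) s$truth$true_volumes_mL[["cerebrum"]], 0)
    stats::sd(v) / mean(v)
  }
  expect_gt(cov_of(2.5), cov_of(0.5))
})

test_that("truth-derived atlas priors are one-hot at zero smoothing and normalized", {
  tr <- phantom_clean32()$truth
  atl0 <- atlas_from_truth(list(tr), smoothing_mm = 0)
  lab <- tr$label_map$data
  for (k in seq_along(tissue_classes())) {
    p <- atl0$priors[[tissue_classes()[k]]]$data
    expect_true(all(p[lab == k] == 1))
  }
  atl <- atlas_from_truth(list(tr), smoothing_mm = 1.2)
  total <- Reduce(`+`, lapply(atl$priors, function(p) p$data))
  inside <- atl$mask$data > 0
  expect_true(all(abs(total[inside] - 1) < 1e-10))
  expect_true(all(total[!inside] == 0))
})

test_that("increasing prior smoothing never sharpens the priors", {
  tr <- phantom_clean32()$truth
  maxima <- vapply(c(0, 1.2, 3), function(s) {
    atl <- atlas_from_truth(list(tr), smoothing_mm = s)
    max(vapply(atl$priors, function(p) max(p$data), 0))
  }, 0)
  expect_true(all(diff(maxima) <= 1e-12))
})

test_that("with equal cerebrum and CSF means the two regions are indistinguishable by intensity", {
  spec <- phantom_spec(grid_shape = 32,
                       class_mean_intensities = c(cerebrum = 900,
                                                  cerebellum = 420,
                                                  brainstem = 300,
                                                  csf = 900),
                       class_noise_sd = 0, bias_amplitude = 1,
                       deform_sd = 0)
  ph <- generate_phantom(spec)
  lab <- ph$truth$label_map$data
  expect_identical(unique(ph$image$data[lab == 1]),
                   unique(ph$image$data[lab == 4]))
})
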