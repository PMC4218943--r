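# small cohort + groupwise atlas, shared across tests below
groupwise_fixture <- function() fixture("groupwise", function() {
  spec <- phantom_spec(grid_shape = 48, seed = 15, deform_sd = 1.2,
                       bias_amplitude = 1)
  cohort <- generate_cohort(spec, 5)
  segs <- lapply(cohort, function(s) {
    atl <- atlas_from_truth(list(s$truth), smoothing_mm = 1.2)
    em_segment(s$image, atl$priors, s$truth$head_mask)
  })
  atlas <- suppressWarnings(build_groupwise_atlas(
    images = lapply(cohort, `[[`, "image"),
    segmentations = segs,
    masks = lapply(cohort, function(s) s$truth$head_mask),
    schedule = atlas_schedule(1, 2, 2),
    params = reg_params(bspline_iterations = 30)))
  list(spec = spec, cohort = cohort, segs = segs, atlas = atlas)
})

test_that("a cohort of identical subjects averages to itself", {
  ph <- phantom_default48()
  atl0 <- atlas48()
  seg <- em_segment(ph$image, atl0$priors, ph$truth$head_mask)
  atlas <- suppressWarnings(build_groupwise_atlas(
    images = list(ph$image, ph$image),
    segmentations = list(seg, seg),
    masks = list(ph$truth$head_mask, ph$truth$head_mask),
    schedule = "rigid"))
  inner <- ph$truth$head_mask$data > 0
  expect_gt(stats::cor(atlas$template$data[inner], ph$image$data[inner]),
            0.999)
  inside <- atlas$mask$data > 0
  for (cl in tissue_classes()) {
    d <- abs(atlas$priors[[cl]]$data - seg$posteriors[[cl]]$data)
    expect_lt(stats::median(d[inside]), 0.02)
  }
})

test_that("registering an affine copy sharpens the average", {
  ph <- generate_phantom(phantom_spec(grid_shape = 32, seed = 16,
                                      bias_amplitude = 1))
  M <- diag(4); M[1:3, 4] <- c(2.4, -1.2, 0.6); M[1, 1] <- 1.08
  copy <- resample(ph$image, tf_affine(M), ph$image)
  atl0 <- atlas_from_truth(list(ph$truth), smoothing_mm = 1.2)
  seg <- em_segment(ph$image, atl0$priors, ph$truth$head_mask)
  grad_energy <- function(img) {
    g <- pmbrainvol:::cpp_gradient3d(as.numeric(img), dim(img))
    sum(g^2)
  }
  naive <- (ph$image$data + copy$data) / 2
  atlas <- suppressWarnings(build_groupwise_atlas(
    images = list(ph$image, copy),
    segmentations = list(seg, seg),
    masks = list(ph$truth$head_mask, ph$truth$head_mask),
    schedule = atlas_schedule(1, 2, 0)))
  expect_gt(grad_energy(atlas$template$data), grad_energy(naive))
})

test_that("groupwise priors recover the truth-derived atlas of the base geometry", {
  gw <- groupwise_fixture()
  base_truth <- generate_phantom(phantom_spec(
    grid_shape = 48, seed = 15, deform_sd = 0, class_noise_sd = 0,
    bias_amplitude = 1))$truth
  ref <- atlas_from_truth(list(base_truth), smoothing_mm = 0)
  # the groupwise template lives in its own average space (the mean of a
  # few random warps is not exactly zero), so align it to the reference
  # atlas before comparing priors at the 0.5-threshold
  tfa <- register(ref$template, gw$atlas$template, "affine")
  tf <- suppressWarnings(register(ref$template, gw$atlas$template,
                                  "bspline", init = tfa))
  for (cl in tissue_classes()) {
    moved <- resample(gw$atlas$priors[[cl]], tf, ref$template)
    a <- with_data(ref$mask, as.integer(moved$data > 0.5))
    b <- with_data(ref$mask, as.integer(ref$priors[[cl]]$data > 0.5))
    expect_gt(dice(a, b, 1), 0.85)
  }
})

test_that("template change diagnostic shrinks below tolerance across rounds", {
  gw <- groupwise_fixture()
  change <- gw$atlas$provenance$template_change
  rng <- diff(range(gw$atlas$template$data))
  expect_lt(change[length(change)], 0.05 * rng)
  expect_lt(change[length(change)], change[1])
})

test_that("replaying the stored transforms reproduces the atlas priors bit-identically", {
  gw <- groupwise_fixture()
  tfs <- attr(gw$atlas, "transforms")
  prior_sum <- NULL
  for (s in seq_along(tfs)) {
    prop <- propagate_to_average(gw$segs[[s]]$posteriors, tfs[[s]],
                                 gw$atlas)
    add <- lapply(prop, function(p) p$data)
    prior_sum <- if (is.null(prior_sum)) add
                 else Map(`+`, prior_sum, add)
  }
  maskarr <- gw$atlas$mask$data > 0
  total <- Reduce(`+`, prior_sum)
  for (cl in tissue_classes()) {
    p <- prior_sum[[cl]]
    p[maskarr] <- p[maskarr] / pmax(total[maskarr], .Machine$double.eps)
    p[!maskarr] <- 0
    expect_identical(p, gw$atlas$priors[[cl]]$data)
  }
})

test_that("propagated posteriors stay normalized on the atlas grid", {
  gw <- groupwise_fixture()
  tfs <- attr(gw$atlas, "transforms")
  prop <- propagate_to_average(gw$segs[[1]]$posteriors, tfs[[1]], gw$atlas)
  total <- Reduce(`+`, lapply(prop, function(p) p$data))
  expect_lte(max(total), 1 + 1e-10)
})

test_that("the builder refuses degenerate cohorts", {
  ph <- phantom_clean32()
  seg <- em_segment(ph$image, atlas_from_truth(list(ph$truth), 1.2)$priors,
                    ph$truth$head_mask)
  expect_error(build_groupwise_atlas(list(ph$image), list(seg),
                                     list(ph$truth$head_mask)),
               "n >= 2")
})
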