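flat_priors <- function(image, k, classes) {
  stats::setNames(lapply(seq_len(k), function(j) with_data(image, 1 / k)),
                  classes)
}

test_that("pure EM recovers well-separated class means within 1%", {
  dims <- c(12, 12, 12)
  set.seed(5)
  truth <- array(sample(1:2, prod(dims), replace = TRUE), dim = dims)
  y <- ifelse(truth == 1, 200, 800) + stats::rnorm(prod(dims), sd = 30)
  img <- vol3d(array(y, dim = dims))
  mask <- with_data(img, 1)
  res <- em_segment(img, flat_priors(img, 2, c("a", "b")), mask,
                    em_params(mrf_beta = 0, relaxation_alpha = 0))
  expect_lt(abs(res$class_params$mean[1] - 200) / 200, 0.01)
  expect_lt(abs(res$class_params$mean[2] - 800) / 800, 0.01)
})

test_that("the pure-EM objective is non-decreasing every iteration", {
  ph <- generate_phantom(phantom_spec(grid_shape = 24, seed = 6))
  atl <- atlas_from_truth(list(generate_phantom(
    phantom_spec(grid_shape = 24, seed = 6, class_noise_sd = 0,
                 bias_amplitude = 1))$truth), smoothing_mm = 1.2)
  res <- em_segment(ph$image, atl$priors, ph$truth$head_mask,
                    em_params(mrf_beta = 0, relaxation_alpha = 0))
  tol <- 1e-9 * max(abs(res$objective_trace))
  expect_true(all(diff(res$objective_trace) > -tol))
})

test_that("E/M updates match an independent brute-force EM to 1e-10", {
  dims <- c(8, 8, 8)
  n <- prod(dims)
  set.seed(8)
  y <- c(stats::rnorm(n / 2, 300, 40), stats::rnorm(n / 2, 700, 60))
  img <- vol3d(array(y, dim = dims))
  mask <- with_data(img, 1)
  pr <- matrix(stats::runif(n * 3, 0.1, 1), n, 3)
  pr <- pr / rowSums(pr)
  priors <- stats::setNames(lapply(1:3, function(j)
    with_data(img, pr[, j])), c("a", "b", "c"))
  n_iter <- 6
  res <- em_segment(img, priors, mask,
                    em_params(max_iterations = n_iter, tolerance = 1e-300,
                              mrf_beta = 0, relaxation_alpha = 0))
  # same deterministic moment initialization as the implementation
  mu0 <- colSums(pr * y) / colSums(pr)
  sig0 <- colSums(pr * (outer(y, mu0, `-`))^2) / colSums(pr)
  bf <- brute_force_em(y, pr, mu0, sig0, n_iter)
  expect_lt(max(abs(res$class_params$mean - bf$mu)), 1e-10)
  expect_lt(max(abs(res$class_params$sd^2 - bf$sig2) / bf$sig2), 1e-10)
  post <- vapply(res$posteriors, function(p) as.numeric(p$data), numeric(n))
  expect_lt(max(abs(post - bf$posteriors)), 1e-10)
  expect_lt(max(abs(res$objective_trace - bf$trace)), 1e-6)
})

test_that("the MRF suppresses isolated single-voxel islands", {
  ph <- generate_phantom(phantom_spec(grid_shape = 32, class_noise_sd = 90,
                                      bias_amplitude = 1, seed = 14))
  atl <- atlas_from_truth(list(generate_phantom(
    phantom_spec(grid_shape = 32, class_noise_sd = 0, bias_amplitude = 1,
                 seed = 14))$truth), smoothing_mm = 1.2)
  islands <- function(beta) {
    res <- em_segment(ph$image, atl$priors, ph$truth$head_mask,
                      em_params(mrf_beta = beta, relaxation_alpha = 0))
    lab <- res$hard_labels$data
    dims <- dim(lab)
    same <- array(0L, dims)
    shift <- function(a, ax, by) {
      idx <- lapply(dims, seq_len)
      src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), dims[ax])
      a[src[[1]], src[[2]], src[[3]]]
    }
    neigh_same <- array(FALSE, dims)
    for (ax in 1:3) for (by in c(-1, 1))
      neigh_same <- neigh_same | (shift(lab, ax, by) == lab)
    sum(!neigh_same & lab > 0)
  }
  expect_lt(islands(0.5), islands(0))
})

test_that("merging classes conserves posteriors and re-takes the argmax", {
  ph <- phantom_default48()
  atl <- atlas48()
  res <- em_segment(correct_bias(ph$image,
                                 estimate_bias_field(ph$image,
                                                     ph$truth$head_mask)),
                    atl$priors, ph$truth$head_mask)
  identity_groups <- stats::setNames(as.list(tissue_classes()),
                                     tissue_classes())
  same <- merge_classes(res, identity_groups)
  expect_identical(as.integer(same$data),
                   as.integer(res$hard_labels$data))
  merged <- merge_classes(res)
  post <- attr(merged, "posteriors")
  total <- Reduce(`+`, lapply(post, function(p) p$data))
  inside <- res$hard_labels$data > 0
  expect_true(all(abs(total[inside] - 1) < 1e-10))
  expect_error(merge_classes(res, list(a = c("cerebrum", "csf"))),
               "partition")
})

test_that("a voxel split 0.3/0.3/0.4 flips from cerebellum to the merged class", {
  # hand-computed argmax before and after merging
  dims <- c(2, 1, 1)
  mk <- function(v) vol3d(array(v, dim = dims))
  post <- list(cerebrum = mk(c(0.3, 0.25)), cerebellum = mk(c(0.4, 0.3)),
               brainstem = mk(c(0, 0.45)), csf = mk(c(0.3, 0)))
  res <- structure(list(
    posteriors = post,
    hard_labels = vol3d(array(c(2L, 3L), dim = dims)),
    class_params = data.frame()), class = "segmentation_result")
  merged <- merge_classes(res)
  expect_identical(as.integer(merged$data), c(1L, 3L))
})

test_that("with collapsed cerebrum/CSF contrast the merged labels stay stable across noise seeds", {
  collapsed <- function(seed) {
    spec <- phantom_spec(grid_shape = 32,
                         class_mean_intensities = c(cerebrum = 880,
                                                    cerebellum = 420,
                                                    brainstem = 300,
                                                    csf = 900),
                         bias_amplitude = 1, seed = seed)
    ph <- generate_phantom(spec)
    atl <- atlas_from_truth(list(generate_phantom(
      phantom_spec(grid_shape = 32, class_noise_sd = 0, bias_amplitude = 1,
                   seed = seed))$truth), smoothing_mm = 1.2)
    res <- em_segment(ph$image, atl$priors, ph$truth$head_mask)
    merge_classes(res)
  }
  a <- collapsed(31)
  b <- collapsed(32)   # same geometry, different noise realization
  expect_gt(dice(a, b, 1), 0.98)
  expect_gt(dice(a, b, 2), 0.9)
})
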