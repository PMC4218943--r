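# Shared fixtures, built once per test run and cached. All phantom-based:
# no data files are required.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# clean 32^3 phantom, no noise/bias/texture
phantom_clean32 <- function() fixture("clean32", function() {
  generate_phantom(phantom_spec(grid_shape = 32, class_noise_sd = 0,
                                bias_amplitude = 1, deform_sd = 0,
                                seed = 1))
})

# default-condition 48^3 phantom (noise 30, bias 1.3)
phantom_default48 <- function() fixture("default48", function() {
  generate_phantom(phantom_spec(grid_shape = 48, seed = 7))
})

# truth-derived atlas for the default 48^3 geometry
atlas48 <- function() fixture("atlas48", function() {
  atlas_from_truth(list(phantom_default48()$truth), smoothing_mm = 1.2)
})

# independent brute-force EM (pure Gaussian mixture with per-voxel priors):
# loops over voxels and classes, no vectorized shortcuts shared with the
# package implementation
brute_force_em <- function(y, priors, mu, sig2, n_iter) {
  n <- length(y)
  k <- ncol(priors)
  post <- matrix(0, n, k)
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    ll <- 0
    for (i in seq_len(n)) {
      w <- numeric(k)
      for (j in seq_len(k))
        w[j] <- priors[i, j] *
          exp(-(y[i] - mu[j])^2 / (2 * sig2[j])) / sqrt(2 * pi * sig2[j])
      ll <- ll + log(sum(w))
      post[i, ] <- w / sum(w)
    }
    trace[it] <- ll
    for (j in seq_len(k)) {
      tot <- 0; m1 <- 0
      for (i in seq_len(n)) { tot <- tot + post[i, j]; m1 <- m1 + post[i, j] * y[i] }
      mu[j] <- m1 / tot
      v <- 0
      for (i in seq_len(n)) v <- v + post[i, j] * (y[i] - mu[j])^2
      sig2[j] <- v / tot
    }
  }
  list(posteriors = post, mu = mu, sig2 = sig2, trace = trace)
}

# brute-force Dice via explicit voxel index sets
brute_force_dice <- function(a, b, label) {
  A <- which(as.numeric(a$data) == label)
  B <- which(as.numeric(b$data) == label)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# known-warp fixture: textured phantom warped by a smooth random field
# (texture makes the warp identifiable away from tissue boundaries)
warp_fixture <- function() fixture("warp48", function() {
  base <- generate_phantom(phantom_spec(
    grid_shape = 48, seed = 11, class_noise_sd = 20, bias_amplitude = 1,
    texture_amplitude = 80, deform_sd = 0))
  dims <- dim(base$image$data)
  mask <- base$truth$head_mask$data > 0
  u <- pmbrainvol:::with_seed(42, pmbrainvol:::random_deformation(
    dims, 0.6, 1.5, mask))
  vox <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                               y = seq_len(dims[2]) - 1,
                               z = seq_len(dims[3]) - 1))
  p <- vox + matrix(u, ncol = 3) / 0.6
  warped <- with_data(base$image, pmbrainvol:::cpp_sample_volume(
    as.numeric(base$image$data), as.integer(dims),
    p[, 1], p[, 2], p[, 3], FALSE, 0))
  list(base = base, u = matrix(u, ncol = 3), warped = warped, mask = mask)
})
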