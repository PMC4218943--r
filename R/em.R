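#' EM segmentation settings
#'
#' @param max_iterations iteration budget.
#' @param tolerance relative change of the objective that stops iteration.
#' @param mrf_beta Potts coupling strength of the mean-field Markov random
#'   field on the 6-connected neighbourhood (>= 0; 0 disables the MRF).
#' @param relaxation_alpha prior-relaxation weight in `[0, 1]`: each
#'   iteration the effective prior becomes
#'   `(1 - alpha) * atlas_prior + alpha * smoothed(posterior)`.
#' @param relaxation_sigma spatial smoothing of the relaxed priors, voxels.
#' @export
em_params <- function(max_iterations = 100L, tolerance = 1e-5,
                      mrf_beta = 0.5, relaxation_alpha = 0.2,
                      relaxation_sigma = 2) {
  stopifnot(max_iterations >= 1, tolerance > 0, mrf_beta >= 0,
            relaxation_alpha >= 0, relaxation_alpha <= 1,
            relaxation_sigma >= 0)
  list(max_iterations = as.integer(max_iterations), tolerance = tolerance,
       mrf_beta = mrf_beta, relaxation_alpha = relaxation_alpha,
       relaxation_sigma = relaxation_sigma)
}

#' Expectation-maximization tissue segmentation with atlas priors
#'
#' Gaussian class-conditional intensity model with per-voxel atlas priors,
#' prior relaxation and a mean-field Potts MRF. Each iteration: the E-step
#' computes class responsibilities from Gaussian likelihoods x effective
#' priors x `exp(beta * sum of neighbour posteriors)`; the M-step updates
#' class means and variances from the responsibilities; the relaxation
#' step blends the atlas priors with Gaussian-smoothed current posteriors.
#' Initialization is deterministic: class parameters from prior-weighted
#' intensity moments. With `mrf_beta = 0` and `relaxation_alpha = 0` this
#' is exact EM for a Gaussian mixture with spatially varying priors and
#' the objective (incomplete-data log-likelihood) is non-decreasing.
#'
#' @param image a [vol3d()].
#' @param priors named list of [vol3d()] prior volumes on the image grid;
#'   per-voxel sum must be positive inside the mask.
#' @param mask a [vol3d()]; nonzero voxels are segmented.
#' @param params an [em_params()] list.
#' @return A `segmentation_result`: `posteriors` (named list of
#'   [vol3d()]), `hard_labels` (a [vol3d()]; argmax with ties to the
#'   lowest class index, 0 outside the mask), `class_params`
#'   (data.frame of class intensity means/SDs), `mixing` (effective
#'   priors after relaxation), `n_iterations`, `converged`,
#'   `objective_trace`.
#' @export
em_segment <- function(image, priors, mask, params = em_params()) {
  if (length(priors) < 2) stop("need at least 2 classes")
  for (p in priors) stop_if_grid_mismatch(image, p, "image and priors")
  stop_if_grid_mismatch(image, mask, "image and mask")
  dims <- dim(image$data)
  nvox <- prod(dims)
  k <- length(priors)
  cls <- names(priors)
  inside <- as.numeric(mask$data) > 0
  midx <- which(inside)
  y <- as.numeric(image$data)[midx]
  if (any(!is.finite(y))) stop("non-finite intensities inside the mask")
  P <- vapply(priors, function(p) as.numeric(p$data)[midx],
              numeric(length(midx)))
  psum <- rowSums(P)
  if (any(psum <= 0))
    stop("priors sum to zero at ", sum(psum <= 0), " voxel(s) inside the mask")
  P <- P / psum
  Peff <- P
  w <- P
  mu <- colSums(w * y) / colSums(w)
  sig2 <- colSums(w * (outer(y, mu, `-`))^2) / colSums(w)
  if (diff(range(mu)) < 1e-6 * max(diff(range(y)), 1)) {
    # spatially uniform priors make all moment-initialized classes
    # identical and EM cannot break the symmetry; fall back to intensity
    # quantiles (deterministic)
    mu <- stats::quantile(y, probs = (seq_len(k) * 2 - 1) / (2 * k),
                          names = FALSE)
    sig2 <- rep(stats::var(y) / k, k)
  }
  var_floor <- max(stats::var(y), .Machine$double.eps) * 1e-8
  sig2 <- pmax(sig2, var_floor)
  sigma_vox <- rep(params$relaxation_sigma, 3)
  post <- w
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  post_full <- matrix(0, nvox, k)   # posteriors on the full grid for MRF
  while (it < params$max_iterations) {
    it <- it + 1L
    logw <- matrix(0, length(midx), k)
    if (params$mrf_beta > 0) {
      post_full[midx, ] <- post
      S <- cpp_neighbour_sum(as.numeric(post_full), dims, k)
      S <- matrix(S, nvox, k)[midx, , drop = FALSE]
    } else S <- NULL
    for (j in seq_len(k)) {
      logw[, j] <- log(pmax(Peff[, j], 1e-300)) +
        stats::dnorm(y, mu[j], sqrt(sig2[j]), log = TRUE)
      if (!is.null(S)) logw[, j] <- logw[, j] + params$mrf_beta * S[, j]
    }
    mx <- do.call(pmax, as.data.frame(logw))
    wexp <- exp(logw - mx)
    norm <- rowSums(wexp)
    post <- wexp / norm
    obj <- sum(mx + log(norm))
    trace <- c(trace, obj)
    # M-step
    tot <- colSums(post)
    starved <- tot < 1e-8
    if (any(starved))
      warning("class(es) with vanishing responsibility: ",
              paste(cls[starved], collapse = ", "),
              " (variance floored, class retained)")
    for (j in seq_len(k)) {
      if (starved[j]) { sig2[j] <- max(sig2[j], var_floor); next }
      mu[j] <- sum(post[, j] * y) / tot[j]
      sig2[j] <- max(sum(post[, j] * (y - mu[j])^2) / tot[j], var_floor)
    }
    # prior relaxation
    if (params$relaxation_alpha > 0) {
      sm <- matrix(0, length(midx), k)
      tmp <- numeric(nvox)
      for (j in seq_len(k)) {
        tmp[] <- 0; tmp[midx] <- post[, j]
        sm[, j] <- cpp_gauss_smooth(tmp, dims, sigma_vox)[midx]
      }
      sm <- sm / pmax(rowSums(sm), .Machine$double.eps)
      Peff <- (1 - params$relaxation_alpha) * P + params$relaxation_alpha * sm
      Peff <- Peff / rowSums(Peff)
    }
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
          params$tolerance * abs(trace[it - 1])) {
      converged <- TRUE
      break
    }
  }
  to_vol <- function(colmat, j) {
    a <- numeric(nvox); a[midx] <- colmat[, j]
    vol3d(array(a, dim = dims), image$spacing)
  }
  posteriors <- stats::setNames(lapply(seq_len(k), function(j)
    to_vol(post, j)), cls)
  mixing <- stats::setNames(lapply(seq_len(k), function(j)
    to_vol(Peff, j)), cls)
  hard <- integer(nvox)
  hard[midx] <- max.col(post, ties.method = "first")
  structure(list(
    posteriors = posteriors,
    hard_labels = vol3d(array(hard, dim = dims), image$spacing),
    class_params = data.frame(class = cls, mean = mu, sd = sqrt(sig2),
                              row.names = NULL),
    mixing = mixing, n_iterations = it, converged = converged,
    objective_trace = trace), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d classes, %d iteration(s)%s\n",
              length(x$posteriors), x$n_iterations,
              if (x$converged) ", converged" else ""))
  print(x$class_params)
  invisible(x)
}

#' Merge segmentation classes
#'
#' Sums posteriors within each group and re-takes the argmax. The default
#' grouping collapses cerebrum and CSF (inseparable post mortem) while
#' keeping cerebellum and brainstem.
#'
#' @param result a `segmentation_result`.
#' @param groups named list partitioning the class set; output label codes
#'   follow the group order.
#' @return A [vol3d()] label map of merged codes (0 outside the mask),
#'   with attribute `posteriors`: the named list of merged posterior
#'   volumes.
#' @export
merge_classes <- function(result, groups = default_merge_groups()) {
  cls <- names(result$posteriors)
  check_partition(groups, cls)
  merged <- lapply(groups, function(members)
    Reduce(`+`, lapply(result$posteriors[members], function(p) p$data)))
  dims <- dim(result$hard_labels$data)
  post <- vapply(merged, as.numeric, numeric(prod(dims)))
  inside <- as.numeric(result$hard_labels$data) > 0
  hard <- integer(prod(dims))
  hard[inside] <- max.col(post[inside, , drop = FALSE], ties.method = "first")
  g <- result$hard_labels
  out <- with_data(g, hard)
  attr(out, "posteriors") <- lapply(merged, function(m)
    vol3d(m, g$spacing))
  out
}
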