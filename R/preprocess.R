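#' Estimate a smooth multiplicative bias field
#'
#' Log-domain weighted least-squares fit of a low-order tensor-polynomial
#' basis to within-mask log-intensities. Tissue structure is kept out of
#' the field by interleaving a k-means tissue classification with the fit:
#' at each round the current field is removed, voxels are classified into
#' `n_classes` intensity clusters (deterministic quantile-seeded k-means),
#' the per-class log-means are subtracted, and the basis is refit to the
#' residual. The returned field is normalized to mean 1 inside the mask so
#' correction preserves mean brightness (volumetry thresholds stay
#' comparable across subjects).
#'
#' @param image a [vol3d()] with positive intensities inside the mask.
#' @param mask a [vol3d()]; nonzero voxels define the fit domain.
#' @param order per-axis polynomial degree of the basis.
#' @param n_classes intensity clusters removed during the fit.
#' @param max_iterations classification/fit rounds.
#' @param sample_max at most this many mask voxels (deterministic stride
#'   subsample) enter the least-squares fit.
#' @return A `bias_field`: list with `field` (a [vol3d()], strictly
#'   positive) and `model_order`.
#' @export
estimate_bias_field <- function(image, mask, order = 2L, n_classes = 6L,
                                max_iterations = 8L, sample_max = 60000L) {
  stop_if_grid_mismatch(image, mask, "image and mask")
  idx <- which(mask$data > 0)
  if (length(idx) == 0) stop("mask is empty: no voxels to fit the bias field")
  y <- image$data[idx]
  if (any(y <= 0))
    stop("non-positive intensities inside the mask: log-domain fit undefined")
  logy <- log(y)
  dims <- dim(image$data)
  fit_idx <- idx[unique(round(seq(1, length(idx),
                                  length.out = min(length(idx), sample_max))))]
  basis_full <- polynomial_basis(dims, order = as.integer(order))
  X <- basis_full[fit_idx, , drop = FALSE]
  XtX <- crossprod(X)
  logy_fit <- log(image$data[fit_idx])
  f_full <- numeric(prod(dims))
  for (it in seq_len(max_iterations)) {
    r <- logy_fit - f_full[fit_idx]
    cl <- classify_1d(r, n_classes)
    resid <- logy_fit - cl$centers[cl$cluster]
    beta <- solve(XtX, crossprod(X, resid))
    f_new <- as.numeric(basis_full %*% beta)
    delta <- max(abs(f_new[idx] - f_full[idx]))
    f_full <- f_new
    if (delta < 1e-5) break
  }
  field <- exp(array(f_full, dim = dims))
  field <- field / mean(field[idx])
  structure(list(field = vol3d(field, image$spacing),
                 model_order = as.integer(order)),
            class = "bias_field")
}

# deterministic 1-D Lloyd clustering: centers seeded equally spaced across
# the trimmed value range; clusters that empty out keep their center (so a
# generous n_classes over-segments harmlessly instead of failing)
classify_1d <- function(x, k, iterations = 30L) {
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  centers <- q[1] + (seq_len(k) * 2 - 1) / (2 * k) * (q[2] - q[1])
  cluster <- NULL
  for (it in seq_len(iterations)) {
    cluster <- max.col(-abs(outer(x, centers, `-`)), ties.method = "first")
    new_centers <- vapply(seq_len(k), function(j) {
      xs <- x[cluster == j]
      if (length(xs)) mean(xs) else centers[j]
    }, 0)
    if (max(abs(new_centers - centers)) < 1e-10) { centers <- new_centers; break }
    centers <- new_centers
  }
  list(cluster = cluster, centers = centers)
}

#' Remove a multiplicative bias field
#'
#' Voxelwise division of the image by the field; metadata preserved.
#' @param image a [vol3d()].
#' @param field a `bias_field` from [estimate_bias_field()] (or a
#'   [vol3d()] of gains).
#' @export
correct_bias <- function(image, field) {
  fvol <- if (inherits(field, "bias_field")) field$field else field
  stop_if_grid_mismatch(image, fvol, "image and bias field")
  with_data(image, image$data / fvol$data)
}

#' Propagate the atlas brain mask onto a target grid
#'
#' Nearest-neighbour resampling of the atlas mask through a transform that
#' maps target space to atlas space (typically obtained by registering the
#' target image to the atlas template).
#' @param atlas a `probabilistic_atlas`.
#' @param transform a `transform` mapping target space to atlas space.
#' @param target_grid a [vol3d()] defining the output grid.
#' @export
propagate_mask <- function(atlas, transform, target_grid) {
  resample(atlas$mask, transform, target_grid, interpolation = "nearest")
}

#' Ingest an externally edited brain mask
#'
#' Stands in for interactive mask correction: the edited mask replaces the
#' original and the voxel-level difference is reported.
#' @param mask,edits [vol3d()] masks on the same grid.
#' @return `edits`, with attribute `diff` = `c(added =, removed =)`.
#' @export
apply_mask_edits <- function(mask, edits) {
  stop_if_grid_mismatch(mask, edits, "mask and edits")
  a <- mask$data > 0
  b <- edits$data > 0
  added <- sum(b & !a)
  removed <- sum(a & !b)
  if (!any(b)) warning("edited mask is empty")
  message("mask edits: ", added, " voxel(s) added, ", removed, " removed")
  structure(edits, diff = c(added = added, removed = removed))
}
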