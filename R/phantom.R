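#' Specification of a synthetic post-mortem brain phantom
#'
#' Describes a 3D phantom built from nested ellipsoids: a head envelope
#' filled with CSF, a cerebrum with ventricular CSF pockets, a cerebellum
#' and a brainstem. Ellipsoids have analytic volumes, which gives every
#' downstream volume computation an exact oracle. Intensities emulate a
#' heavily T2-weighted post-mortem acquisition: CSF bright, tissue darker,
#' with the cerebrum mean settable arbitrarily close to the CSF mean to
#' reproduce the post-mortem contrast collapse (T1/T2 converging toward
#' free-water values).
#'
#' @param grid_shape integer length-3 (or 1, recycled), voxels per axis.
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @param region_geometry list of regions as produced by
#'   [default_region_geometry()]; each region has `name`, `class`,
#'   `center_frac`, `semiaxes_frac` (fractions of the grid half-extent) and
#'   `priority` (lower wins where regions overlap on the voxel grid).
#' @param class_mean_intensities named numeric, expected signal per tissue
#'   class (dimensionless).
#' @param class_noise_sd additive Gaussian noise SD (scalar).
#' @param texture_amplitude SD of a smooth intra-tissue intensity texture
#'   added to the clean image inside the head (0 = piecewise-constant
#'   tissue). Texture is anatomy: it is generated once per phantom and
#'   deforms with the subject, which is what makes non-rigid registration
#'   of the phantom identifiable away from tissue boundaries.
#' @param texture_smooth_vox correlation length of the texture, voxels.
#' @param bias_amplitude peak-to-trough ratio of the multiplicative bias
#'   field (>= 1; 1 disables bias).
#' @param deform_sd RMS displacement magnitude (mm) of the random smooth
#'   warps used for cohort variation.
#' @param seed RNG seed; identical specs give bit-identical phantoms.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = 0.6,
                         region_geometry = default_region_geometry(),
                         class_mean_intensities = c(cerebrum = 600,
                                                    cerebellum = 420,
                                                    brainstem = 300,
                                                    csf = 900),
                         class_noise_sd = 30,
                         texture_amplitude = 0,
                         texture_smooth_vox = 3,
                         bias_amplitude = 1.3,
                         deform_sd = 1.5,
                         seed = 1L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (any(grid_shape < 8L)) stop("grid_shape must be at least 8 voxels per axis")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (class_noise_sd < 0) stop("class_noise_sd must be >= 0")
  if (texture_amplitude < 0) stop("texture_amplitude must be >= 0")
  if (bias_amplitude < 1) stop("bias_amplitude must be >= 1")
  if (deform_sd < 0) stop("deform_sd must be >= 0")
  missing <- setdiff(tissue_classes(), names(class_mean_intensities))
  if (length(missing))
    stop("class_mean_intensities missing classes: ",
         paste(missing, collapse = ", "))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 region_geometry = region_geometry,
                 class_mean_intensities = class_mean_intensities,
                 class_noise_sd = class_noise_sd,
                 texture_amplitude = texture_amplitude,
                 texture_smooth_vox = texture_smooth_vox,
                 bias_amplitude = bias_amplitude,
                 deform_sd = deform_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default nested-ellipsoid brain geometry
#'
#' Fractions are of the grid half-extent, so the same geometry scales to any
#' grid size. Overlaps are resolved by priority: brainstem > cerebellum >
#' ventricular CSF > cerebrum > surrounding CSF (small structures win).
#' @export
default_region_geometry <- function() {
  list(
    list(name = "brainstem", class = "brainstem", priority = 1,
         center_frac = c(0, -0.12, -0.50),
         semiaxes_frac = c(0.13, 0.13, 0.30)),
    list(name = "cerebellum", class = "cerebellum", priority = 2,
         center_frac = c(0, -0.42, -0.48),
         semiaxes_frac = c(0.34, 0.25, 0.22)),
    list(name = "ventricle_left", class = "csf", priority = 3,
         center_frac = c(-0.18, 0.08, 0.18),
         semiaxes_frac = c(0.10, 0.26, 0.10)),
    list(name = "ventricle_right", class = "csf", priority = 3,
         center_frac = c(0.18, 0.08, 0.18),
         semiaxes_frac = c(0.10, 0.26, 0.10)),
    list(name = "cerebrum", class = "cerebrum", priority = 4,
         center_frac = c(0, 0.03, 0.10),
         semiaxes_frac = c(0.78, 0.80, 0.68)),
    list(name = "head", class = "csf", priority = 5,
         center_frac = c(0, 0, 0),
         semiaxes_frac = c(0.92, 0.92, 0.90))
  )
}

# voxel-centre world coordinates (mm) relative to the grid centre, one
# matrix column per axis
phantom_coords <- function(grid_shape, voxel_size_mm) {
  half <- (grid_shape - 1) * voxel_size_mm / 2
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * voxel_size_mm - half[a])
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]], half = half)
}

phantom_label_map <- function(spec) {
  co <- phantom_coords(spec$grid_shape, spec$voxel_size_mm)
  classes <- tissue_classes()
  regions <- spec$region_geometry[order(vapply(spec$region_geometry,
                                               `[[`, 0, "priority"))]
  labels <- array(0L, dim = spec$grid_shape)
  head_mask <- array(FALSE, dim = spec$grid_shape)
  extent <- (spec$grid_shape - 1) * spec$voxel_size_mm
  for (rg in rev(regions)) {   # low priority first, high priority overwrites
    ctr <- rg$center_frac * co$half
    ax <- rg$semiaxes_frac * co$half
    if (any(ax <= 0) || any(abs(ctr) + ax > extent / 2 + spec$voxel_size_mm))
      stop("degenerate geometry: region '", rg$name,
           "' lies outside the grid or has non-positive semi-axes")
    d2 <- outer(outer(((co$x - ctr[1]) / ax[1])^2,
                      ((co$y - ctr[2]) / ax[2])^2, `+`),
                ((co$z - ctr[3]) / ax[3])^2, `+`)
    inside <- d2 <= 1
    labels[inside] <- match(rg$class, classes)
    head_mask <- head_mask | inside
  }
  list(labels = labels, head_mask = head_mask)
}

# smooth multiplicative bias field: random degree-2 tensor polynomial in
# the log domain, scaled to the requested peak-to-trough ratio and unit
# geometric mean inside the mask
phantom_bias_field <- function(spec, mask) {
  if (spec$bias_amplitude == 1)
    return(array(1, dim = spec$grid_shape))
  basis <- polynomial_basis(spec$grid_shape, order = 2L)
  beta <- stats::rnorm(ncol(basis))
  beta[1] <- 0
  f <- array(basis %*% beta, dim = spec$grid_shape)
  rng <- max(f[mask]) - min(f[mask])
  f <- f * log(spec$bias_amplitude) / rng
  f <- f - mean(f[mask])
  exp(f)
}

# per-axis-degree <= order tensor polynomial basis on [-1, 1]^3 coordinates,
# column 1 the constant term
polynomial_basis <- function(grid_shape, order = 2L) {
  ax <- lapply(grid_shape, function(n) seq(-1, 1, length.out = n))
  pow <- function(v, k) v^k
  degs <- expand.grid(dx = 0:order, dy = 0:order, dz = 0:order)
  degs <- degs[order(degs$dx + degs$dy + degs$dz), , drop = FALSE]
  n <- prod(grid_shape)
  out <- matrix(0, n, nrow(degs))
  gx <- rep(ax[[1]], times = grid_shape[2] * grid_shape[3])
  gy <- rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3])
  gz <- rep(ax[[3]], each = grid_shape[1] * grid_shape[2])
  for (i in seq_len(nrow(degs)))
    out[, i] <- pow(gx, degs$dx[i]) * pow(gy, degs$dy[i]) * pow(gz, degs$dz[i])
  out
}

# smooth intra-tissue intensity texture inside the head mask (0 if disabled)
phantom_texture <- function(spec, head_mask) {
  if (spec$texture_amplitude == 0) return(0)
  dims <- as.integer(spec$grid_shape)
  tex <- cpp_gauss_smooth(stats::rnorm(prod(dims)), dims,
                          rep(spec$texture_smooth_vox, 3))
  tex <- tex / stats::sd(tex[head_mask]) * spec$texture_amplitude
  array(tex, dim = dims) * head_mask
}

phantom_truth <- function(spec, labels, head_mask, bias, clean) {
  voxvol_mL <- spec$voxel_size_mm^3 / 1000
  classes <- tissue_classes()
  counts <- vapply(seq_along(classes),
                   function(k) sum(labels == k), 0)
  vols <- c(stats::setNames(counts * voxvol_mL, classes),
            head = sum(head_mask) * voxvol_mL)
  spacing <- rep(spec$voxel_size_mm, 3)
  structure(list(label_map = vol3d(labels, spacing),
                 head_mask = vol3d(array(as.numeric(head_mask),
                                         dim = spec$grid_shape), spacing),
                 true_volumes_mL = vols,
                 true_bias_field = vol3d(bias, spacing),
                 clean_image = vol3d(clean, spacing)),
            class = "phantom_truth")
}

#' Generate a phantom image and its ground truth
#'
#' Builds the piecewise-constant clean image from the region geometry and
#' class means, multiplies by a smooth random bias field and adds Gaussian
#' noise. The returned truth carries the label map, the exact per-region
#' volumes, the bias field and the clean image.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` (a [vol3d()]) and `truth`
#'   (a `phantom_truth`: label map, head mask, true volumes in mL, true
#'   bias field, clean image).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    lm <- phantom_label_map(spec)
    clean <- array(0, dim = spec$grid_shape)
    for (k in seq_along(tissue_classes()))
      clean[lm$labels == k] <- spec$class_mean_intensities[[tissue_classes()[k]]]
    clean <- clean + phantom_texture(spec, lm$head_mask)
    bias <- phantom_bias_field(spec, lm$head_mask)
    img <- clean * bias
    if (spec$class_noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = spec$class_noise_sd)
    spacing <- rep(spec$voxel_size_mm, 3)
    list(image = vol3d(img, spacing),
         truth = phantom_truth(spec, lm$labels, lm$head_mask, bias, clean))
  })
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth random displacement field (mm), [dims x 3]; low-frequency by
# Gaussian smoothing of white noise, scaled to RMS magnitude `sd_mm`
# inside the mask, rejection-sampled to keep a positive Jacobian
random_deformation <- function(grid_shape, voxel_size_mm, sd_mm, mask,
                               smooth_vox = 8, max_tries = 6) {
  dims <- as.integer(grid_shape)
  n <- prod(dims)
  for (try in seq_len(max_tries)) {
    u <- vapply(1:3, function(a) {
      w <- stats::rnorm(n)
      cpp_gauss_smooth(w, dims, rep(smooth_vox, 3))
    }, numeric(n))
    rms <- sqrt(mean(rowSums(u[mask, , drop = FALSE]^2)))
    u <- u * sd_mm / rms
    if (displacement_jacobian_ok(u, dims, voxel_size_mm)) {
      if (try > 1)
        message("deformation resampled ", try - 1,
                " time(s) to avoid folding")
      return(array(u, dim = c(dims, 3)))
    }
    sd_mm <- sd_mm * 0.7
  }
  stop("could not draw a fold-free deformation after ", max_tries, " tries")
}

# positive-Jacobian check for the map x -> x + u(x), central differences
displacement_jacobian_ok <- function(u, dims, voxel_size_mm) {
  n <- prod(dims)
  J <- array(0, dim = c(n, 3, 3))
  for (a in 1:3) {
    g <- cpp_gradient3d(u[, a], dims)
    J[, a, ] <- matrix(g, n, 3) / voxel_size_mm
  }
  detJ <- (1 + J[, 1, 1]) * ((1 + J[, 2, 2]) * (1 + J[, 3, 3]) - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * (1 + J[, 3, 3]) - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - (1 + J[, 2, 2]) * J[, 3, 1])
  all(detJ > 0)
}

#' Generate a cohort of independently deformed phantoms
#'
#' Each subject is the base phantom pulled back through an independent
#' smooth random displacement field of RMS magnitude `deform_sd` mm
#' (rejection-sampled to keep a positive Jacobian), with its own bias field
#' and noise realization. Truths carry the warped labels and recomputed
#' volumes.
#'
#' @param spec a [phantom_spec()]; `spec$seed` fixes the whole cohort.
#' @param n number of subjects (>= 1).
#' @return list of length `n`; each element as [generate_phantom()].
#' @export
generate_cohort <- function(spec, n) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  base <- with_seed(spec$seed, phantom_label_map(spec))
  classes <- tissue_classes()
  clean0 <- array(0, dim = spec$grid_shape)
  for (k in seq_along(classes))
    clean0[base$labels == k] <- spec$class_mean_intensities[[classes[k]]]
  tex0 <- with_seed(spec$seed + 1L, phantom_texture(spec, base$head_mask))
  clean0 <- clean0 + tex0
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n))
  dims <- as.integer(spec$grid_shape)
  co <- phantom_coords(spec$grid_shape, spec$voxel_size_mm)
  vox0 <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                                y = seq_len(dims[2]) - 1,
                                z = seq_len(dims[3]) - 1))
  lapply(seq_len(n), function(i) with_seed(seeds[i], {
    if (spec$deform_sd > 0) {
      u <- random_deformation(spec$grid_shape, spec$voxel_size_mm,
                              spec$deform_sd, base$head_mask)
      p <- vox0 + matrix(u, ncol = 3) / spec$voxel_size_mm
      labels <- array(as.integer(cpp_sample_volume(
        as.numeric(base$labels), dims, p[, 1], p[, 2], p[, 3],
        TRUE, 0)), dim = dims)
      head_mask <- array(cpp_sample_volume(
        as.numeric(base$head_mask), dims, p[, 1], p[, 2], p[, 3],
        TRUE, 0) > 0.5, dim = dims)
      clean <- array(0, dim = dims)
      for (k in seq_along(classes))
        clean[labels == k] <- spec$class_mean_intensities[[classes[k]]]
      if (spec$texture_amplitude > 0)
        clean <- clean + array(cpp_sample_volume(
          as.numeric(tex0), dims, p[, 1], p[, 2], p[, 3], FALSE, 0),
          dim = dims) * head_mask
    } else {
      labels <- base$labels; head_mask <- base$head_mask; clean <- clean0
    }
    bias <- phantom_bias_field(spec, head_mask)
    img <- clean * bias
    if (spec$class_noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = spec$class_noise_sd)
    spacing <- rep(spec$voxel_size_mm, 3)
    list(image = vol3d(img, spacing),
         truth = phantom_truth(spec, labels, head_mask, bias, clean))
  }))
}

#' Build a probabilistic atlas from phantom ground truths
#'
#' Per-class priors are the smoothed average of the truth indicator
#' volumes, renormalized to sum to one inside the atlas mask (voxels where
#' at least half the truths lie inside the head). The template is the
#' average clean image. Plays the role of an external probabilistic brain
#' atlas in tests and phantom pipelines.
#'
#' @param truths list of `phantom_truth` objects on a common grid.
#' @param smoothing_mm isotropic Gaussian smoothing of the priors (0 = the
#'   one-hot average).
#' @return A `probabilistic_atlas`: list with `template`, `priors` (named
#'   list of [vol3d()], one per [tissue_classes()]), `mask` and
#'   `provenance`.
#' @export
atlas_from_truth <- function(truths, smoothing_mm = 1.2) {
  stopifnot(length(truths) >= 1)
  g <- truths[[1]]$label_map
  for (t in truths) stop_if_grid_mismatch(g, t$label_map, "truths")
  dims <- dim(g$data)
  classes <- tissue_classes()
  sig <- rep(smoothing_mm / g$spacing[1], 3)
  priors <- lapply(seq_along(classes), function(k) {
    ind <- Reduce(`+`, lapply(truths, function(t) (t$label_map$data == k) * 1))
    ind <- ind / length(truths)
    if (smoothing_mm > 0)
      ind <- array(cpp_gauss_smooth(as.numeric(ind), dims, sig), dim = dims)
    ind
  })
  names(priors) <- classes
  maskarr <- Reduce(`+`, lapply(truths, function(t) t$head_mask$data))
  maskarr <- (maskarr / length(truths)) >= 0.5
  total <- Reduce(`+`, priors)
  empty <- vapply(priors, function(p) sum(p[maskarr]) == 0, TRUE)
  if (any(empty))
    warning("empty prior class(es): ", paste(classes[empty], collapse = ", "))
  for (k in seq_along(priors)) {
    p <- priors[[k]]
    p[maskarr] <- p[maskarr] / pmax(total[maskarr], .Machine$double.eps)
    p[!maskarr] <- 0
    priors[[k]] <- vol3d(p, g$spacing)
  }
  template <- Reduce(`+`, lapply(truths, function(t) t$clean_image$data)) /
    length(truths)
  probabilistic_atlas(
    template = vol3d(template, g$spacing), priors = priors,
    mask = vol3d(array(as.numeric(maskarr), dim = dims), g$spacing),
    provenance = list(source = "phantom_truth", n = length(truths),
                      smoothing_mm = smoothing_mm))
}

#' Probabilistic atlas container
#'
#' A template image, per-class prior probability volumes and a brain mask
#' sharing one reference grid.
#' @param template,mask [vol3d()] objects.
#' @param priors named list of [vol3d()] priors, one per [tissue_classes()].
#' @param provenance free-form list recording how the atlas was built.
#' @export
probabilistic_atlas <- function(template, priors, mask, provenance = list()) {
  stopifnot(is_vol3d(template), is_vol3d(mask))
  for (p in priors) stop_if_grid_mismatch(template, p, "atlas components")
  stop_if_grid_mismatch(template, mask, "atlas components")
  structure(list(template = template, priors = priors, mask = mask,
                 provenance = provenance), class = "probabilistic_atlas")
}

#' @export
print.probabilistic_atlas <- function(x, ...) {
  cat(sprintf("<probabilistic_atlas> %s voxels, %d priors (%s)\n",
              paste(dim(x$template$data), collapse = "x"),
              length(x$priors), paste(names(x$priors), collapse = ", ")))
  invisible(x)
}
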