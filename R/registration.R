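#' Spatial transforms
#'
#' Transforms map points from the fixed (target) image space to the moving
#' (source) image space, in millimetres — the pull-back convention, so that
#' resampling a moving image onto a fixed grid is a single forward
#' application per target voxel. Linear transforms are 4x4 homogeneous
#' matrices; non-rigid transforms are cubic-B-spline free-form deformations
#' parameterized by a control-point displacement lattice; composites apply
#' an ordered list right-to-left.
#'
#' @param matrix 4x4 homogeneous matrix (last row `c(0,0,0,1)`).
#' @return A `transform` object.
#' @name transforms
NULL

#' @rdname transforms
#' @export
tf_affine <- function(matrix) {
  matrix <- unname(as.matrix(matrix))
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("linear transform is singular")
  structure(list(kind = "affine", matrix = matrix),
            class = c("tf_affine", "transform"))
}

#' @rdname transforms
#' @export
tf_identity <- function() tf_affine(diag(4))

#' @rdname transforms
#' @param angles_rad length-3 Euler angles (rotations about x, y, z).
#' @param translation_mm length-3 translation.
#' @param center_mm rotation centre (default origin).
#' @export
tf_rigid <- function(angles_rad = c(0, 0, 0), translation_mm = c(0, 0, 0),
                     center_mm = c(0, 0, 0)) {
  R <- rotation_matrix(angles_rad)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center_mm - R %*% center_mm + translation_mm
  tf_affine(M)
}

rotation_matrix <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' @rdname transforms
#' @param cp control-point displacement lattice, array
#'   `[ncx, ncy, ncz, 3]` in mm, defined over the fixed grid described by
#'   `grid_dim`/`grid_spacing` with `cp_spacing` voxels between knots.
#' @param cp_spacing knot spacing in voxels of the defining grid.
#' @param grid_dim,grid_spacing the defining grid.
#' @export
tf_bspline <- function(cp, cp_spacing, grid_dim, grid_spacing) {
  grid_dim <- as.integer(grid_dim)
  stopifnot(cp_spacing > 0, length(dim(cp)) == 4L, dim(cp)[4] == 3L)
  ncp <- cpp_bspline_ncp(grid_dim, cp_spacing)
  stopifnot(all(dim(cp)[1:3] == ncp))
  structure(list(kind = "bspline", cp = cp, cp_spacing = cp_spacing,
                 grid_dim = grid_dim,
                 grid_spacing = rep_len(as.numeric(grid_spacing), 3L),
                 cache = new.env(parent = emptyenv())),
            class = c("tf_bspline", "transform"))
}

#' Compose two transforms
#'
#' `compose_transforms(outer, inner)` acts as `outer(inner(x))`; affine
#' pairs collapse to their matrix product, other pairs become an ordered
#' composite applied right-to-left.
#' @param outer,inner `transform` objects.
#' @export
compose_transforms <- function(outer, inner) {
  if (inherits(outer, "tf_affine") && inherits(inner, "tf_affine"))
    return(tf_affine(outer$matrix %*% inner$matrix))
  parts <- c(tf_parts(outer), tf_parts(inner))
  structure(list(kind = "composite", parts = parts),
            class = c("tf_composite", "transform"))
}

tf_parts <- function(tf) {
  if (inherits(tf, "tf_composite")) tf$parts else list(tf)
}

#' Invert a linear transform
#' @param tf a `tf_affine`.
#' @export
tf_invert <- function(tf) {
  if (!inherits(tf, "tf_affine"))
    stop("only linear transforms have a closed-form inverse")
  tf_affine(solve(tf$matrix))
}

# dense displacement field of a bspline transform on its defining grid
# (mm, array [dims, 3]); cached
tf_dense_field <- function(tf) {
  if (is.null(tf$cache$field))
    tf$cache$field <- array(
      cpp_bspline_field(as.numeric(tf$cp), dim(tf$cp)[1:3],
                        tf$grid_dim, tf$cp_spacing),
      dim = c(tf$grid_dim, 3))
  tf$cache$field
}

#' Apply a transform to points
#' @param tf a `transform`.
#' @param pts_mm n x 3 matrix of fixed-space coordinates (mm).
#' @return n x 3 matrix of moving-space coordinates (mm).
#' @export
tf_apply <- function(tf, pts_mm) {
  pts_mm <- matrix(pts_mm, ncol = 3)
  if (inherits(tf, "tf_affine")) {
    out <- pts_mm %*% t(tf$matrix[1:3, 1:3])
    return(sweep(out, 2, tf$matrix[1:3, 4], `+`))
  }
  if (inherits(tf, "tf_bspline")) {
    u <- tf_dense_field(tf)
    dims <- tf$grid_dim
    disp <- vapply(1:3, function(a) {
      # edge-extend the displacement field beyond the defining grid
      q <- lapply(1:3, function(b)
        pmin(pmax(pts_mm[, b] / tf$grid_spacing[b], 0), dims[b] - 1))
      cpp_sample_volume(as.numeric(u[, , , a]), dims,
                        q[[1]], q[[2]], q[[3]], FALSE, 0)
    }, numeric(nrow(pts_mm)))
    return(pts_mm + disp)
  }
  if (inherits(tf, "tf_composite")) {
    for (part in rev(tf$parts)) pts_mm <- tf_apply(part, pts_mm)
    return(pts_mm)
  }
  stop("unknown transform kind")
}

#' @export
print.transform <- function(x, ...) {
  cat("<transform:", x$kind, ">\n")
  invisible(x)
}

grid_points_mm <- function(vol) {
  d <- dim(vol$data)
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]) * vol$spacing[1],
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]) * vol$spacing[2],
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]) * vol$spacing[3])
}

#' Resample a volume through a transform
#'
#' Pull-back resampling: every voxel of `target_grid` is mapped through
#' `transform` into the space of `source` and interpolated there. Use
#' nearest-neighbour interpolation for label maps (enforced when the source
#' looks integer-coded unless overridden).
#'
#' @param source a [vol3d()] (intensity image, label map or prior volume).
#' @param transform a `transform` mapping target space to source space.
#' @param target_grid a [vol3d()] defining the output grid.
#' @param interpolation "linear" or "nearest".
#' @param fill value for samples falling outside `source` (default 0).
#' @return a [vol3d()] on the grid of `target_grid`.
#' @export
resample <- function(source, transform, target_grid,
                     interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  if (is.integer(source$data) && interpolation != "nearest")
    stop("label maps (integer-coded volumes) must be resampled with ",
         "nearest-neighbour interpolation")
  p <- tf_apply(transform, grid_points_mm(target_grid))
  d <- dim(source$data)
  vals <- cpp_sample_volume(as.numeric(source$data), d,
                            p[, 1] / source$spacing[1],
                            p[, 2] / source$spacing[2],
                            p[, 3] / source$spacing[3],
                            interpolation == "nearest", fill)
  with_data(target_grid, vals)
}

#' Resample per-class prior volumes, renormalizing the per-voxel sum
#'
#' Priors are interpolated linearly and then renormalized so the per-voxel
#' sum never exceeds 1 (sums below 1 near the brain boundary are kept, as
#' they encode background probability).
#' @param priors named list of [vol3d()] priors on a common grid.
#' @inheritParams resample
#' @export
resample_priors <- function(priors, transform, target_grid) {
  out <- lapply(priors, resample, transform = transform,
                target_grid = target_grid, interpolation = "linear")
  total <- Reduce(`+`, lapply(out, function(p) p$data))
  scale <- 1 / pmax(total, 1)
  lapply(out, function(p) with_data(p, p$data * scale))
}

#' Registration settings
#'
#' Defaults chosen for same-modality phantom work: normalized
#' cross-correlation similarity, a coarse-to-fine pyramid for linear
#' registration, and a single-resolution cubic-B-spline stage with a
#' bending-energy penalty at 8-voxel knot spacing (counted on the
#' full-resolution grid).
#'
#' @param pyramid downsampling factors for linear registration,
#'   coarse to fine.
#' @param maxit `optim` iteration budget per pyramid level.
#' @param bspline_factor working-resolution downsampling for the B-spline
#'   stage.
#' @param cp_spacing_vox knot spacings (full-resolution voxels), one
#'   optimization stage per value, coarse to fine.
#' @param bspline_iterations gradient-ascent budget per stage.
#' @param step_vox initial update magnitude, voxels.
#' @param bending bending-energy weight.
#' @export
reg_params <- function(pyramid = c(4, 2), maxit = 80,
                       bspline_factor = 2, cp_spacing_vox = c(16, 8),
                       bspline_iterations = 50, step_vox = 0.4,
                       bending = 1e-6) {
  list(pyramid = pyramid, maxit = maxit, bspline_factor = bspline_factor,
       cp_spacing_vox = cp_spacing_vox,
       bspline_iterations = bspline_iterations, step_vox = step_vox,
       bending = bending)
}

downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  d <- dim(vol$data)
  sm <- array(cpp_gauss_smooth(as.numeric(vol$data), d,
                               rep(factor / 2, 3)), dim = d)
  idx <- lapply(d, function(n) seq(1, n, by = factor))
  vol3d(sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
        vol$spacing * factor)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) return(0)
  sum(a * b) / den
}

# negative NCC between fixed and moving-resampled-through-tf, over voxels
# with valid samples (and fixed_mask if given); transforms that lose
# (almost) all overlap score a flat penalty instead of erroring so line
# searches can back off
neg_ncc_objective <- function(tf, fixed, moving, mask_idx = NULL,
                              strict = FALSE) {
  p <- tf_apply(tf, grid_points_mm(fixed))
  vals <- cpp_sample_volume(as.numeric(moving$data), dim(moving$data),
                            p[, 1] / moving$spacing[1],
                            p[, 2] / moving$spacing[2],
                            p[, 3] / moving$spacing[3], FALSE, NA_real_)
  f <- as.numeric(fixed$data)
  ok <- !is.na(vals)
  if (!is.null(mask_idx)) {
    keep <- logical(length(f)); keep[mask_idx] <- TRUE
    ok <- ok & keep
  }
  if (sum(ok) < 32) {
    if (strict) stop("empty overlap between fixed and moving images")
    return(2)
  }
  -ncc(f[ok], vals[ok])
}

linear_par_to_tf <- function(par, kind, center_mm) {
  if (kind == "rigid") {
    tf_rigid(par[1:3], par[4:6], center_mm)
  } else {
    M <- diag(4)
    M[1:3, 1:3] <- diag(3) + matrix(par[1:9], 3, 3)
    M[1:3, 4] <- par[10:12]
    C <- diag(4); C[1:3, 4] <- -center_mm
    Cb <- diag(4); Cb[1:3, 4] <- center_mm
    tf_affine(Cb %*% M %*% C)
  }
}

#' Register a moving image to a fixed image
#'
#' Maximizes normalized cross-correlation. Rigid (6 dof) and affine
#' (12 dof) transforms are optimized with [stats::optim()] over a
#' coarse-to-fine image pyramid; the cubic-B-spline free-form deformation
#' is optimized by backtracking gradient ascent on the control-point
#' lattice with a bending-energy penalty, coarse-to-fine in knot spacing.
#' Deterministic given identical inputs and settings.
#'
#' @param fixed,moving [vol3d()] images.
#' @param kind "rigid", "affine" or "bspline".
#' @param params a [reg_params()] list.
#' @param init optional initial transform: for "affine"/"rigid" an affine
#'   starting point; for "bspline" a linear transform composed outside the
#'   deformation (result is `init(x + u(x))`).
#' @param fixed_mask optional [vol3d()] mask restricting the similarity to
#'   nonzero voxels.
#' @return a `transform`; attribute `trace` holds the per-stage objective
#'   values (negative NCC for linear stages, penalized NCC for B-spline),
#'   attribute `converged` a flag.
#' @export
register <- function(fixed, moving, kind = c("rigid", "affine", "bspline"),
                     params = reg_params(), init = NULL, fixed_mask = NULL) {
  kind <- match.arg(kind)
  if (kind == "bspline")
    return(register_bspline(fixed, moving, params, init, fixed_mask))
  center <- (dim(fixed$data) - 1) * fixed$spacing / 2
  npar <- if (kind == "rigid") 6L else 12L
  par <- numeric(npar)
  if (!is.null(init)) {
    if (!inherits(init, "tf_affine"))
      stop("init for linear registration must be affine")
    if (kind == "rigid")
      stop("rigid registration does not accept an initial transform")
    C <- diag(4); C[1:3, 4] <- -center
    Cb <- diag(4); Cb[1:3, 4] <- center
    M <- C %*% init$matrix %*% Cb
    par <- c(as.numeric(M[1:3, 1:3] - diag(3)), M[1:3, 4])
  }
  trace <- numeric(0)
  for (f in sort(params$pyramid, decreasing = TRUE)) {
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    midx <- if (!is.null(fixed_mask))
      which(downsample_volume(fixed_mask, f)$data > 0.5) else NULL
    obj <- function(p)
      neg_ncc_objective(linear_par_to_tf(p, kind, center), fx, mv, midx)
    # fail loudly if even the starting transform has no overlap
    neg_ncc_objective(linear_par_to_tf(par, kind, center), fx, mv, midx,
                      strict = TRUE)
    scale <- c(rep(0.05, npar - 3), rep(max(fixed$spacing), 3))
    fit <- stats::optim(par, obj, method = "BFGS",
                        control = list(maxit = params$maxit,
                                       parscale = scale,
                                       reltol = 1e-10))
    par <- fit$par
    trace <- c(trace, fit$value)
  }
  out <- linear_par_to_tf(par, kind, center)
  attr(out, "trace") <- trace
  attr(out, "converged") <- TRUE
  out
}

bending_energy <- function(cp) {
  e <- 0
  for (a in 1:3) {
    d2 <- diff_axis2(cp, a)
    e <- e + sum(d2^2)
  }
  e
}

diff_axis2 <- function(cp, axis) {
  n <- dim(cp)[axis]
  idx <- function(shift) {
    args <- list(cp, 1:dim(cp)[1], 1:dim(cp)[2], 1:dim(cp)[3], 1:3)
    args[[axis + 1]] <- seq_len(n - 2) + shift
    do.call(`[`, c(args, drop = FALSE))
  }
  idx(0) - 2 * idx(1) + idx(2)
}

register_bspline <- function(fixed, moving, params, init, fixed_mask) {
  f <- params$bspline_factor
  fx <- downsample_volume(fixed, f)
  mv <- downsample_volume(moving, f)
  dims <- dim(fx$data)
  n <- prod(dims)
  pts <- grid_points_mm(fx)
  fvec <- as.numeric(fx$data)
  keep <- rep(TRUE, n)
  if (!is.null(fixed_mask))
    keep <- downsample_volume(fixed_mask, f)$data > 0.5
  A <- if (is.null(init)) NULL else {
    if (!inherits(init, "tf_affine"))
      stop("init for bspline registration must be affine")
    init
  }
  A3 <- if (is.null(A)) diag(3) else A$matrix[1:3, 1:3]
  grad_m <- array(cpp_gradient3d(as.numeric(mv$data), dims), dim = c(n, 3))
  grad_m <- sweep(grad_m, 2, mv$spacing, `/`)   # intensity per mm
  trace <- numeric(0)
  stage_starts <- integer(0)
  cp <- NULL
  converged <- FALSE
  objective <- function(cp_arr, cps_level) {
    u <- array(cpp_bspline_field(as.numeric(cp_arr), dim(cp_arr)[1:3],
                                 dims, cps_level), dim = c(n, 3))
    p <- pts + u
    if (!is.null(A)) p <- tf_apply(A, p)
    # clamp into the moving volume (edge extension) so the objective stays
    # continuous as samples cross the boundary
    q <- vapply(1:3, function(a)
      pmin(pmax(p[, a] / mv$spacing[a], 0), dims[a] - 1), numeric(n))
    m <- cpp_sample_volume(as.numeric(mv$data), dims, q[, 1], q[, 2],
                           q[, 3], FALSE, 0)
    val <- ncc(fvec[keep], m[keep]) - params$bending * bending_energy(cp_arr)
    list(value = val, m = m, q = q)
  }
  for (cps_full in params$cp_spacing_vox) {
    cps <- cps_full / f                      # knot spacing in working voxels
    ncp <- cpp_bspline_ncp(dims, cps)
    cp_new <- array(0, dim = c(ncp, 3))
    if (!is.null(cp)) {
      # initialize the finer lattice from the coarse dense field
      u_prev <- array(cpp_bspline_field(as.numeric(cp), dim(cp)[1:3],
                                        dims, prev_cps), dim = c(dims, 3))
      for (a in 1:3) {
        loc <- lapply(1:3, function(b)
          pmin(pmax((seq_len(ncp[b]) - 2) * cps, 0), dims[b] - 1))
        gridpts <- as.matrix(expand.grid(loc[[1]], loc[[2]], loc[[3]]))
        cp_new[, , , a] <- array(cpp_sample_volume(
          as.numeric(u_prev[, , , a]), dims, gridpts[, 1], gridpts[, 2],
          gridpts[, 3], FALSE, 0), dim = ncp)
      }
    }
    cp <- cp_new
    step <- params$step_vox * max(fx$spacing)
    cur <- objective(cp, cps)
    stage_starts <- c(stage_starts, length(trace) + 1L)
    trace <- c(trace, cur$value)
    for (it in seq_len(params$bspline_iterations)) {
      # d NCC / d m at the voxels entering the similarity
      m <- cur$m
      fc <- fvec[keep] - mean(fvec[keep])
      mc <- m[keep] - mean(m[keep])
      Bm <- sum(mc * mc); Cf <- sum(fc * fc)
      dccc <- numeric(n)
      den <- sqrt(Cf * Bm)
      if (den == 0) break
      dccc[keep] <- (fc - (sum(fc * mc) / Bm) * mc) / den
      gq <- vapply(1:3, function(a)
        cpp_sample_volume(grad_m[, a], dims, cur$q[, 1], cur$q[, 2],
                          cur$q[, 3], FALSE, 0), numeric(n))
      force <- (gq %*% A3) * dccc
      gcp <- array(cpp_bspline_splat(as.numeric(force), dim(cp)[1:3],
                                     dims, cps), dim = dim(cp))
      gcp <- gcp - 2 * params$bending * bending_gradient_simple(cp)
      gmax <- max(abs(gcp))
      if (gmax == 0) { converged <- TRUE; break }
      accepted <- FALSE
      for (bt in 1:5) {
        cand <- cp + gcp * (step / gmax)
        res <- objective(cand, cps)
        if (res$value > cur$value + 1e-10) {
          cp <- cand; cur <- res; accepted <- TRUE
          trace <- c(trace, res$value)
          break
        }
        step <- step / 2
      }
      if (!accepted) { converged <- TRUE; break }
      step <- min(step * 1.3, params$step_vox * max(fx$spacing))
    }
    prev_cps <- cps
  }
  B <- tf_bspline(cp, prev_cps, dims, fx$spacing)
  out <- if (is.null(A)) B else compose_transforms(A, B)
  if (!converged)
    warning("B-spline registration stopped at the iteration budget; ",
            "returning best-so-far transform")
  attr(out, "trace") <- trace
  attr(out, "stage_starts") <- stage_starts
  attr(out, "converged") <- converged
  out
}

# gradient of the sum of squared second differences along each lattice axis
bending_gradient_simple <- function(cp) {
  g <- array(0, dim = dim(cp))
  d <- dim(cp)
  for (a in 1:3) {
    n <- d[a]
    if (n < 3) next
    d2 <- diff_axis2(cp, a)
    pad <- function(shift) {
      out <- array(0, dim = d)
      args <- lapply(d, seq_len)
      args[[a]] <- seq_len(n - 2) + shift
      out[args[[1]], args[[2]], args[[3]], args[[4]]] <- d2
      out
    }
    g <- g + pad(0) - 2 * pad(1) + pad(2)
  }
  2 * g
}

#' Serialize / deserialize transforms as JSON
#' @param tf a `transform`.
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(tf_to_list(tf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

tf_to_list <- function(tf) {
  if (inherits(tf, "tf_affine"))
    return(list(kind = "affine", matrix = as.numeric(tf$matrix)))
  if (inherits(tf, "tf_bspline"))
    return(list(kind = "bspline", cp = as.numeric(tf$cp),
                cp_dim = dim(tf$cp), cp_spacing = tf$cp_spacing,
                grid_dim = tf$grid_dim, grid_spacing = tf$grid_spacing))
  if (inherits(tf, "tf_composite"))
    return(list(kind = "composite", parts = lapply(tf$parts, tf_to_list)))
  stop("unknown transform kind")
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  tf_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

tf_from_list <- function(x) {
  switch(x$kind,
    affine = tf_affine(matrix(unlist(x$matrix), 4, 4)),
    bspline = tf_bspline(array(unlist(x$cp), dim = unlist(x$cp_dim)),
                         x$cp_spacing, unlist(x$grid_dim),
                         unlist(x$grid_spacing)),
    composite = structure(
      list(kind = "composite", parts = lapply(x$parts, tf_from_list)),
      class = c("tf_composite", "transform")),
    stop("unknown transform kind in file"))
}
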