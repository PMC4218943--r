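#' Registration schedule for groupwise atlas construction
#'
#' The default schedule is one rigid, four affine and four non-rigid
#' (cubic-B-spline) rounds; the number of rounds typically depends on the
#' diversity of the images, so it is configurable.
#' @param rigid,affine,bspline number of rounds of each kind.
#' @return character vector of round kinds, in order.
#' @export
atlas_schedule <- function(rigid = 1, affine = 4, bspline = 4) {
  c(rep("rigid", rigid), rep("affine", affine), rep("bspline", bspline))
}

#' Build a groupwise average atlas
#'
#' Iteratively registers every subject to the current average image with
#' an increasing-degrees-of-freedom schedule, resamples and re-averages
#' (arithmetic mean) to define a new average space. After the final round,
#' the per-subject transforms (average space to native space, the
#' pull-back direction) propagate the individual soft posteriors and
#' brain masks into the average space; priors are their voxelwise average
#' renormalized inside the average mask, and the average mask keeps
#' voxels where at least half the propagated masks agree.
#'
#' @param images list of [vol3d()] subject images (>= 2).
#' @param segmentations list of `segmentation_result` objects (one per
#'   subject), whose posteriors become the atlas priors.
#' @param masks list of [vol3d()] brain masks, one per subject.
#' @param schedule character vector of round kinds, e.g.
#'   [atlas_schedule()].
#' @param params a [reg_params()] list used for every registration.
#' @return A `probabilistic_atlas`; `provenance` records the schedule, the
#'   per-round template change diagnostic (`template_change`, mean
#'   voxelwise absolute change of the average image after each round) and
#'   any dropped subjects. Attribute `transforms` holds the final
#'   average-to-native transform per subject.
#' @export
build_groupwise_atlas <- function(images, segmentations, masks,
                                  schedule = atlas_schedule(),
                                  params = reg_params()) {
  n <- length(images)
  stopifnot(n >= 2, length(segmentations) == n, length(masks) == n,
            length(schedule) >= 1)
  g <- images[[1]]
  for (im in images) stop_if_grid_mismatch(g, im, "subject images")
  template <- with_data(g, Reduce(`+`, lapply(images, function(x) x$data)) / n)
  transforms <- rep(list(tf_identity()), n)
  linear_tf <- rep(list(NULL), n)
  alive <- rep(TRUE, n)
  change <- numeric(0)
  for (round in seq_along(schedule)) {
    kind <- schedule[round]
    new_imgs <- vector("list", n)
    for (s in which(alive)) {
      tf <- tryCatch({
        if (kind == "bspline")
          register(template, images[[s]], "bspline", params,
                   init = linear_tf[[s]])
        else
          register(template, images[[s]], kind, params,
                   init = if (kind == "affine") linear_tf[[s]] else NULL)
      }, error = function(e) {
        warning("registration failed for subject ", s, " in round ",
                round, ": ", conditionMessage(e), "; subject dropped")
        NULL
      })
      if (is.null(tf)) { alive[s] <- FALSE; next }
      if (kind != "bspline") linear_tf[[s]] <- tf
      transforms[[s]] <- tf
      new_imgs[[s]] <- resample(images[[s]], tf, template)
    }
    if (sum(alive) < 2)
      stop("fewer than 2 subjects survived registration round ", round)
    new_template <- with_data(template,
      Reduce(`+`, lapply(new_imgs[alive], function(x) x$data)) / sum(alive))
    change <- c(change, mean(abs(new_template$data - template$data)))
    template <- new_template
  }
  classes <- names(segmentations[[which(alive)[1]]]$posteriors)
  prior_sum <- stats::setNames(
    rep(list(array(0, dim = dim(template$data))), length(classes)), classes)
  mask_sum <- array(0, dim = dim(template$data))
  for (s in which(alive)) {
    prop <- propagate_to_average(segmentations[[s]]$posteriors,
                                 transforms[[s]],
                                 list(template = template))
    for (cl in classes)
      prior_sum[[cl]] <- prior_sum[[cl]] + prop[[cl]]$data
    m <- resample(masks[[s]], transforms[[s]], template,
                  interpolation = "nearest")
    mask_sum <- mask_sum + (m$data > 0)
  }
  maskarr <- mask_sum / sum(alive) >= 0.5
  total <- Reduce(`+`, prior_sum)
  priors <- lapply(prior_sum, function(p) {
    p[maskarr] <- p[maskarr] / pmax(total[maskarr], .Machine$double.eps)
    p[!maskarr] <- 0
    vol3d(p, template$spacing)
  })
  atlas <- probabilistic_atlas(
    template = template, priors = priors,
    mask = with_data(template, as.numeric(maskarr)),
    provenance = list(schedule = schedule, n_subjects = sum(alive),
                      dropped = which(!alive), template_change = change))
  attr(atlas, "transforms") <- transforms[alive]
  atlas
}

#' Propagate posteriors or a label map into the atlas average space
#'
#' Resamples through the average-to-native transform onto the atlas grid:
#' linear interpolation with per-voxel renormalization for posterior
#' lists, nearest-neighbour for label maps.
#'
#' @param item a named list of posterior [vol3d()] volumes, or a single
#'   [vol3d()] label map.
#' @param transform average-space-to-native transform for the subject.
#' @param atlas a `probabilistic_atlas` (or any list with `$template`).
#' @export
propagate_to_average <- function(item, transform, atlas) {
  target <- atlas$template
  if (is_vol3d(item))
    return(resample(item, transform, target, interpolation = "nearest"))
  resample_priors(item, transform, target)
}
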