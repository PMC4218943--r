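#' Cohort pipeline configuration
#'
#' @param cohort "newborn" or "fetal" (labelling only; the processing
#'   chain is identical, the prior source differs).
#' @param em an [em_params()] list.
#' @param reg a [reg_params()] list.
#' @param schedule groupwise registration schedule ([atlas_schedule()]).
#' @param density_g_per_mL brain density for weight estimation.
#' @param correct_bias estimate and remove the bias field per subject.
#' @param mask_signal_frac voxels of the propagated brain mask whose
#'   corrected intensity falls below this fraction of the within-mask
#'   median are dropped before segmentation — the automated analogue of
#'   manually excluding non-brain voxels from a propagated mask (0
#'   disables).
#' @param nonrigid_priors refine the prior-propagation registration with a
#'   B-spline stage on top of the affine one.
#' @param build_atlas build the groupwise average atlas after segmenting a
#'   newborn cohort.
#' @param seed RNG seed recorded in provenance (the chain itself is
#'   deterministic).
#' @export
pipeline_config <- function(cohort = c("newborn", "fetal"),
                            em = em_params(), reg = reg_params(),
                            schedule = atlas_schedule(),
                            density_g_per_mL = 1.08,
                            correct_bias = TRUE,
                            mask_signal_frac = 0.25,
                            nonrigid_priors = TRUE,
                            build_atlas = TRUE,
                            seed = 1L) {
  list(cohort = match.arg(cohort), em = em, reg = reg, schedule = schedule,
       density_g_per_mL = density_g_per_mL, correct_bias = correct_bias,
       mask_signal_frac = mask_signal_frac,
       nonrigid_priors = nonrigid_priors, build_atlas = build_atlas,
       seed = as.integer(seed))
}

# preprocess + register + resample priors + EM + merge + volumetry for one
# subject against one prior source
segment_subject <- function(subject, atlas, config) {
  image <- subject$image
  tf_lin <- register(image, atlas$template, "affine", config$reg)
  mask <- propagate_mask(atlas, tf_lin, image)
  corrected <- image
  bias <- NULL
  if (isTRUE(config$correct_bias)) {
    # a propagated mask can leak a few non-brain voxels whose intensity is
    # pure noise (possibly <= 0); the log-domain fit uses the positive part
    fit_mask <- with_data(mask, as.numeric(mask$data > 0 & image$data > 0))
    bias <- estimate_bias_field(image, fit_mask)
    corrected <- correct_bias(image, bias)
  }
  tf <- if (isTRUE(config$nonrigid_priors))
    register(corrected, atlas$template, "bspline", config$reg, init = tf_lin)
  else tf_lin
  priors <- resample_priors(atlas$priors, tf, corrected)
  # uniform prior floor: residual registration error can leave mask voxels
  # outside the propagated prior support; EM renormalizes per voxel
  priors <- lapply(priors, function(p) with_data(p, p$data + 1e-3))
  seg_mask <- mask
  if (config$mask_signal_frac > 0) {
    # drop propagated-mask voxels with no tissue signal (non-brain leak)
    cutoff <- config$mask_signal_frac *
      stats::median(corrected$data[mask$data > 0])
    seg_mask <- with_data(mask,
                          as.numeric(mask$data > 0 &
                                       corrected$data > cutoff))
  }
  seg <- em_segment(corrected, priors, seg_mask, config$em)
  merged <- merge_classes(seg)
  report <- volumetry_report(
    corrected, with_data(merged, as.numeric(merged$data == 1)),
    threshold = subject$threshold,
    subject_id = if (is.null(subject$id)) NA_character_ else subject$id,
    density_g_per_mL = config$density_g_per_mL)
  list(id = subject$id, corrected = corrected, bias = bias, mask = mask,
       transform = tf, segmentation = seg, merged = merged,
       report = report)
}

run_cohort <- function(subjects, atlas, config) {
  results <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    results[[i]] <- tryCatch(
      segment_subject(subjects[[i]], atlas, config),
      error = function(e) {
        warning("subject ", i, " skipped: ", conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(results, is.null, TRUE)
  list(results = results[ok], ok = ok)
}

#' Run the newborn cohort pipeline
#'
#' Per subject: affine registration to the prior atlas, mask propagation,
#' bias-field correction, non-rigid refinement, prior resampling, EM-MRF
#' segmentation, cerebrum+CSF merging and CSF-threshold volumetry. The
#' segmented cohort is then averaged into a new groupwise atlas (unless
#' disabled), which is the prior source for the fetal cohort.
#'
#' @param subjects list of subjects; each a list with `image` (a
#'   [vol3d()]), `threshold` (CSF threshold) and optionally `id`.
#' @param atlas initial `probabilistic_atlas` (the external prior source).
#' @param config a [pipeline_config()].
#' @return list with `subjects` (per-subject results: corrected image,
#'   mask, transform, segmentation, merged labels, volumetry report),
#'   `records` (stacked volumetry rows), `atlas` (the groupwise atlas, or
#'   `NULL` if not built) and `config`.
#' @export
run_newborn_pipeline <- function(subjects, atlas, config = pipeline_config()) {
  set.seed(config$seed)
  run <- run_cohort(subjects, atlas, config)
  res <- run$results
  if (length(res) == 0) stop("no subject survived the pipeline")
  new_atlas <- NULL
  if (isTRUE(config$build_atlas)) {
    if (length(res) < 2)
      stop("cohort stages require at least 2 surviving subjects")
    new_atlas <- build_groupwise_atlas(
      images = lapply(res, `[[`, "corrected"),
      segmentations = lapply(res, `[[`, "segmentation"),
      masks = lapply(res, `[[`, "mask"),
      schedule = config$schedule, params = config$reg)
  }
  list(subjects = res,
       records = do.call(rbind, lapply(res, `[[`, "report")),
       atlas = new_atlas, config = config)
}

#' Run the fetal cohort pipeline
#'
#' The same per-subject chain as [run_newborn_pipeline()], using a
#' supplied atlas (typically the groupwise newborn atlas) as the prior
#' source. If `compare_atlas` is given, every subject with a known truth
#' is additionally segmented with that alternative prior source and the
#' per-class Dice of both prior sources against the truth is reported.
#'
#' @inheritParams run_newborn_pipeline
#' @param compare_atlas optional second `probabilistic_atlas` for the
#'   prior-source comparison; subjects need a `truth` element
#'   (a `phantom_truth`) to be scored.
#' @return as [run_newborn_pipeline()] (no atlas is built), plus
#'   `prior_comparison`: per-subject data.frames from
#'   [compare_prior_sources()] (`dice_A` = `atlas`, `dice_B` =
#'   `compare_atlas`).
#' @export
run_fetal_pipeline <- function(subjects, atlas, config = pipeline_config("fetal"),
                               compare_atlas = NULL) {
  set.seed(config$seed)
  run <- run_cohort(subjects, atlas, config)
  res <- run$results
  if (length(res) == 0) stop("no subject survived the pipeline")
  comparison <- NULL
  if (!is.null(compare_atlas)) {
    kept <- subjects[run$ok]
    comparison <- vector("list", length(res))
    for (i in seq_along(res)) {
      if (is.null(kept[[i]]$truth)) next
      alt <- segment_subject(kept[[i]], compare_atlas, config)
      truth_merged <- merge_label_map(kept[[i]]$truth$label_map)
      comparison[[i]] <- compare_prior_sources(
        res[[i]]$merged, alt$merged, truth_merged)
    }
  }
  list(subjects = res,
       records = do.call(rbind, lapply(res, `[[`, "report")),
       prior_comparison = comparison, config = config)
}

#' Recompute the cohort agreement statistics from the packaged tables
#'
#' Loads the packaged newborn and fetal cohort tables, recomputes the
#' Bland-Altman aggregates over the complete MRI/autopsy pairs, rounds to
#' the nearest gram (half away from zero) and compares with the expected
#' printed values registered in the package manifest. Also recomputes the
#' row-level weight = volume x density round trip for every row.
#'
#' @param tables_dir directory containing `newborn_cohort.csv`,
#'   `fetal_cohort.csv` and `printed_aggregates.json` (default: the
#'   packaged copies).
#' @return A data.frame with one row per aggregate (cohort, statistic,
#'   computed, rounded, expected, pass). Attributes: `ok` (all aggregates
#'   match), `roundtrip` (per-cohort data.frame of row-level weight
#'   discrepancies), `summaries` (the two `agreement_stats` objects).
#' @export
reproduce_tables <- function(tables_dir = system.file("extdata",
                                                      package = "pmbrainvol")) {
  paths <- file.path(tables_dir,
                     c("newborn_cohort.csv", "fetal_cohort.csv",
                       "printed_aggregates.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing table file(s): ", paste(missing, collapse = ", "))
  expected <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  out <- NULL
  roundtrip <- list()
  summaries <- list()
  for (cohort in c("newborn", "fetal")) {
    tab <- load_subject_table(file.path(tables_dir,
                                        paste0(cohort, "_cohort.csv")))
    s <- cohort_summary(tab)
    summaries[[cohort]] <- s
    computed <- c(mean_mri_weight_g = s$mean_test,
                  mean_autopsy_weight_g = s$mean_reference,
                  mean_absolute_difference_g = s$mean_absolute_difference,
                  loa_low_g = s$loa_low,
                  loa_high_g = s$loa_high)
    exp_c <- unlist(expected[[cohort]])[names(computed)]
    out <- rbind(out, data.frame(
      cohort = cohort, statistic = names(computed),
      computed = unname(computed),
      rounded = unname(round_half_away(computed)),
      expected = unname(exp_c),
      pass = unname(round_half_away(computed) == exp_c),
      row.names = NULL))
    roundtrip[[cohort]] <- data.frame(
      subject_id = tab$subject_id,
      discrepancy_g = volume_to_weight(tab$mri_volume_mL) - tab$mri_weight_g)
  }
  structure(out, ok = all(out$pass), roundtrip = roundtrip,
            summaries = summaries)
}
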