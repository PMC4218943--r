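#' Dice overlap of one label between two label maps
#'
#' The number of voxels where both maps carry the label, divided by the
#' average number of voxels carrying it in each map —
#' `2|A n B| / (|A| + |B|)`. Symmetric, in `[0, 1]`. If the label is
#' absent from both maps the score is defined as 1 (empty-vs-empty
#' agreement) with a warning.
#'
#' @param a,b [vol3d()] label maps on the same grid.
#' @param label label code to compare.
#' @export
dice <- function(a, b, label = 1) {
  stop_if_grid_mismatch(a, b, "label maps")
  na <- sum(a$data == label)
  nb <- sum(b$data == label)
  if (na + nb == 0) {
    warning("label ", label, " absent from both maps; Dice defined as 1")
    return(1)
  }
  2 * sum(a$data == label & b$data == label) / (na + nb)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `reference - test` (autopsy minus MRI in the cohort
#' analyses). The standard deviation uses the n-1 denominator and the 95%
#' limits of agreement are `mean difference +/- 1.96 SD`.
#'
#' @param reference,test paired measurements (complete, n >= 2).
#' @return An `agreement_stats` list: `n`, `mean_reference`, `mean_test`,
#'   `mean_difference`, `sd_difference`, `loa_low`, `loa_high`,
#'   `mean_absolute_difference`, `max_relative_error_fraction` (largest
#'   `|difference| / reference`), and `pairs` (per-pair mean and
#'   difference, the Bland-Altman plot coordinates).
#' @export
bland_altman <- function(reference, test) {
  stopifnot(length(reference) == length(test))
  if (any(is.na(reference)) || any(is.na(test)))
    stop("pairs must be complete (no missing values)")
  n <- length(reference)
  if (n < 2) stop("need at least 2 pairs")
  d <- reference - test
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(
    n = n,
    mean_reference = mean(reference),
    mean_test = mean(test),
    mean_difference = m,
    sd_difference = s,
    loa_low = m - 1.96 * s,
    loa_high = m + 1.96 * s,
    mean_absolute_difference = mean(abs(d)),
    max_relative_error_fraction = max(abs(d) / reference),
    pairs = data.frame(mean = (reference + test) / 2, difference = d)
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_stats> n = %d\n",
    "  means (reference vs test): %.2f vs %.2f\n",
    "  mean difference %.2f (SD %.2f), limits of agreement [%.2f, %.2f]\n",
    "  mean absolute difference %.2f, max relative error %.1f%%\n"),
    x$n, x$mean_reference, x$mean_test, x$mean_difference,
    x$sd_difference, x$loa_low, x$loa_high, x$mean_absolute_difference,
    100 * x$max_relative_error_fraction))
  invisible(x)
}

#' Half-away-from-zero rounding to the nearest integer
#'
#' Reporting convention for cohort aggregates in grams (base R `round`
#' rounds half to even).
#' @param x numeric.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cohort agreement summary from a subject table
#'
#' Filters records to those with both the test and reference weight and
#' returns Bland-Altman statistics plus the per-pair plot coordinates.
#' @param records data.frame from [load_subject_table()].
#' @param reference,test column names (reference defaults to the autopsy
#'   weight, test to the MRI-derived weight).
#' @export
cohort_summary <- function(records, reference = "autopsy_weight_g",
                           test = "mri_weight_g") {
  stopifnot(all(c(reference, test) %in% names(records)))
  keep <- !is.na(records[[reference]]) & !is.na(records[[test]])
  if (!any(keep)) stop("no complete pairs in the table")
  bland_altman(records[[reference]][keep], records[[test]][keep])
}

#' Per-class Dice for two prior sources against a common truth
#'
#' Phantom analogue of the matched-vs-public-atlas comparison: the same
#' subject segmented with two different prior sources, both scored against
#' the ground truth.
#' @param segA,segB [vol3d()] label maps from the two prior sources.
#' @param truth [vol3d()] ground-truth label map with the same label
#'   scheme.
#' @param labels named integer vector of label codes to score (default:
#'   the merged regions).
#' @return data.frame with one row per class: `class`, `dice_A`, `dice_B`.
#' @export
compare_prior_sources <- function(segA, segB, truth,
                                  labels = stats::setNames(
                                    seq_along(merged_classes()),
                                    merged_classes())) {
  stop_if_grid_mismatch(segA, segB, "segmentations")
  stop_if_grid_mismatch(segA, truth, "segmentation and truth")
  present <- function(s) sort(unique(as.integer(s$data[s$data > 0])))
  scheme <- union(as.integer(labels), present(truth))
  if (!all(present(segA) %in% scheme) || !all(present(segB) %in% scheme))
    stop("label-scheme mismatch: segmentations carry codes outside the ",
         "truth/requested label set")
  data.frame(
    class = names(labels),
    dice_A = vapply(labels, function(l) dice(segA, truth, l), 0),
    dice_B = vapply(labels, function(l) dice(segB, truth, l), 0),
    row.names = NULL)
}
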