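#' Exclude fluid from the merged cerebrum+CSF region by intensity threshold
#'
#' Cerebrum and CSF cannot be separated by the segmentation post mortem,
#' but on heavily T2-weighted images fluid is bright: voxels of the merged
#' region with intensity strictly greater than the per-subject threshold
#' are excluded; boundary voxels equal to the threshold are retained.
#'
#' @param image a [vol3d()] (bias-corrected intensities).
#' @param region a [vol3d()] binary mask of the merged cerebrum+CSF region.
#' @param threshold intensity cutoff (finite; `Inf` keeps everything).
#' @return A binary [vol3d()] mask; attribute `excluded` counts the
#'   removed voxels.
#' @export
apply_csf_threshold <- function(image, region, threshold) {
  stop_if_grid_mismatch(image, region, "image and region")
  if (is.na(threshold)) stop("threshold must not be NA")
  inside <- region$data > 0
  keep <- inside & (image$data <= threshold)
  if (!any(keep) && any(inside))
    warning("threshold ", threshold,
            " excludes every voxel of the region")
  structure(with_data(region, as.numeric(keep)),
            excluded = sum(inside) - sum(keep))
}

#' Region volume in millilitres
#'
#' Binary sum of the mask voxels multiplied by the voxel volume:
#' `count * prod(spacing) mm^3 * 1e-3 mL/mm^3`.
#' @param mask a [vol3d()] (nonzero = inside).
#' @param voxel_size_mm optional spacing override (length 1 or 3, mm).
#' @export
compute_volume <- function(mask, voxel_size_mm = NULL) {
  spacing <- if (is.null(voxel_size_mm)) mask$spacing
             else rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  sum(mask$data > 0) * prod(spacing) / 1000
}

#' Convert brain volume to estimated weight
#'
#' Multiplies the segmented volume by a literature brain density,
#' 1.08 g/mL by default (configurable; the constant may not hold exactly
#' post mortem).
#' @param volume_mL volume(s) in mL (>= 0).
#' @param density_g_per_mL tissue density (> 0).
#' @return weight in grams.
#' @export
volume_to_weight <- function(volume_mL, density_g_per_mL = 1.08) {
  if (any(volume_mL < 0, na.rm = TRUE)) stop("volume must be >= 0")
  if (density_g_per_mL <= 0) stop("density must be > 0")
  volume_mL * density_g_per_mL
}

#' Load a per-subject cohort table
#'
#' Reads a CSV mirroring the cohort tables: subject id, gestational age
#' (weeks and days), postnatal age where applicable, per-subject CSF
#' threshold, MRI volume (mL), MRI weight (g), manual-segmentation weight
#' and autopsy weight (g); `N/A` marks missing values. The packaged
#' newborn and fetal cohort tables live in
#' `system.file("extdata", package = "pmbrainvol")`.
#'
#' @param path CSV file path.
#' @return data.frame of typed subject records.
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path)
  df <- utils::read.csv(path, na.strings = c("N/A", "NA"),
                        check.names = TRUE)
  if (nrow(df) == 0) stop("empty subject table: ", path)
  required <- c("subject_id", "csf_threshold", "mri_volume_mL",
                "mri_weight_g")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("malformed subject table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  num_cols <- setdiff(names(df), "subject_id")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "")
    if (length(bad))
      stop("malformed value in ", path, " column ", cn, ", row ", bad[1])
    df[[cn]] <- v
  }
  neg <- c("mri_volume_mL", "mri_weight_g", "autopsy_weight_g")
  for (cn in intersect(neg, names(df)))
    if (any(df[[cn]] < 0, na.rm = TRUE))
      stop("negative ", cn, " in ", path)
  df
}

#' Suggest a CSF threshold from the region intensity histogram
#'
#' Experimental helper: finds the deepest valley between the two highest
#' modes of a smoothed intensity histogram of the merged cerebrum+CSF
#' region. Thresholds in the cohort tables were chosen manually; this is
#' an automation aid, not a validated replacement.
#' @param image a [vol3d()].
#' @param region binary [vol3d()] mask.
#' @param bins histogram bins.
#' @export
suggest_csf_threshold <- function(image, region, bins = 128) {
  stop_if_grid_mismatch(image, region, "image and region")
  v <- image$data[region$data > 0]
  if (length(v) < 10) stop("region too small for a histogram")
  d <- stats::density(v, n = bins)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2)
    stop("no bimodal structure found in the region histogram")
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
  d$x[valley]
}

#' Per-subject volumetry report
#'
#' Applies the per-subject CSF threshold to the merged region, computes
#' the retained volume and the density-derived weight.
#' @param image bias-corrected [vol3d()].
#' @param merged_region binary [vol3d()] cerebrum+CSF mask.
#' @param threshold per-subject CSF threshold.
#' @param subject_id identifier for the report row.
#' @param density_g_per_mL brain density.
#' @return one-row data.frame: id, threshold, voxels retained/excluded,
#'   volume (mL), weight (g).
#' @export
volumetry_report <- function(image, merged_region, threshold,
                             subject_id = NA_character_,
                             density_g_per_mL = 1.08) {
  kept <- apply_csf_threshold(image, merged_region, threshold)
  vol <- compute_volume(kept)
  data.frame(subject_id = subject_id, csf_threshold = threshold,
             voxels_retained = sum(kept$data > 0),
             voxels_excluded = unname(attr(kept, "excluded")),
             mri_volume_mL = vol,
             mri_weight_g = volume_to_weight(vol, density_g_per_mL),
             row.names = NULL)
}
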