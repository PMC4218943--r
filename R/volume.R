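#' @useDynLib pmbrainvol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D scalar volume with voxel spacing
#'
#' The unit of all image processing in the package: a 3D numeric array plus
#' its voxel spacing in millimetres. World coordinates are
#' `(voxel index - 1) * spacing` along each axis (axis-aligned grids; the
#' scanner orientation matrix is not modelled).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel edge lengths in mm (recycled from
#'   length 1).
#' @return An object of class `vol3d`: a list with elements `data` and
#'   `spacing`.
#' @export
vol3d <- function(data, spacing = c(0.6, 0.6, 0.6)) {
  if (length(dim(data)) != 3L)
    stop("vol3d needs a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be positive and finite")
  structure(list(data = data, spacing = spacing), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname vol3d
#' @param x object to test.
#' @export
is_vol3d <- function(x) inherits(x, "vol3d")

#' @rdname vol3d
#' @export
vol_dim <- function(x) dim(x$data)

#' Voxel volume in mm^3
#' @param x a [vol3d()].
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Check two volumes share a grid
#' @param a,b [vol3d()] objects.
#' @param tol spacing tolerance (mm).
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$spacing - b$spacing) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid: ",
         paste(dim(a$data), collapse = "x"), " @ ",
         paste(signif(a$spacing, 4), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), " @ ",
         paste(signif(b$spacing, 4), collapse = "x"))
}

#' Build a vol3d on the grid of another, with new data
#' @param x template [vol3d()].
#' @param data replacement array or vector (reshaped to `dim(x$data)`).
#' @export
with_data <- function(x, data) {
  vol3d(array(data, dim = dim(x$data)), x$spacing)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti} preserving voxel spacing through the
#' `pixdim` header field. Label maps round-trip as integer-valued volumes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [vol3d()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol3d(array(as.numeric(img), dim = dim(img)[1:3]),
        RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param x a [vol3d()] to write.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Canonical tissue classes
#'
#' Fixed class order used throughout: cerebrum, cerebellum, brainstem, CSF
#' (label codes 1-4; 0 is background). Ties in any argmax are broken toward
#' the lowest class index.
#' @export
tissue_classes <- function() c("cerebrum", "cerebellum", "brainstem", "csf")

#' Regions kept after merging cerebrum with CSF
#' @export
merged_classes <- function() c("cerebrum_csf", "cerebellum", "brainstem")

#' Default class grouping for the merge stage
#'
#' Cerebrum and CSF collapse into one region; post-mortem T1/T2 convergence
#' makes their intensities inseparable, while keeping CSF as a separate class
#' during EM protects the cerebellum and brainstem (surrounded by fluid).
#' @export
default_merge_groups <- function() {
  list(cerebrum_csf = c("cerebrum", "csf"),
       cerebellum = "cerebellum",
       brainstem = "brainstem")
}

#' Merge labels of an integer label map according to a grouping
#'
#' @param labels a [vol3d()] with integer codes 1..4 per [tissue_classes()]
#'   (0 = background).
#' @param groups named list partitioning [tissue_classes()]; output code is
#'   the position of the group in the list.
#' @return a [vol3d()] label map with merged codes (0 preserved).
#' @export
merge_label_map <- function(labels, groups = default_merge_groups()) {
  classes <- tissue_classes()
  check_partition(groups, classes)
  lut <- integer(length(classes))
  for (g in seq_along(groups)) lut[match(groups[[g]], classes)] <- g
  out <- array(0L, dim = dim(labels$data))
  inside <- labels$data > 0
  out[inside] <- lut[labels$data[inside]]
  with_data(labels, out)
}

check_partition <- function(groups, classes) {
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, classes))
    stop("groups must partition the class set {",
         paste(classes, collapse = ", "), "}")
  invisible(TRUE)
}
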