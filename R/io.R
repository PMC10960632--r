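#' Write / read a beta series as NIfTI
#'
#' The beta stack is stored as a 4-D NIfTI volume (float32) next to a
#' 3-D mask NIfTI and a JSON sidecar holding the trial ids and voxel
#' size. Shapes and voxel sizes are validated on read.
#'
#' @param bs a [beta_series()].
#' @param path output path without extension; writes `<path>.nii.gz`,
#'   `<path>_mask.nii.gz`, `<path>.json`.
#' @return (invisibly) the main file path.
#' @export
write_beta_series <- function(bs, path) {
  stopifnot(inherits(bs, "beta_series"))
  arr <- array(bs$data, dim = c(bs$dim3, ncol(bs$data)))
  vs <- rep(bs$voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = vs),
                     paste0(path, ".nii.gz"))
  mask_arr <- array(as.numeric(bs$mask), dim = bs$dim3)
  RNifti::writeNifti(RNifti::asNifti(mask_arr, pixdim = vs),
                     paste0(path, "_mask.nii.gz"))
  jsonlite::write_json(list(trial_id = bs$trial_id,
                            voxel_size_mm = bs$voxel_size_mm),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(paste0(path, ".nii.gz"))
}

#' @rdname write_beta_series
#' @export
read_beta_series <- function(path) {
  arr <- RNifti::readNifti(paste0(path, ".nii.gz"))
  mask_arr <- RNifti::readNifti(paste0(path, "_mask.nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- dim(arr)
  if (length(d) != 4)
    stop("read_beta_series: expected a 4-D volume", call. = FALSE)
  if (!identical(dim(mask_arr), d[1:3]))
    stop("read_beta_series: mask grid mismatch", call. = FALSE)
  mask <- as.vector(mask_arr) > 0
  if (!any(mask))
    stop("read_beta_series: empty mask rejected", call. = FALSE)
  beta_series(matrix(as.vector(arr), prod(d[1:3]), d[4]),
              d[1:3], side$trial_id, mask = mask,
              voxel_size_mm = side$voxel_size_mm)
}

#' Write / read a trial table as TSV
#'
#' Tab-separated values with a header row; `NA` encoded as `n/a`
#' following BIDS events conventions.
#'
#' @param design trial table.
#' @param path file path.
#' @return (invisibly) the path; `read_trial_table` returns the table.
#' @export
write_trial_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    stringsAsFactors = FALSE)
}

#' Write a 3-D statistic map as NIfTI
#'
#' @param values full-grid numeric vector (NA allowed).
#' @param dim3 grid dimensions.
#' @param path output file (`.nii.gz`).
#' @param voxel_size_mm isotropic voxel size.
#' @return (invisibly) the path.
#' @export
write_stat_map <- function(values, dim3, path, voxel_size_mm = 2) {
  arr <- array(values, dim = dim3)
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(voxel_size_mm, 3)),
                     path)
  invisible(path)
}
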