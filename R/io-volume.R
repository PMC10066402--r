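#' Read a 3-D NIfTI volume
#'
#' Thin wrapper around RNifti that enforces the pipeline's contract: volumes
#' must be 3-D and non-negative, masks binary. Grid metadata (shape, affine)
#' travels with the data so downstream stages can reject mismatched grids.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3-D array), `shape` (integer vector of length
#'   3) and `affine` (4x4 matrix).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("volume not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 3) {
    abort(sprintf("expected a 3-D volume, got %d dimensions: %s",
                  length(d), path))
  }
  if (any(arr < 0)) abort(sprintf("volume contains negative values: %s", path))
  list(data = array(as.numeric(arr), dim = d),
       shape = as.integer(d),
       affine = structure(RNifti::xform(img), class = "matrix"))
}

#' Write a 3-D array as NIfTI
#'
#' @param data 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path) {
  if (length(dim(data)) != 3) abort("`data` must be a 3-D array")
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

is_binary <- function(x) all(x %in% c(0, 1))
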