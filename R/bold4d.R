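#' Construct a 4D BOLD scan object
#'
#' Container for one subject's functional run: a 4D array of voxel values
#' (x, y, z, t), the repetition time in seconds, a 3D brain mask, and a
#' subject identifier. This is the raw material for quality control and the
#' group decomposition.
#'
#' @param voxels 4D numeric array, spatial dims first, time last.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param mask 3D logical array matching the spatial dimensions; `NULL` means
#'   all voxels in-mask.
#' @param subject_id Character scalar naming the subject.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(voxels, tr_seconds, mask = NULL, subject_id = "subject") {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    abort("`voxels` must be a 4D array (x, y, z, t).")
  }
  dims <- dim(voxels)
  if (dims[4] < 2L) abort("A BOLD scan needs at least 2 timepoints.")
  tr_seconds <- check_number(tr_seconds, "tr_seconds", min = 1e-6)
  if (is.null(mask)) {
    mask <- array(TRUE, dims[1:3])
  }
  if (!identical(dim(mask), dims[1:3])) {
    abort("`mask` dimensions must equal the spatial dimensions of `voxels`.")
  }
  mask <- array(as.logical(mask), dims[1:3])
  if (!any(mask)) abort("`mask` must contain at least one in-mask voxel.")
  structure(
    list(voxels = voxels, tr_seconds = tr_seconds, mask = mask,
         subject_id = as.character(subject_id)),
    class = "bold4d"
  )
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bold4d> %s: %dx%dx%d x %d volumes, TR = %g s, %d in-mask voxels\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

# In-mask data matrix, t x v, voxel order = column-major order of the mask.
bold_matrix <- function(scan) {
  d <- dim(scan$voxels)
  m <- matrix(scan$voxels, prod(d[1:3]), d[4])
  t(m[as.vector(scan$mask), , drop = FALSE])
}

#' Write a BOLD scan to NIfTI-1
#'
#' Stores the 4D data with the repetition time recorded in the time-axis
#' header field (`pixdim[4]`), and optionally the mask as a byte volume
#' alongside it.
#'
#' @param scan A [bold4d()] object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param mask_path Optional path for the mask volume.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(scan, path, mask_path = NULL) {
  stopifnot(inherits(scan, "bold4d"))
  img <- RNifti::asNifti(scan$voxels)
  RNifti::pixdim(img) <- c(1, 1, 1, scan$tr_seconds)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(scan$mask), dim(scan$mask))),
                       mask_path)
  }
  invisible(path)
}

#' Read a BOLD scan from NIfTI-1
#'
#' @param path NIfTI file with 4D data; TR is taken from the time-axis pixdim.
#' @param mask_path Optional NIfTI mask volume (nonzero = in-mask).
#' @param subject_id Subject identifier; defaults to the file name.
#' @param tr_seconds Override for the repetition time if the header lacks one.
#' @return A [bold4d()] object.
#' @export
read_bold_nifti <- function(path, mask_path = NULL, subject_id = NULL,
                            tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  tr <- tr_seconds %||% RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) {
    abort(sprintf("No usable TR in the header of '%s'; pass `tr_seconds`.", path))
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m) != 0, dim(m))
  }
  bold4d(arr, tr_seconds = tr, mask = mask,
         subject_id = subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}
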