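#' A single subject's 4D BOLD run
#'
#' Container for one resting-state acquisition: a 4D array (x, y, z, time),
#' the repetition time, a 4x4 voxel-to-world affine and a binary brain mask
#' aligned with the spatial grid.  All per-subject computations
#' ([discard_initial_volumes()], [bandpass_filter()], [compute_dynamic_alff()],
#' ...) take and return objects of this class.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t), arbitrary signal
#'   units.
#' @param tr_s Repetition time in seconds (time between consecutive volumes).
#' @param affine 4x4 voxel-to-world transform (mm); 0-based voxel index
#'   convention.  Defaults to an axial grid with `voxel_size_mm` spacing.
#' @param mask 3D logical (or 0/1) array marking in-brain voxels; defaults to
#'   the full grid.
#' @param voxel_size_mm Isotropic voxel edge length used to build the default
#'   affine when none is given.
#'
#' @return An object of class `bold_run`: a list with elements `data`, `tr_s`,
#'   `affine` and `mask`.
#' @examples
#' run <- bold_run(array(rnorm(4 * 4 * 4 * 20), c(4, 4, 4, 20)), tr_s = 2)
#' run
#' @export
bold_run <- function(data, tr_s, affine = NULL, mask = NULL,
                     voxel_size_mm = 3) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, t)", call. = FALSE)
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a single positive number of seconds", call. = FALSE)
  d <- dim(data)
  if (is.null(affine)) affine <- diag(c(rep(voxel_size_mm, 3), 1))
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), dim(mask))
  if (!all(dim(mask) == d[1:3]))
    stop("mask and data spatial dimensions disagree", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  inmask <- data[rep(mask, d[4])]
  if (any(!is.finite(inmask)))
    stop("non-finite values inside the mask", call. = FALSE)
  structure(list(data = data, tr_s = tr_s, affine = affine, mask = mask),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  vs <- .voxel_size_from_affine(x$affine)
  cat(sprintf("<bold_run> %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TR %.3g s, voxel %s mm, %d / %d voxels in mask\n",
              x$tr_s, paste(signif(vs, 3), collapse = " x "),
              sum(x$mask), prod(d[1:3])))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

#' Number of volumes in a BOLD run
#' @param run A [bold_run()].
#' @return Integer count of time points.
#' @export
n_volumes <- function(run) dim(run$data)[4]

#' Read / write a BOLD run as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}.  `write_bold_run()` stores the data
#' with the run's affine as the sform and the TR in the fourth pixdim slot;
#' `read_bold_run()` recovers them (an explicit `tr_s` overrides the header).
#'
#' @param run A [bold_run()].
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask_path Optional path to a 3D mask NIfTI.
#' @param tr_s Optional repetition time override (seconds).
#' @return `read_bold_run()` returns a [bold_run()]; `write_bold_run()`
#'   returns `path` invisibly.
#' @export
write_bold_run <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`sform<-`(img, structure(run$affine, code = 2L))
  hdr <- RNifti::niftiHeader(img)
  pd <- hdr$pixdim
  pd[5] <- run$tr_s
  img <- RNifti::asNifti(img, list(pixdim = pd))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(path, mask_path = NULL, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (is.null(tr_s)) tr_s <- hdr$pixdim[5]
  if (!is.finite(tr_s) || tr_s <= 0)
    stop("TR not present in header; supply tr_s", call. = FALSE)
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  mask <- if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    array(as.numeric(mimg) != 0, dim(mimg)[1:3])
  } else NULL
  bold_run(array(as.numeric(img), dim(img)), tr_s = tr_s, affine = affine,
           mask = mask)
}

#' Write a 3D map as NIfTI
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, affine, path) {
  img <- RNifti::asNifti(values)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
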