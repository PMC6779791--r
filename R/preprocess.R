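#' Head-motion trace
#'
#' Per-volume rigid-body realignment parameters: three translations (mm) and
#' three rotations (radians).  Used by [framewise_displacement()] and
#' [motion_exclusion_check()]; the package does not estimate motion itself
#' (simulated data carry none), it consumes realignment output.
#'
#' @param translations Numeric T x 3 matrix of translations in mm.
#' @param rotations Numeric T x 3 matrix of rotations in radians.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    stop("translations and rotations must each have 3 columns", call. = FALSE)
  if (nrow(translations) != nrow(rotations))
    stop("translations and rotations must have the same number of rows",
         call. = FALSE)
  if (nrow(translations) < 1L) stop("empty motion trace", call. = FALSE)
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' Read a 6-column motion parameter file
#'
#' Plain whitespace- or comma-delimited text, one row per volume: three
#' translations (mm) followed by three rotations (radians).
#'
#' @param path File path.
#' @return A [motion_trace()].
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE, sep = "",
                            comment.char = "#"))
  if (ncol(m) == 1L)
    m <- as.matrix(read.csv(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion file must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Framewise displacement (Power convention)
#'
#' FD at volume t is the sum of absolute backward differences of the six
#' realignment parameters, with rotations converted to arc length on a
#' sphere of radius `radius_mm`:
#' `FD(t) = sum |delta translation| + radius_mm * sum |delta rotation|`,
#' and `FD(1) = 0`.
#'
#' @param trace A [motion_trace()].
#' @param radius_mm Head radius for the rotation arc-length conversion
#'   (default 50 mm).
#' @return List with `fd` (per-volume series) and `mean_fd`.
#' @export
framewise_displacement <- function(trace, radius_mm = 50) {
  stopifnot(inherits(trace, "motion_trace"))
  Tn <- nrow(trace$translations)
  if (Tn < 2L) stop("need at least 2 volumes to compute FD", call. = FALSE)
  dt <- abs(diff(trace$translations))
  dr <- abs(diff(trace$rotations))
  fd <- c(0, rowSums(dt) + radius_mm * rowSums(dr))
  list(fd = fd, mean_fd = mean(fd))
}

#' Subject-level head-motion exclusion rule
#'
#' A subject fails if any absolute translation exceeds `max_translation_mm`,
#' any absolute rotation exceeds `max_rotation_deg` (compared in degrees), or
#' mean framewise displacement exceeds `max_mean_fd`.  Defaults implement the
#' conventional 2 mm / 2 degree / 0.3 rule.
#'
#' @param trace A [motion_trace()].
#' @param mean_fd Optional precomputed mean FD; computed from `trace` (Power
#'   convention, 50 mm radius) when `NULL`.
#' @param max_translation_mm,max_rotation_deg,max_mean_fd Rule thresholds.
#' @return List with `pass` (logical) and `reasons` (character vector naming
#'   each violated rule; empty when passing).
#' @export
motion_exclusion_check <- function(trace, mean_fd = NULL,
                                   max_translation_mm = 2,
                                   max_rotation_deg = 2,
                                   max_mean_fd = 0.3) {
  stopifnot(inherits(trace, "motion_trace"))
  if (is.null(mean_fd)) mean_fd <- framewise_displacement(trace)$mean_fd
  reasons <- character(0)
  if (max(abs(trace$translations)) > max_translation_mm)
    reasons <- c(reasons, sprintf("translation: max |displacement| %.3g mm > %g mm",
                                  max(abs(trace$translations)),
                                  max_translation_mm))
  rot_deg <- abs(trace$rotations) * 180 / pi
  if (max(rot_deg) > max_rotation_deg)
    reasons <- c(reasons, sprintf("rotation: max |rotation| %.3g deg > %g deg",
                                  max(rot_deg), max_rotation_deg))
  if (mean_fd > max_mean_fd)
    reasons <- c(reasons, sprintf("mean FD: %.3g > %g", mean_fd, max_mean_fd))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Drop initial volumes of a run
#'
#' Removes the first `k` time points (scanner equilibration / subject
#' adaptation period); the conventional protocol discards 10 of 185 acquired
#' volumes, leaving 175 for analysis.
#'
#' @param run A [bold_run()].
#' @param k Number of leading volumes to drop (`0 <= k <` run length).
#' @return A [bold_run()] with `T - k` volumes, order preserved.
#' @export
discard_initial_volumes <- function(run, k) {
  stopifnot(inherits(run, "bold_run"))
  Tn <- n_volumes(run)
  if (k < 0 || k >= Tn)
    stop(sprintf("k must satisfy 0 <= k < %d volumes", Tn), call. = FALSE)
  if (k == 0L) return(run)
  run$data <- run$data[, , , (k + 1):Tn, drop = FALSE]
  run
}

#' Friston-24 expansion of motion parameters
#'
#' The 24-parameter motion model: the six realignment parameters, the same
#' six at the previous volume (zero for the first), and the squares of both
#' sets.
#'
#' @param trace A [motion_trace()].
#' @return T x 24 numeric matrix with descriptive column names.
#' @export
friston24 <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  p <- cbind(trace$translations, trace$rotations)
  colnames(p) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  colnames(out) <- c(colnames(p), paste0(colnames(p), "_lag"),
                     paste0(colnames(p), "_sq"),
                     paste0(colnames(p), "_lag_sq"))
  out
}

#' Voxelwise nuisance regression
#'
#' Replaces every voxel series by its ordinary-least-squares residual
#' against an intercept, an optional linear trend (drift removal) and the
#' supplied nuisance regressors (e.g. [friston24()] expansion, mean white
#' matter and CSF signals).  The output is orthogonal to every retained
#' regressor.  Collinear columns are dropped with a warning naming them.
#'
#' @param run A [bold_run()].
#' @param nuisance Optional T x q numeric matrix of nuisance regressors
#'   (rows = retained volumes).
#' @param detrend Include a linear trend column (default `TRUE`).
#' @return A [bold_run()] of residuals.
#' @export
regress_nuisance <- function(run, nuisance = NULL, detrend = TRUE) {
  stopifnot(inherits(run, "bold_run"))
  Tn <- n_volumes(run)
  X <- matrix(1, Tn, 1, dimnames = list(NULL, "intercept"))
  if (detrend)
    X <- cbind(X, trend = seq_len(Tn) - (Tn + 1) / 2)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != Tn)
      stop("nuisance rows must equal the number of volumes", call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning(sprintf("dropping collinear nuisance column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  m <- .time_matrix(run$data)
  res <- qr.resid(qx, m)
  run$data <- .from_time_matrix(res, dim(run$data)[1:3])
  run
}

#' Ideal Fourier band-pass filter
#'
#' Zeros every DFT coefficient whose frequency lies outside `[lo_hz, hi_hz]`
#' (including the DC bin, so the output has zero mean) and inverts the
#' transform.  The ideal mask matches the spectral definition of ALFF
#' exactly -- the retained bins are precisely those ALFF averages over --
#' and it is idempotent: filtering twice equals filtering once.
#'
#' @param run A [bold_run()].
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo < hi <` Nyquist.
#' @return A filtered [bold_run()].
#' @export
bandpass_filter <- function(run, lo_hz = 0.01, hi_hz = 0.08) {
  stopifnot(inherits(run, "bold_run"))
  .check_band(c(lo_hz, hi_hz), run$tr_s)
  m <- .time_matrix(run$data)
  Tn <- nrow(m)
  f <- (seq_len(Tn) - 1) / (Tn * run$tr_s)
  f <- pmin(f, 1 / run$tr_s - f)          # fold to [0, Nyquist]
  keep <- f >= lo_hz - 1e-12 & f <= hi_hz + 1e-12
  Fm <- mvfft(m)
  Fm[!keep, ] <- 0
  run$data <- .from_time_matrix(Re(mvfft(Fm, inverse = TRUE)) / Tn,
                                dim(run$data)[1:3])
  run
}

#' Gaussian spatial smoothing
#'
#' Per-volume separable Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, converted to voxel units by
#' the run's voxel size (taken from the affine).  `fwhm_mm = 0` is the
#' identity.  Boundaries are zero-padded, so interior mass is conserved.
#'
#' @param run A [bold_run()].
#' @param fwhm_mm Full width at half maximum in mm, `>= 0` (default 6).
#' @return A smoothed [bold_run()].
#' @export
spatial_smooth <- function(run, fwhm_mm = 6) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(run)
  vs <- .voxel_size_from_affine(run$affine)
  if (max(vs) - min(vs) > 1e-8 * max(vs)) {
    # anisotropic voxels: smooth axis by axis with per-axis kernels
    d <- dim(run$data)
    arr <- run$data
    for (ax in 1:3) {
      k <- .gauss_kernel_1d(.fwhm_to_sigma_vox(fwhm_mm, vs[ax]))
      arr <- .axis_smooth(arr, ax, k)
    }
    run$data <- arr
  } else {
    run$data <- .smooth_spatial(run$data, fwhm_mm, vs[1])
  }
  run
}

# Smooth one spatial axis of a 3D/4D array with a 1D kernel (R fallback for
# anisotropic voxels; the isotropic path uses the compiled kernel).
.axis_smooth <- function(arr, axis, k) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  b <- aperm(arr, perm)
  db <- dim(b)
  r <- (length(k) - 1) / 2
  n <- db[1]
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    S[i, j] <- k[j - i + r + 1]
  }
  b <- S %*% matrix(b, n)
  dim(b) <- db
  aperm(b, order(perm))
}
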