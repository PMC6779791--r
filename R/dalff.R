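#' Sliding-window specification
#'
#' Window length and step in volumes (TRs).  The default 50-TR window with a
#' 1-TR step segments a 175-volume run into 126 windows.
#'
#' @param length_tr Window length in volumes, `>= 1`.
#' @param step_tr Step between consecutive window starts, `>= 1`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_tr = 50L, step_tr = 1L) {
  length_tr <- as.integer(length_tr)
  step_tr <- as.integer(step_tr)
  if (length_tr < 1L) stop("window length must be >= 1", call. = FALSE)
  if (step_tr < 1L) stop("window step must be >= 1", call. = FALSE)
  structure(list(length_tr = length_tr, step_tr = step_tr),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> length %d TR, step %d TR\n",
              x$length_tr, x$step_tr))
  invisible(x)
}

#' Sliding-window index table
#'
#' Enumerates the `floor((T - w) / s) + 1` windows of length `w` advancing
#' by `s` volumes.  Indices are 1-based and inclusive.
#'
#' @param n_volumes Run length `T` in volumes.
#' @param spec A [window_spec()].
#' @return Data frame with columns `start` and `end`, one row per window in
#'   temporal order.
#' @examples
#' nrow(window_indices(175, window_spec(50, 1)))  # 126
#' @export
window_indices <- function(n_volumes, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  w <- spec$length_tr; s <- spec$step_tr
  if (w > n_volumes)
    stop(sprintf("window length %d exceeds run length %d", w, n_volumes),
         call. = FALSE)
  starts <- seq.int(1L, n_volumes - w + 1L, by = s)
  data.frame(start = starts, end = starts + w - 1L)
}

#' ALFF of a single series
#'
#' The amplitude of low-frequency fluctuations: the mean, over the DFT bins
#' whose frequencies fall inside `band`, of the single-sided amplitude
#' spectrum `a(f) = (2/N) |X(f)|` of the demeaned series.  Averaging (rather
#' than summing) over bins makes values comparable across window lengths.
#' A sinusoid of amplitude `A` at one exact in-band bin yields
#' `A / n_band_bins`.
#'
#' @param series Numeric vector, length `>= 8`, finite.
#' @param tr_s Sampling interval (s).
#' @param band `(lo, hi)` in Hz.
#' @return Non-negative scalar; 0 for a constant (or all-zero) series.
#' @export
compute_alff <- function(series, tr_s, band = c(0.01, 0.08)) {
  if (length(series) < 8) stop("series must have >= 8 samples", call. = FALSE)
  if (any(!is.finite(series))) stop("series must be finite", call. = FALSE)
  .check_band(band, tr_s)
  n <- length(series)
  bins <- .inband_bins(n, tr_s, band)
  if (length(bins) == 0L) return(0)
  amp <- 2 * Mod(fft(series - mean(series))[bins + 1L]) / n
  mean(amp)
}

#' Static (whole-run) ALFF map
#'
#' Applies [compute_alff()] to the full-length series of every in-mask
#' voxel.
#'
#' @param run A preprocessed [bold_run()].
#' @param band `(lo, hi)` in Hz.
#' @return An object of class `alff_map`: list with `values` (3D array, zero
#'   outside the mask), `band` and `mask`.
#' @export
compute_static_alff <- function(run, band = c(0.01, 0.08)) {
  stopifnot(inherits(run, "bold_run"))
  .check_band(band, run$tr_s)
  if (!any(run$mask)) stop("mask is empty", call. = FALSE)
  m <- .time_matrix(run$data)
  n <- nrow(m)
  bins <- .inband_bins(n, run$tr_s, band)
  amp <- .stft_band_amplitude(m, n, 1L, as.integer(bins))  # V x 1
  vals <- array(drop(amp), dim(run$data)[1:3])
  vals[!run$mask] <- 0
  structure(list(values = vals, band = band, mask = run$mask),
            class = "alff_map")
}

#' @export
print.alff_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<alff_map> %s, band %g-%g Hz, in-mask mean %.4g (SD %.4g)\n",
              paste(dim(x$values), collapse = "x"),
              x$band[1], x$band[2], mean(v), sd(v)))
  invisible(x)
}

#' Sliding-window dynamic ALFF maps
#'
#' Computes ALFF inside every sliding window of the run and summarises each
#' voxel's windowed values by their mean, standard deviation (denominator
#' `n_windows - 1`) and coefficient of variation `CV = SD / mean`.  The SD
#' and CV maps quantify the temporal variability of spontaneous
#' low-frequency activity; the CV map is the default input to group
#' inference.  Voxels whose mean windowed ALFF falls below `eps` get
#' `CV = 0` and are flagged (background protection against division
#' blow-ups).
#'
#' @param run A preprocessed [bold_run()].
#' @param spec A [window_spec()]; window length must not exceed the run
#'   length.
#' @param band `(lo, hi)` in Hz.
#' @param keep_stack Retain the full per-window ALFF stack as a 4D array
#'   (x, y, z, window)?  Default `FALSE` to save memory.
#' @param eps Mean-ALFF floor below which CV is set to 0.
#' @return An object of class `dalff_maps`: list with `mean_map`, `sd_map`,
#'   `cv_map` (3D arrays, zero outside the mask), `n_windows`, `spec`,
#'   `band`, `flagged` (3D logical) and optionally `window_stack`.
#' @examples
#' run <- bold_run(array(rnorm(2 * 2 * 2 * 60), c(2, 2, 2, 60)), tr_s = 2)
#' maps <- compute_dynamic_alff(run, window_spec(30, 1))
#' maps$n_windows  # 31
#' @export
compute_dynamic_alff <- function(run, spec = window_spec(),
                                 band = c(0.01, 0.08), keep_stack = FALSE,
                                 eps = 1e-12) {
  stopifnot(inherits(run, "bold_run"), inherits(spec, "window_spec"))
  .check_band(band, run$tr_s)
  Tn <- n_volumes(run)
  w <- spec$length_tr
  if (w > Tn)
    stop(sprintf("window length %d exceeds run length %d", w, Tn),
         call. = FALSE)
  bins <- .inband_bins(w, run$tr_s, band)
  if (length(bins) == 0L)
    stop("band contains no DFT bins at this window length", call. = FALSE)
  m <- .time_matrix(run$data)
  A <- .stft_band_amplitude(m, w, spec$step_tr, as.integer(bins))  # V x nwin
  nwin <- ncol(A)
  sdim <- dim(run$data)[1:3]
  mu <- rowMeans(A)
  if (nwin > 1L) {
    sdv <- sqrt(pmax(rowSums(A * A) - nwin * mu^2, 0) / (nwin - 1))
  } else {
    warning("single window: SD across windows is undefined, returning zeros",
            call. = FALSE)
    sdv <- rep(0, length(mu))
  }
  flagged <- mu < eps
  cv <- ifelse(flagged, 0, sdv / mu)
  shape <- function(v) { a <- array(v, sdim); a[!run$mask] <- 0; a }
  out <- list(mean_map = shape(mu), sd_map = shape(sdv), cv_map = shape(cv),
              n_windows = nwin, spec = spec, band = band, mask = run$mask,
              flagged = array(flagged & as.vector(run$mask), sdim))
  if (keep_stack) out$window_stack <- array(A, c(sdim, nwin))
  structure(out, class = "dalff_maps")
}

#' @export
print.dalff_maps <- function(x, ...) {
  msk <- x$mask
  cat(sprintf("<dalff_maps> %s, %d windows (length %d, step %d), band %g-%g Hz\n",
              paste(dim(x$mean_map), collapse = "x"), x$n_windows,
              x$spec$length_tr, x$spec$step_tr, x$band[1], x$band[2]))
  if (any(msk))
    cat(sprintf("  in-mask CV mean %.3g (SD %.3g); %d flagged voxel(s)\n",
                mean(x$cv_map[msk]), sd(x$cv_map[msk]), sum(x$flagged)))
  invisible(x)
}

#' Z-score a map within a mask
#'
#' Standardises the in-mask voxels to mean 0, SD 1 (voxels outside the mask
#' are set to 0).  Applied per subject before group-level modelling it
#' removes inter-subject scanner scaling; it preserves rank order and is
#' invariant to affine transforms of the input.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array, non-empty.
#' @return 3D array of z-scores.
#' @export
standardize_map <- function(map, mask) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- map[mask]
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("in-mask standard deviation is zero; cannot standardize",
         call. = FALSE)
  out <- array(0, dim(map))
  out[mask] <- (v - mean(v)) / s
  out
}
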