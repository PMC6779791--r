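#' Configuration of the synthetic two-group cohort
#'
#' Collects every knob of the synthetic-data generator.  The defaults mirror
#' the acquisition and cohort the analysis assumes -- two groups of 28
#' subjects, TR 2 s, 185 volumes, a 0.01-0.08 Hz pass band, 3 mm voxels and
#' 6 mm smoothing -- on a compact 16x16x16 grid so a full cohort simulates in
#' seconds.  Patients receive a slow sinusoidal amplitude modulation of the
#' in-band carrier inside a spherical effect region, which raises the
#' across-window variability of windowed ALFF while leaving its mean
#' essentially unchanged; per-subject modulation depth is coupled to the
#' simulated disease duration.
#'
#' @param n_per_group Subjects per group.
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size_mm Voxel edge length (mm).
#' @param tr_s Repetition time (s).
#' @param n_volumes Acquired volumes per run, before any discard.
#' @param band_lo_hz,band_hi_hz Pass band (Hz); must satisfy
#'   `0 < lo < hi < 1/(2 tr_s)`.
#' @param effect_center_vox Integer triple, centre of the planted sphere
#'   (1-based voxel indices).
#' @param effect_radius_vox Sphere radius in voxels (may be fractional).
#' @param modulation_depth Mean amplitude-modulation depth `d >= 0` for the
#'   patient group (unitless; 0 disables the effect).
#' @param mod_freq_hz Frequency of the modulating envelope (Hz); must lie
#'   below `band_lo_hz` so the envelope is slow relative to the carrier.
#' @param duration_coupling Slope (per year) tying each patient's depth to
#'   their disease duration: `d_i = modulation_depth +
#'   duration_coupling * (duration_i - mean duration)`, floored at 0.
#' @param noise_sd White-noise standard deviation added to every voxel
#'   (carrier series have unit expected SD).
#' @param smooth_fwhm_mm FWHM (mm) of the Gaussian spatial smoothing applied
#'   to the noise field, giving the maps the spatial smoothness that
#'   random-field cluster inference assumes.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_group = 28L,
                       grid_shape = c(16L, 16L, 16L),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_volumes = 185L,
                       band_lo_hz = 0.01,
                       band_hi_hz = 0.08,
                       effect_center_vox = c(8L, 8L, 8L),
                       effect_radius_vox = 2.5,
                       modulation_depth = 0.6,
                       mod_freq_hz = 0.005,
                       duration_coupling = 0.05,
                       noise_sd = 1,
                       smooth_fwhm_mm = 6,
                       seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, tr_s = tr_s,
              n_volumes = as.integer(n_volumes),
              band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
              effect_center_vox = effect_center_vox,
              effect_radius_vox = effect_radius_vox,
              modulation_depth = modulation_depth,
              mod_freq_hz = mod_freq_hz,
              duration_coupling = duration_coupling,
              noise_sd = noise_sd, smooth_fwhm_mm = smooth_fwhm_mm,
              seed = as.integer(seed))
  if (cfg$n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stop("grid_shape must be three positive integers", call. = FALSE)
  if (cfg$n_volumes < 8L) stop("n_volumes too small", call. = FALSE)
  .check_band(c(band_lo_hz, band_hi_hz), tr_s)
  if (cfg$modulation_depth < 0)
    stop("modulation_depth must be >= 0", call. = FALSE)
  if (cfg$mod_freq_hz >= cfg$band_lo_hz)
    stop("mod_freq_hz must lie below band_lo_hz (slow envelope)",
         call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(cfg$effect_center_vox - cfg$effect_radius_vox < 1) ||
      any(cfg$effect_center_vox + cfg$effect_radius_vox > cfg$grid_shape))
    stop("effect region must lie fully inside the grid", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d + %d subjects, grid %s, voxel %g mm, TR %g s, %d volumes\n",
              x$n_per_group, x$n_per_group,
              paste(x$grid_shape, collapse = "x"),
              x$voxel_size_mm, x$tr_s, x$n_volumes))
  cat(sprintf("  band %g-%g Hz, depth %g (coupling %g/yr), noise SD %g, smooth %g mm, seed %d\n",
              x$band_lo_hz, x$band_hi_hz, x$modulation_depth,
              x$duration_coupling, x$noise_sd, x$smooth_fwhm_mm, x$seed))
  invisible(x)
}

# Draw one band-limited series (or a matrix of them) using the *current*
# RNG state.  Construction is purely Fourier-domain: complex-Gaussian
# coefficients at the in-band bins, Hermitian symmetry, inverse DFT.  The
# DC bin is zero, so the series has exactly zero mean; the scale gives unit
# expected variance per time point.
.band_noise <- function(n, tr_s, band, n_series = 1L) {
  bins <- .inband_bins(n, tr_s, band)
  nb <- length(bins)
  if (nb == 0L) stop("band contains no DFT bins at this length/TR",
                     call. = FALSE)
  re <- matrix(rnorm(nb * n_series), nb, n_series)
  im <- matrix(rnorm(nb * n_series), nb, n_series)
  .band_synth(re, im, as.integer(bins), as.integer(n))
}

#' Band-limited Gaussian noise series
#'
#' Generates a zero-mean Gaussian series whose spectral energy lies entirely
#' inside `[lo, hi]` Hz, by placing random-phase complex-Gaussian
#' coefficients at the in-band DFT bins only and inverting the transform.
#' The series has unit expected variance per time point.
#'
#' @param n Number of samples (>= 8).
#' @param tr_s Sampling interval in seconds.
#' @param band Numeric `(lo, hi)` in Hz, `0 < lo < hi <` Nyquist.
#' @param seed Optional integer seed; if given the call is reproducible.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- band_limited_noise(175, 2, c(0.01, 0.08), seed = 1)
#' mean(x)  # exactly 0 up to round-off
#' @export
band_limited_noise <- function(n, tr_s, band, seed = NULL) {
  if (n < 8) stop("n must be >= 8", call. = FALSE)
  .check_band(band, tr_s)
  if (!is.null(seed)) set.seed(seed)
  drop(.band_noise(n, tr_s, band))
}

#' Amplitude-modulated band-limited series
#'
#' Multiplies a band-limited carrier by a slow sinusoidal envelope
#' `1 + d sin(2 pi f_mod t + phi)`, the generative mechanism behind the
#' planted dynamic-ALFF effect: the envelope makes the windowed in-band
#' amplitude wax and wane (raising its SD across sliding windows) while the
#' long-run mean amplitude is nearly unchanged.  With `depth = 0` the
#' output is bit-identical to [band_limited_noise()] at the same seed.
#'
#' @inheritParams band_limited_noise
#' @param depth Modulation depth `d >= 0`.
#' @param mod_freq_hz Envelope frequency (Hz), below `band[1]`.
#' @return Numeric vector of length `n`.
#' @export
amplitude_modulated_series <- function(n, tr_s, band, depth, mod_freq_hz,
                                       seed = NULL) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (mod_freq_hz >= band[1])
    stop("mod_freq_hz must be below the band lower edge", call. = FALSE)
  if (n < 8) stop("n must be >= 8", call. = FALSE)
  .check_band(band, tr_s)
  if (!is.null(seed)) set.seed(seed)
  x <- drop(.band_noise(n, tr_s, band))
  if (depth == 0) return(x)
  phi <- runif(1, 0, 2 * pi)
  tt <- (seq_len(n) - 1) * tr_s
  x * (1 + depth * sin(2 * pi * mod_freq_hz * tt + phi))
}

#' Spherical effect mask
#'
#' Marks every voxel whose Euclidean distance (in voxel units) from
#' `center_vox` is at most `radius_vox`.
#'
#' @param grid_shape Integer triple of grid dimensions.
#' @param center_vox Integer triple, 1-based centre voxel.
#' @param radius_vox Radius in voxels, `>= 0` (0 gives the centre voxel only).
#' @return 3D logical array.
#' @examples
#' sum(build_effect_mask(c(16, 16, 16), c(8, 8, 8), 2.5))  # 81 voxels
#' @export
build_effect_mask <- function(grid_shape, center_vox, radius_vox) {
  if (radius_vox < 0) stop("radius_vox must be >= 0", call. = FALSE)
  if (any(center_vox < 1) || any(center_vox > grid_shape))
    stop("center must lie inside the grid", call. = FALSE)
  if (any(center_vox - radius_vox < 1) ||
      any(center_vox + radius_vox > grid_shape))
    stop("sphere must lie fully inside the grid", call. = FALSE)
  g <- expand.grid(x = seq_len(grid_shape[1]),
                   y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- (g$x - center_vox[1])^2 + (g$y - center_vox[2])^2 +
    (g$z - center_vox[3])^2
  array(d2 <= radius_vox^2 + 1e-9, grid_shape)
}

# Covariate draws for the whole cohort (patients first).  Location/scale
# follow the demographics the analysis is designed around: matched age and
# sex, patient-only disease measures, slightly lower MoCA in patients.
.draw_covariates <- function(n) {
  n2 <- 2L * n
  grp <- rep(c("patient", "control"), each = n)
  age <- round(rnorm(n2, 59, 8), 1)
  sex <- ifelse(rbinom(n2, 1L, 0.5) == 1L, "F", "M")
  duration <- pmax(0.5, round(rnorm(n, 8.46, 2.92), 1))
  updrs <- pmax(5, round(rnorm(n, 29.1, 8.7)))
  hy <- pmin(5, pmax(1, round(rnorm(n, 2.02, 0.71) * 2) / 2))
  moca <- pmin(30, round(c(rnorm(n, 24.39, 2.52), rnorm(n, 25.86, 1.73))))
  mmse <- pmin(30, round(c(rnorm(n, 27.64, 1.25), rnorm(n, 27.71, 1.24))))
  mean_fd <- round(pmin(0.29, pmax(0.02, rnorm(n2, 0.12, 0.05))), 3)
  data.frame(subject_id = sprintf("sub-%03d", seq_len(n2)),
             group = factor(grp, levels = c("control", "patient")),
             age = age, sex = sex,
             duration_years = c(duration, rep(NA_real_, n)),
             updrs_iii = c(updrs, rep(NA_real_, n)),
             hy_stage = c(hy, rep(NA_real_, n)),
             moca = moca, mmse = mmse, mean_fd = mean_fd,
             stringsAsFactors = FALSE)
}

# One subject's 4D run: band-limited carriers at every voxel, a slow
# amplitude modulation of depth `depth` inside `effect_mask` (patients
# only), plus spatially smoothed white noise.
.simulate_run <- function(cfg, depth, effect_mask, sub_seed) {
  set.seed(sub_seed)
  d <- cfg$grid_shape
  V <- prod(d)
  N <- cfg$n_volumes
  band <- c(cfg$band_lo_hz, cfg$band_hi_hz)
  x <- .band_noise(N, cfg$tr_s, band, n_series = V)   # N x V
  if (depth > 0) {
    phi <- runif(1, 0, 2 * pi)
    tt <- (seq_len(N) - 1) * cfg$tr_s
    env <- 1 + depth * sin(2 * pi * cfg$mod_freq_hz * tt + phi)
    idx <- which(as.vector(effect_mask))
    x[, idx] <- x[, idx] * env
  }
  if (cfg$noise_sd > 0) {
    noise <- array(rnorm(V * N, sd = cfg$noise_sd), dim = c(d, N))
    if (cfg$smooth_fwhm_mm > 0)
      noise <- .smooth_spatial(noise, cfg$smooth_fwhm_mm, cfg$voxel_size_mm)
    x <- x + .time_matrix(noise)
  }
  # internally generated data are finite by construction; skip validation
  structure(list(data = .from_time_matrix(x, d), tr_s = cfg$tr_s,
                 affine = diag(c(rep(cfg$voxel_size_mm, 3), 1)),
                 mask = array(TRUE, d)),
            class = "bold_run")
}

#' Simulate a two-group BOLD cohort with a planted dynamic-ALFF effect
#'
#' Generates `2 * n_per_group` 4D runs plus a covariates table.  Every voxel
#' carries an independent band-limited Gaussian signal; inside the spherical
#' effect region, patient voxels are amplitude-modulated by a slow sinusoid
#' whose per-subject depth is
#' `d_i = modulation_depth + duration_coupling * (duration_i - mean duration)`
#' (floored at 0), so regional windowed-ALFF variability tracks disease
#' duration.  Controls and out-of-region voxels are unmodulated, which means
#' group differences appear in dynamic-ALFF variability but not (to first
#' order) in mean ALFF.  Smoothed white noise supplies the spatial
#' correlation structure random-field inference expects.
#'
#' All randomness flows from `config$seed`: covariates are drawn first, then
#' each subject's run from its own derived sub-stream, so the cohort is
#' byte-identical across calls.
#'
#' @param config A [sim_config()].
#' @return An object of class `dalff_cohort`: list with `runs` (list of
#'   [bold_run()]), `covariates` (data frame, one row per subject),
#'   `effect_mask` (3D logical) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_group = 2,
#'                                      grid_shape = c(6, 6, 6),
#'                                      effect_center_vox = c(3, 3, 3),
#'                                      effect_radius_vox = 1, seed = 7))
#' cohort
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_group
  set.seed(config$seed)
  cov <- .draw_covariates(n)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  effect_mask <- build_effect_mask(config$grid_shape,
                                   config$effect_center_vox,
                                   config$effect_radius_vox)
  dur <- cov$duration_years[seq_len(n)]
  depth <- pmax(0, config$modulation_depth +
                  config$duration_coupling * (dur - mean(dur)))
  runs <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    di <- if (i <= n) depth[i] else 0
    runs[[i]] <- .simulate_run(config, di, effect_mask, sub_seeds[i])
  }
  names(runs) <- cov$subject_id
  structure(list(runs = runs, covariates = cov, effect_mask = effect_mask,
                 config = config),
            class = "dalff_cohort")
}

#' @export
print.dalff_cohort <- function(x, ...) {
  cat(sprintf("<dalff_cohort> %d subjects (%d patients, %d controls)\n",
              nrow(x$covariates), sum(x$covariates$group == "patient"),
              sum(x$covariates$group == "control")))
  cat(sprintf("  grid %s, %d volumes, effect region %d voxels, seed %d\n",
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_volumes, sum(x$effect_mask), x$config$seed))
  invisible(x)
}

#' Write / read a simulated cohort on disk
#'
#' `write_cohort()` writes one gzipped NIfTI per subject
#' (`<subject_id>_bold.nii.gz`), the brain mask (`mask.nii.gz`) and a
#' `covariates.csv` with the standard header
#' `subject_id,group,age,sex,duration_years,updrs_iii,hy_stage,moca,mmse,mean_fd`.
#' `read_cohort()` reconstructs a `dalff_cohort` from such a directory.
#'
#' @param cohort A `dalff_cohort`.
#' @param dir Directory (created if missing).
#' @param tr_s Optional TR override when reading.
#' @return The directory (write) or a `dalff_cohort` (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$runs))
    write_bold_run(cohort$runs[[id]], file.path(dir, paste0(id, "_bold.nii.gz")))
  run1 <- cohort$runs[[1]]
  write_map(array(as.numeric(run1$mask), dim(run1$mask)), run1$affine,
            file.path(dir, "mask.nii.gz"))
  write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, tr_s = NULL) {
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  mask_path <- file.path(dir, "mask.nii.gz")
  if (!file.exists(mask_path)) mask_path <- NULL
  runs <- lapply(cov$subject_id, function(id)
    read_bold_run(file.path(dir, paste0(id, "_bold.nii.gz")),
                  mask_path = mask_path, tr_s = tr_s))
  names(runs) <- cov$subject_id
  structure(list(runs = runs, covariates = cov, effect_mask = NULL,
                 config = NULL),
            class = "dalff_cohort")
}
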