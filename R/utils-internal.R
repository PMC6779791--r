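# Internal helpers shared across modules.

.nyquist <- function(tr_s) 1 / (2 * tr_s)

.check_band <- function(band, tr_s) {
  if (length(band) != 2L || !is.numeric(band) || any(!is.finite(band)))
    stop("band must be two finite numbers (lo, hi) in Hz", call. = FALSE)
  lo <- band[1]; hi <- band[2]
  if (!(lo > 0 && lo < hi && hi < .nyquist(tr_s)))
    stop(sprintf(
      "invalid band [%g, %g] Hz: need 0 < lo < hi < Nyquist = %g Hz",
      lo, hi, .nyquist(tr_s)), call. = FALSE)
  invisible(band)
}

# DFT bin indices k (frequencies k/(n*tr_s)) lying inside [lo, hi],
# restricted to the single-sided range 1..floor(n/2).  A small tolerance
# keeps bins that sit exactly on a band edge.
.inband_bins <- function(n, tr_s, band, tol = 1e-12) {
  k <- seq_len(n %/% 2L)
  f <- k / (n * tr_s)
  k[f >= band[1] - tol & f <= band[2] + tol & f < .nyquist(tr_s) - tol]
}

# FWHM (mm) -> Gaussian sigma in voxel units, per axis.
.fwhm_to_sigma_vox <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

.gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Smooth the three spatial axes of a 3D or 4D array (isotropic FWHM in mm).
.smooth_spatial <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(arr)
  k <- .gauss_kernel_1d(.fwhm_to_sigma_vox(fwhm_mm, voxel_size_mm))
  d <- dim(arr)
  out <- .separable_smooth(as.double(arr), as.integer(d), as.double(k))
  dim(out) <- d
  out
}

# 4D (x,y,z,t) array <-> T x V time-by-voxel matrix.
.time_matrix <- function(data4d) {
  d <- dim(data4d)
  t(matrix(data4d, nrow = prod(d[1:3]), ncol = d[4]))
}

.from_time_matrix <- function(m, spatial_dim) {
  array(t(m), dim = c(spatial_dim, nrow(m)))
}

.voxel_size_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Map 0-based voxel indices (i, j, k) to world mm through the affine.
.voxel_to_world <- function(affine, ijk) {
  drop(affine %*% c(ijk - 1, 1))[1:3]
}
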