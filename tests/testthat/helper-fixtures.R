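# Shared fixtures: everything is generated in code at test time.

# A small, fast cohort configuration for unit tests (not the full study
# conditions used in the acceptance suite).
tiny_config <- function(seed = 1, depth = 0.6, n_per_group = 4L, ...) {
  sim_config(n_per_group = n_per_group, grid_shape = c(8L, 8L, 8L),
             n_volumes = 85L, effect_center_vox = c(4L, 4L, 4L),
             effect_radius_vox = 1.8, modulation_depth = depth,
             seed = seed, ...)
}

tiny_window <- function() window_spec(30L, 1L)

# Direct DFT: independent oracle for spectra and ALFF (no fft()).
direct_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    w <- -2i * pi * k * (0:(n - 1)) / n
    sum(x * exp(w))
  }, complex(1))
}

oracle_alff <- function(x, tr_s, band) {
  n <- length(x)
  X <- direct_dft(x - mean(x))
  k <- seq_len(n %/% 2)
  f <- k / (n * tr_s)
  keep <- f >= band[1] - 1e-12 & f <= band[2] + 1e-12 & f < 1 / (2 * tr_s) - 1e-12
  mean(2 * Mod(X[k[keep] + 1]) / n)
}

# Pooled-variance two-sample t (patient minus control), textbook form.
oracle_two_sample_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}
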