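test_that("initial-volume discard keeps the right volumes in order", {
  run <- bold_run(array(seq_len(2 * 2 * 2 * 185), c(2, 2, 2, 185)), tr_s = 2)
  out <- discard_initial_volumes(run, 10)
  expect_equal(n_volumes(out), 175)
  expect_identical(discard_initial_volumes(run, 0), run)
  small <- bold_run(array(seq_len(1 * 1 * 1 * 12), c(1, 1, 1, 12)), tr_s = 2)
  kept <- discard_initial_volumes(small, 5)
  expect_equal(as.vector(kept$data), 6:12)
  expect_error(discard_initial_volumes(small, 12), "k must")
})

test_that("framewise displacement follows the Power convention", {
  Tn <- 176
  still <- motion_trace(matrix(0, Tn, 3), matrix(0, Tn, 3))
  expect_equal(framewise_displacement(still)$mean_fd, 0)
  # one +1 mm step in x between two otherwise still volumes
  tr1 <- matrix(0, Tn, 3); tr1[100:Tn, 1] <- 1
  fd <- framewise_displacement(motion_trace(tr1, matrix(0, Tn, 3)))
  expect_equal(fd$fd[100], 1)
  expect_equal(sum(fd$fd), 1)
  expect_equal(fd$mean_fd, 1 / Tn)
  # a 0.02 rad rotation step at 50 mm radius contributes 1.0 mm
  ro <- matrix(0, 3, 3); ro[2:3, 1] <- 0.02
  fd2 <- framewise_displacement(motion_trace(matrix(0, 3, 3), ro),
                                radius_mm = 50)
  expect_equal(fd2$fd, c(0, 1, 0))
  expect_error(framewise_displacement(
    motion_trace(matrix(0, 1, 3), matrix(0, 1, 3))), "at least 2")
})

test_that("motion exclusion applies the 2 mm / 2 deg / 0.3 rules", {
  Tn <- 20
  zeros <- matrix(0, Tn, 3)
  expect_true(motion_exclusion_check(motion_trace(zeros, zeros))$pass)
  tr1 <- zeros; tr1[5, 1] <- 2.5
  chk <- motion_exclusion_check(motion_trace(tr1, zeros))
  expect_false(chk$pass)
  expect_match(chk$reasons, "translation")
  ro <- zeros; ro[7, 2] <- 2.5 * pi / 180
  chk2 <- motion_exclusion_check(motion_trace(zeros, ro))
  expect_false(chk2$pass)
  expect_match(chk2$reasons, "rotation")
  chk3 <- motion_exclusion_check(motion_trace(zeros, zeros), mean_fd = 0.31)
  expect_false(chk3$pass)
  expect_match(chk3$reasons, "FD")
  expect_true(motion_exclusion_check(motion_trace(zeros, zeros),
                                     mean_fd = 0.29)$pass)
})

test_that("motion traces round-trip through 6-column text", {
  Tn <- 15
  tr <- matrix(rnorm(Tn * 3, sd = 0.2), Tn, 3)
  ro <- matrix(rnorm(Tn * 3, sd = 0.005), Tn, 3)
  f <- tempfile(fileext = ".txt")
  write.table(cbind(tr, ro), f, row.names = FALSE, col.names = FALSE)
  got <- read_motion_trace(f)
  expect_equal(unname(got$translations), tr, tolerance = 1e-12)
  expect_equal(unname(got$rotations), ro, tolerance = 1e-12)
  unlink(f)
})

test_that("friston24 expansion has the documented structure", {
  Tn <- 10
  tr <- matrix(rnorm(Tn * 3), Tn, 3); ro <- matrix(rnorm(Tn * 3), Tn, 3)
  f24 <- friston24(motion_trace(tr, ro))
  expect_equal(dim(f24), c(Tn, 24))
  expect_equal(f24[, 1], tr[, 1])
  expect_equal(unname(f24[5, "tx_lag"]), tr[4, 1])
  expect_equal(unname(f24[1, "tx_lag"]), 0)
  expect_equal(f24[, "rz_sq"], ro[, 3]^2)
})

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  set.seed(5)
  run <- bold_run(array(rnorm(3 * 3 * 3 * 40), c(3, 3, 3, 40)), tr_s = 2)
  nuis <- cbind(wm = rnorm(40), csf = rnorm(40))
  out <- regress_nuisance(run, nuis)
  m <- t(matrix(out$data, 27, 40))
  X <- cbind(1, seq_len(40), nuis)
  expect_lt(max(abs(crossprod(X, m))) / 40, 1e-10)
  # regressing a voxel on its own series zeroes it
  self <- run$data[1, 1, 1, ]
  out2 <- regress_nuisance(run, cbind(self = self))
  expect_lt(max(abs(out2$data[1, 1, 1, ])), 1e-10)
  # intercept only = demeaning
  out3 <- regress_nuisance(run, detrend = FALSE)
  expect_equal(out3$data[2, 2, 2, ],
               run$data[2, 2, 2, ] - mean(run$data[2, 2, 2, ]),
               tolerance = 1e-12)
  # collinear columns are dropped with a warning
  expect_warning(regress_nuisance(run, cbind(a = nuis[, 1], b = nuis[, 1])),
                 "collinear")
})

test_that("ideal band-pass keeps the pass band and kills the stop band", {
  tt <- (0:199) * 2
  mk <- function(f) bold_run(array(rep(sin(2 * pi * f * tt), each = 1),
                                   c(1, 1, 1, 200)), tr_s = 2)
  stop_out <- bandpass_filter(mk(0.2), 0.01, 0.08)
  expect_lt(sqrt(mean(stop_out$data^2)), 0.01 * sqrt(mean(mk(0.2)$data^2)))
  pass_out <- bandpass_filter(mk(0.04), 0.01, 0.08)   # 0.04 = exact bin 16
  expect_equal(as.vector(pass_out$data), as.vector(mk(0.04)$data),
               tolerance = 0.01)
  # white noise: > 99% of output power in band, by direct DFT
  set.seed(8)
  wn <- bold_run(array(rnorm(200), c(1, 1, 1, 200)), tr_s = 2)
  out <- bandpass_filter(wn, 0.01, 0.08)
  P <- Mod(direct_dft(as.vector(out$data)))^2
  f <- (0:199) / (200 * 2); f <- pmin(f, 0.5 - f)
  inband <- f >= 0.01 - 1e-9 & f <= 0.08 + 1e-9
  expect_gt(sum(P[inband]) / sum(P), 0.99)
  expect_equal(mean(out$data), 0, tolerance = 1e-12)
  # idempotence of the ideal mask
  twice <- bandpass_filter(out, 0.01, 0.08)
  expect_equal(twice$data, out$data, tolerance = 1e-10)
  expect_error(bandpass_filter(wn, 0.1, 0.05), "band")
})

test_that("spatial smoothing matches an explicit-kernel oracle", {
  a <- array(0, c(9, 9, 9, 1)); a[5, 5, 5, 1] <- 1
  run <- bold_run(a, tr_s = 2, voxel_size_mm = 3)
  expect_identical(spatial_smooth(run, 0)$data, run$data)
  sm <- spatial_smooth(run, 6)
  sigma <- (6 / 3) / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  # separable kernel: value at offset (dx,dy,dz) is k[dx]k[dy]k[dz]
  expect_equal(sm$data[5, 5, 5, 1], k[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm$data[6, 5, 4, 1], k[r + 2] * k[r + 1] * k[r], tolerance = 1e-12)
  # interior delta: total mass conserved
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  expect_error(spatial_smooth(run, -1), "fwhm")
})
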