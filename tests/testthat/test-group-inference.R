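test_that("group contrast with no covariates equals the pooled two-sample t", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    y <- c(rnorm(n1, 1), rnorm(n0))
    grp <- rep(c("patient", "control"), c(n1, n0))
    X <- build_design(data.frame(group = grp), covars = character(0))
    fit <- fit_voxelwise_glm(matrix(y, nrow = 1), X)
    expect_equal(fit$t_map[1],
                 oracle_two_sample_t(y[seq_len(n1)], y[n1 + seq_len(n0)]),
                 tolerance = 1e-10)
  }
})

test_that("a covariate orthogonal to group leaves the group t unchanged", {
  set.seed(12)
  n <- 20
  grp <- rep(c("patient", "control"), each = n / 2)
  y <- rnorm(n)
  z <- rnorm(n)
  g <- as.numeric(grp == "patient")
  # orthogonalise z against intercept, group and the outcome: it then
  # explains nothing, so the group beta and (df-adjusted) t are untouched
  z <- qr.resid(qr(cbind(1, g, y)), z)
  X0 <- build_design(data.frame(group = grp), covars = character(0))
  X1 <- cbind(X0, z = z)
  f0 <- fit_voxelwise_glm(matrix(y, 1), X0)
  f1 <- fit_voxelwise_glm(matrix(y, 1), X1)
  expect_equal(f1$beta["group", 1], f0$beta["group", 1], tolerance = 1e-10)
  expect_equal(f1$t_map[1], f0$t_map[1] * sqrt(f1$df / f0$df),
               tolerance = 1e-8)
  # rank deficiency is reported with the offending column
  Xbad <- cbind(X0, dup = X0[, "group"])
  expect_error(fit_voxelwise_glm(matrix(y, 1), Xbad), "rank deficient")
})

test_that("voxelwise p < 0.001 rate is calibrated under a label-free null", {
  set.seed(13)
  n <- 40; V <- 6000
  Y <- matrix(rnorm(n * V), V, n)
  grp <- rep(c("patient", "control"), each = n / 2)
  X <- build_design(data.frame(group = grp), covars = character(0))
  fit <- fit_voxelwise_glm(Y, X)
  p <- 2 * pt(-abs(fit$t_map), fit$df)
  rate <- mean(p < 0.001)
  # binomial 99.9% band around 0.001 with V*1 independent voxels
  expect_lt(abs(rate - 0.001), 3.3 * sqrt(0.001 * 0.999 / V) + 1e-12)
})

test_that("smoothness estimates recover known FWHM within 20%", {
  set.seed(14)
  d <- c(16, 16, 16)
  mask <- array(TRUE, d)
  n <- 12
  white <- matrix(rnorm(n * prod(d)), n)
  fw <- estimate_fwhm(white, mask, 3)
  expect_true(all(abs(fw - 3) / 3 < 0.2))    # ~ voxel size
  smoothed <- t(vapply(seq_len(n), function(i) {
    as.vector(dynalff:::.smooth_spatial(array(rnorm(prod(d)), d), 6, 3))
  }, numeric(prod(d))))
  fw6 <- estimate_fwhm(smoothed, mask, 3)
  expect_true(all(abs(fw6 - 6) / 6 < 0.2))
  # units: doubling the voxel size doubles the reported FWHM
  expect_equal(estimate_fwhm(white, mask, 6), 2 * fw, tolerance = 1e-12)
  expect_error(estimate_fwhm(white[1:2, ], mask, 3), "at least 3")
})

test_that("connected-component labeling respects connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # diagonal neighbours
  lab26 <- label_clusters(m, 26)
  expect_equal(max(lab26), 1)
  lab6 <- label_clusters(m, 6)
  expect_equal(max(lab6), 2)
  m[4, 4, 4] <- TRUE
  expect_equal(max(label_clusters(m, 26)), 2)
  expect_equal(sort(tabulate(label_clusters(m, 26))), c(1, 2))
})

test_that("GRF cluster correction recovers a planted blob and orders p by extent", {
  # empty map -> empty table
  d <- c(12, 12, 12)
  mask <- array(TRUE, d)
  empty <- grf_cluster_correction(array(0, d), 50, mask, 6, 3)
  expect_s3_class(empty, "cluster_table")
  expect_equal(nrow(empty), 0)
  # strong planted blob in an otherwise quiet map
  tm <- array(rnorm(prod(d), sd = 0.5), d)
  blob <- build_effect_mask(d, c(6, 6, 6), 2)
  tm[blob] <- 8
  ct <- grf_cluster_correction(tm, 50, mask, 6, 3)
  expect_equal(nrow(ct), 1)
  cl_mask <- attr(ct, "label_map") == 1
  expect_gt(dice_overlap(cl_mask, blob), 0.9)
  expect_equal(ct$peak_t[1], 8)
  # monotonicity: corrected p decreases with extent at fixed smoothness
  p_of_size <- vapply(c(5, 10, 20, 40), function(k) {
    tmk <- array(0, d)
    tmk[seq_len(k)] <- 8
    g <- grf_cluster_correction(tmk, 50, mask, 6, 3, cluster_p = 0.9999)
    g$p_cluster[1]
  }, numeric(1))
  expect_true(all(diff(p_of_size) < 0))
  # world-space peak coordinates through the affine
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-15, -15, -15)
  ct2 <- grf_cluster_correction(tm, 50, mask, 6, 3, affine = aff)
  pk <- which(tm == 8 & blob, arr.ind = TRUE)[1, ]  # any blob voxel has t=8
  expect_true(all(ct2[1, c("x", "y", "z")] >= -15))
})

test_that("permutation cluster correction agrees with GRF on a strong effect", {
  set.seed(15)
  d <- c(10, 10, 10)
  mask <- array(TRUE, d)
  n <- 24
  grp <- rep(c("patient", "control"), each = n / 2)
  Y <- matrix(rnorm(prod(d) * n), prod(d), n)
  blob <- build_effect_mask(d, c(5, 5, 5), 2)
  Y[as.vector(blob), grp == "patient"] <-
    Y[as.vector(blob), grp == "patient"] + 3
  X <- build_design(data.frame(group = grp), covars = character(0))
  ct <- permutation_cluster_correction(Y, X, mask, n_perm = 99, seed = 2)
  expect_gte(nrow(ct), 1)
  expect_gt(dice_overlap(attr(ct, "label_map") == 1, blob), 0.5)
  expect_true(all(ct$p_cluster > 0))
})

test_that("partial correlation matches the two-stage regression oracle", {
  set.seed(16)
  x <- rnorm(10)
  expect_equal(partial_correlation(x, x)$r, 1)
  # 10-point data set vs brute-force residual correlation
  y <- rnorm(10); z1 <- rnorm(10); z2 <- rnorm(10)
  got <- partial_correlation(x, y, cbind(z1, z2))
  rx <- resid(lm(x ~ z1 + z2)); ry <- resid(lm(y ~ z1 + z2))
  expect_equal(got$r, cor(rx, ry), tolerance = 1e-12)
  # p from the t transform with k = 2 covariates
  tt <- got$r * sqrt((10 - 2 - 2) / (1 - got$r^2))
  expect_equal(got$p, 2 * pt(-abs(tt), 6), tolerance = 1e-12)
  # no covariates -> plain Pearson r
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # degenerate: both exact functions of a covariate
  z <- rnorm(10)
  expect_error(partial_correlation(2 * z, -3 * z, cbind(z)), "undefined")
})

test_that("chi-square 2x2 matches printed and closed-form values", {
  res <- chi_square_2x2(rbind(c(15, 13), c(14, 14)))
  expect_equal(round(res$p, 3), 0.789)
  res0 <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  res40 <- chi_square_2x2(rbind(c(20, 0), c(0, 20)))
  # closed form N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  expect_equal(res40$chi2, 40 * (20 * 20)^2 / (20 * 20 * 20 * 20))
  expect_equal(res40$p, pchisq(40, 1, lower.tail = FALSE))
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("group_scalar_test reduces to the two-sample t without covariates", {
  set.seed(17)
  for (i in 1:20) {
    y <- rnorm(14)
    grp <- rep(c(1, 0), each = 7)
    got <- group_scalar_test(y, grp)
    tt <- t.test(y[1:7], y[8:14], var.equal = TRUE)
    expect_equal(got$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$p, tt$p.value, tolerance = 1e-10)
  }
  # identical groups: |t| ~ 0
  same <- rep(c(1, 2, 3), 4)
  got0 <- group_scalar_test(same, rep(c(1, 0), each = 6))
  expect_lt(abs(got0$statistic), 1e-10)
})
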