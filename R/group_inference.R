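#' Group-comparison design matrix
#'
#' Builds the subjects-by-predictors matrix for voxelwise group inference:
#' intercept, a 0/1 group indicator (`patient = 1`) and mean-centred
#' covariates (by default age, sex and mean framewise displacement, the
#' standard head-motion confound).  Sex is coded 0/1 (`M = 0`, `F = 1`);
#' centring keeps the intercept interpretable and leaves the group contrast
#' unchanged.
#'
#' @param covariates Data frame with at least `group` plus the requested
#'   covariate columns (as produced by [simulate_cohort()] or
#'   [read_covariates()]).
#' @param covars Character vector of covariate column names to adjust for.
#' @return Numeric matrix with named columns; full column rank is enforced.
#' @export
build_design <- function(covariates,
                         covars = c("age", "sex", "mean_fd")) {
  grp <- as.character(covariates$group)
  if (!all(grp %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'", call. = FALSE)
  X <- cbind(intercept = 1, group = as.numeric(grp == "patient"))
  for (cv in covars) {
    if (!cv %in% names(covariates))
      stop(sprintf("covariate column '%s' not found", cv), call. = FALSE)
    v <- covariates[[cv]]
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      if (all(v %in% c("M", "F"))) v <- as.numeric(v == "F")
      else v <- as.numeric(factor(v)) - 1
    }
    v <- as.numeric(v)
    if (any(is.na(v)))
      stop(sprintf("covariate '%s' contains missing values", cv),
           call. = FALSE)
    X <- cbind(X, v - mean(v))
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  X
}

# Accept a list of 3D arrays or a V x n matrix; return V x n matrix.
.maps_to_matrix <- function(maps) {
  if (is.list(maps)) {
    maps <- vapply(maps, function(m) {
      if (inherits(m, "dalff_maps")) m <- m$cv_map
      if (inherits(m, "alff_map")) m <- m$values
      as.vector(m)
    }, numeric(length(as.vector(
      if (inherits(maps[[1]], "dalff_maps")) maps[[1]]$cv_map
      else if (inherits(maps[[1]], "alff_map")) maps[[1]]$values
      else maps[[1]]))))
  }
  as.matrix(maps)
}

#' Voxelwise general linear model
#'
#' Fits ordinary least squares at every in-mask voxel and computes the
#' t statistic for one contrast (by default the group column):
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with
#' `df = n - ncol(design)`.  Residual images are retained for spatial
#' smoothness estimation.
#'
#' @param maps Per-subject 3D arrays (list, possibly of [compute_dynamic_alff()]
#'   results, in which case the CV map is used) or a voxels-by-subjects
#'   matrix.
#' @param design Design matrix from [build_design()] (subjects in the same
#'   order as `maps`).
#' @param contrast Numeric contrast vector of length `ncol(design)`, or the
#'   name of a design column (default `"group"`).
#' @param mask 3D logical array; required when `maps` is a bare matrix and
#'   a spatial `t_map` is wanted.
#' @return An object of class `voxel_glm`: list with `t_map` (3D array or
#'   vector), `beta`, `df`, `residuals` (subjects x voxels), `design`,
#'   `contrast`, `mask`.
#' @export
fit_voxelwise_glm <- function(maps, design, contrast = "group",
                              mask = NULL) {
  Y <- .maps_to_matrix(maps)                       # V x n
  if (is.list(maps) && is.null(mask)) {
    m1 <- maps[[1]]
    if (inherits(m1, "dalff_maps")) mask <- m1$mask
    else if (inherits(m1, "alff_map")) mask <- m1$mask
  }
  sdim <- if (is.list(maps)) {
    m1 <- maps[[1]]
    dim(if (inherits(m1, "dalff_maps")) m1$cv_map
        else if (inherits(m1, "alff_map")) m1$values else m1)
  } else if (!is.null(mask)) dim(mask) else NULL
  n <- ncol(Y)
  if (nrow(design) != n)
    stop("design rows must equal the number of subjects", call. = FALSE)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop(sprintf("design is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.character(contrast)) {
    cvec <- as.numeric(colnames(design) == contrast)
    if (sum(cvec) != 1L)
      stop(sprintf("contrast column '%s' not found", contrast), call. = FALSE)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != ncol(design))
      stop("contrast length must equal ncol(design)", call. = FALSE)
  }
  Yt <- t(Y)                                       # n x V
  beta <- qr.coef(qx, Yt)                          # p x V
  res <- Yt - design %*% beta                      # n x V
  df <- n - ncol(design)
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)
  sig2 <- colSums(res^2) / df
  XtXi <- chol2inv(qr.R(qx))
  cvar <- drop(t(cvec) %*% XtXi %*% cvec)
  tval <- drop(cvec %*% beta) / sqrt(sig2 * cvar)
  tval[!is.finite(tval)] <- 0
  t_map <- if (!is.null(sdim)) {
    tm <- array(tval, sdim)
    if (!is.null(mask)) tm[!mask] <- 0
    tm
  } else tval
  structure(list(t_map = t_map, beta = beta, df = df, residuals = res,
                 design = design, contrast = cvec, mask = mask),
            class = "voxel_glm")
}

#' @export
print.voxel_glm <- function(x, ...) {
  tv <- if (!is.null(x$mask)) x$t_map[x$mask] else x$t_map
  cat(sprintf("<voxel_glm> %d subjects, %d predictors, df = %d\n",
              nrow(x$design), ncol(x$design), x$df))
  cat(sprintf("  contrast t: min %.3g, max %.3g\n", min(tv), max(tv)))
  invisible(x)
}

#' Spatial smoothness (FWHM) of residual images
#'
#' Random-field-theory smoothness estimator: residual images are
#' standardised voxelwise across subjects, and for each axis the variance of
#' the normalized residuals' spatial first differences (pooled over subjects
#' and in-mask neighbour pairs) gives
#' `FWHM_axis = voxel_size * sqrt(4 log 2 / lambda_axis)`.  For unsmoothed
#' white noise the estimate is close to one voxel.  Estimates are floored at
#' the voxel size.
#'
#' @param residuals Subjects-by-voxels residual matrix (as stored by
#'   [fit_voxelwise_glm()]) or a list of 3D residual arrays; at least 3
#'   maps.
#' @param mask 3D logical array defining the estimation domain (and the
#'   spatial shape of the residual vectors).
#' @param voxel_size_mm Scalar or length-3 voxel size in mm.
#' @return Length-3 numeric vector of per-axis FWHM estimates (mm).
#' @export
estimate_fwhm <- function(residuals, mask, voxel_size_mm) {
  if (is.list(residuals))
    residuals <- t(vapply(residuals, as.vector,
                          numeric(length(residuals[[1]]))))
  n <- nrow(residuals)
  if (n < 3L) stop("need at least 3 residual maps", call. = FALSE)
  mask <- array(as.logical(mask), dim(mask))
  sdim <- dim(mask)
  vs <- rep(voxel_size_mm, length.out = 3)
  den <- sqrt(colSums(residuals^2))
  den[den == 0] <- Inf
  U <- sweep(residuals, 2, den, "/")               # n x V, unit norm/voxel
  lambda <- numeric(3)
  for (ax in 1:3) {
    idx <- array(seq_len(prod(sdim)), sdim)
    take <- function(a, off) {
      if (ax == 1) a[seq_len(sdim[1] - 1) + off, , , drop = FALSE]
      else if (ax == 2) a[, seq_len(sdim[2] - 1) + off, , drop = FALSE]
      else a[, , seq_len(sdim[3] - 1) + off, drop = FALSE]
    }
    i1 <- as.vector(take(idx, 0L)); i2 <- as.vector(take(idx, 1L))
    ok <- as.vector(take(mask, 0L)) & as.vector(take(mask, 1L))
    if (!any(ok)) { lambda[ax] <- NA; next }
    d2 <- (U[, i2[ok], drop = FALSE] - U[, i1[ok], drop = FALSE])^2
    lambda[ax] <- sum(d2) / sum(ok)
  }
  fwhm <- vs * sqrt(4 * log(2) / lambda)
  pmax(fwhm, vs)
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first 3D labeling under 6-, 18- or 26-neighbour connectivity.
#'
#' @param x 3D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of the same shape: 0 for background, 1..K for the
#'   K components.
#' @export
label_clusters <- function(x, connectivity = 26) {
  x <- array(as.logical(x), dim(x))
  d <- dim(x)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = nn == 1, "18" = nn >= 1 & nn <= 2, "26" = nn >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  offs <- offs[keep, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(x)
  if (length(idx_all) == 0L) return(lab)
  coord <- arrayInd(idx_all, d)
  pos <- array(0L, d); pos[idx_all] <- seq_along(idx_all)
  for (start in seq_along(idx_all)) {
    if (lab[idx_all[start]] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[idx_all[start]] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- coord[cur, ]
      for (o in seq_len(nrow(offs))) {
        nb <- cc + offs[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + d[1] * (nb[2] - 1L + d[2] * (nb[3] - 1L))
        if (x[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, pos[li])
        }
      }
    }
  }
  lab
}

# Euler-characteristic density (3D) of a t field at threshold u, df nu
# (Worsley's formula); used for the expected number of clusters per resel.
.ec3_t <- function(u, nu) {
  (4 * log(2))^1.5 / (2 * pi)^2 *
    ((nu - 1) / nu * u^2 - 1) * (1 + u^2 / nu)^(-(nu - 1) / 2)
}

#' Gaussian random-field cluster-level correction
#'
#' Thresholds the t map at the voxel-level quantile `u = t(1 - voxel_p, df)`
#' (both signs by default), labels suprathreshold clusters, and assigns each
#' a corrected cluster-level p-value from random-field theory: with resel
#' count `R = V / prod(FWHM / voxel size)` the expected number of clusters
#' is `E[m] = R * rho3(u)` (doubled for two-sided excursions), the expected
#' cluster extent is `E[n] = V * voxel_p / E[m]` one-sided, and the extent
#' tail is `P(n >= k) = exp(-beta k^(2/3))` with
#' `beta = (gamma(5/2) / E[n])^(2/3)`; finally
#' `p_cluster = 1 - exp(-E[m] * P(n >= k))`.  Clusters with
#' `p_cluster < cluster_p` are retained.
#'
#' @param t_map 3D t-statistic array.
#' @param df Residual degrees of freedom.
#' @param mask 3D logical analysis mask.
#' @param fwhm_mm Per-axis smoothness estimate (mm), e.g. from
#'   [estimate_fwhm()].
#' @param voxel_size_mm Scalar or length-3 voxel size (mm).
#' @param voxel_p Voxel-level threshold (default 0.001).
#' @param cluster_p Cluster-level threshold (default 0.05).
#' @param sided `"two"` (default), `"pos"` or `"neg"`.  Two-sided analysis
#'   doubles the expected cluster count so the family-wise rate covers both
#'   signs.
#' @param connectivity Cluster connectivity (default 26).
#' @param affine Optional 4x4 affine; when given, peak coordinates are
#'   reported in world mm, otherwise in voxel indices.
#' @return An object of class `cluster_table`: data frame with columns
#'   `size`, `peak_t`, `x`, `y`, `z`, `p_cluster`, sorted by size
#'   descending; attributes record the threshold, resel count and the
#'   labelled cluster image (`attr(, "label_map")`).  Empty when nothing
#'   survives.
#' @export
grf_cluster_correction <- function(t_map, df, mask, fwhm_mm, voxel_size_mm,
                                   voxel_p = 0.001, cluster_p = 0.05,
                                   sided = c("two", "pos", "neg"),
                                   connectivity = 26, affine = NULL) {
  sided <- match.arg(sided)
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  mask <- array(as.logical(mask), dim(mask))
  u <- qt(1 - voxel_p, df)
  vs <- rep(voxel_size_mm, length.out = 3)
  fwhm_vox <- pmax(rep(fwhm_mm, length.out = 3) / vs, 1)
  Vn <- sum(mask)
  resels <- Vn / prod(fwhm_vox)
  em1 <- max(resels * .ec3_t(u, df), 1e-12)
  two <- sided == "two"
  em <- if (two) 2 * em1 else em1
  en <- (Vn * voxel_p) / em1               # expected voxels per cluster
  beta <- (gamma(5 / 2) / en)^(2 / 3)

  excurs <- switch(sided,
                   two = abs(t_map) >= u,
                   pos = t_map >= u,
                   neg = t_map <= -u)
  excurs <- excurs & mask
  lab <- label_clusters(excurs, connectivity)
  empty <- structure(
    data.frame(size = integer(0), peak_t = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0), p_cluster = numeric(0)),
    class = c("cluster_table", "data.frame"),
    threshold = u, resels = resels, expected_clusters = em,
    fwhm_mm = rep(fwhm_mm, length.out = 3),
    label_map = array(0L, dim(mask)))
  k <- max(lab)
  if (k == 0L) return(empty)
  rows <- lapply(seq_len(k), function(ci) {
    vox <- which(lab == ci)
    size <- length(vox)
    pk <- vox[which.max(abs(t_map[vox]))]
    ijk <- drop(arrayInd(pk, dim(mask)))
    xyz <- if (!is.null(affine)) .voxel_to_world(affine, ijk) else ijk
    p <- 1 - exp(-em * exp(-beta * size^(2 / 3)))
    data.frame(size = size, peak_t = t_map[pk], x = xyz[1], y = xyz[2],
               z = xyz[3], p_cluster = p)
  })
  tab <- do.call(rbind, rows)
  keep <- which(tab$p_cluster < cluster_p)
  relabel <- array(0L, dim(mask))
  ord <- keep[order(tab$size[keep], decreasing = TRUE)]
  for (i in seq_along(ord)) relabel[lab == ord[i]] <- i
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("cluster_table", "data.frame"),
            threshold = u, resels = resels, expected_clusters = em,
            fwhm_mm = rep(fwhm_mm, length.out = 3), label_map = relabel)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d surviving cluster(s); |t| threshold %.3f, %.1f resels\n",
              nrow(x), attr(x, "threshold"), attr(x, "resels")))
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$peak_t <- round(df$peak_t, 2)
    df$p_cluster <- signif(df$p_cluster, 3)
    print(df)
  }
  invisible(x)
}

#' Permutation-based cluster-extent correction
#'
#' Nonparametric alternative to [grf_cluster_correction()]: the group
#' labels (the group column of the design) are permuted `n_perm` times, the
#' voxelwise GLM and voxel-level threshold are re-applied, and the maximal
#' cluster extent of each permutation forms the null distribution.  Each
#' observed cluster gets `p = (1 + #{max extent >= size}) / (1 + n_perm)`.
#'
#' @inheritParams fit_voxelwise_glm
#' @inheritParams grf_cluster_correction
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return A `cluster_table` (see [grf_cluster_correction()]).
#' @export
permutation_cluster_correction <- function(maps, design, mask,
                                           contrast = "group",
                                           voxel_p = 0.001, cluster_p = 0.05,
                                           sided = c("two", "pos", "neg"),
                                           connectivity = 26, n_perm = 199,
                                           seed = 1, affine = NULL) {
  sided <- match.arg(sided)
  Y <- .maps_to_matrix(maps)
  fit <- fit_voxelwise_glm(Y, design, contrast = contrast, mask = mask)
  u <- qt(1 - voxel_p, fit$df)
  thr <- function(tm) {
    ex <- switch(sided, two = abs(tm) >= u, pos = tm >= u, neg = tm <= -u)
    ex & mask
  }
  t_arr <- array(if (is.array(fit$t_map)) fit$t_map else fit$t_map,
                 dim(mask))
  lab <- label_clusters(thr(t_arr), connectivity)
  k <- max(lab)
  gi <- which(colnames(design) == "group")
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    Xp <- design
    Xp[, gi] <- sample(design[, gi])
    tp <- fit_voxelwise_glm(Y, Xp, contrast = contrast, mask = mask)$t_map
    lb <- label_clusters(thr(array(tp, dim(mask))), connectivity)
    if (max(lb) == 0L) 0L else max(tabulate(lb[lb > 0L]))
  }, integer(1))
  empty <- structure(
    data.frame(size = integer(0), peak_t = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0), p_cluster = numeric(0)),
    class = c("cluster_table", "data.frame"), threshold = u,
    resels = NA_real_, expected_clusters = NA_real_,
    fwhm_mm = NA_real_, label_map = array(0L, dim(mask)))
  if (k == 0L) return(empty)
  rows <- lapply(seq_len(k), function(ci) {
    vox <- which(lab == ci)
    pk <- vox[which.max(abs(t_arr[vox]))]
    ijk <- drop(arrayInd(pk, dim(mask)))
    xyz <- if (!is.null(affine)) .voxel_to_world(affine, ijk) else ijk
    data.frame(size = length(vox), peak_t = t_arr[pk], x = xyz[1],
               y = xyz[2], z = xyz[3],
               p_cluster = (1 + sum(null_max >= length(vox))) / (1 + n_perm))
  })
  tab <- do.call(rbind, rows)
  keep <- which(tab$p_cluster < cluster_p)
  relabel <- array(0L, dim(mask))
  ord <- keep[order(tab$size[keep], decreasing = TRUE)]
  for (i in seq_along(ord)) relabel[lab == ord[i]] <- i
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("cluster_table", "data.frame"), threshold = u,
            resels = NA_real_, expected_clusters = NA_real_,
            fwhm_mm = NA_real_, label_map = relabel)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on an intercept plus the covariates.  With no covariates this is
#' the ordinary Pearson correlation.  The two-sided p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `k` covariates.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame of covariates
#'   (sex-like character columns are coded 0/1).
#' @return List with `r`, `p`, `df` and `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (!is.null(covariates)) {
    Z <- as.data.frame(covariates)
    Z <- vapply(Z, function(v) {
      if (is.character(v) || is.factor(v)) {
        v <- as.character(v)
        if (all(v %in% c("M", "F"))) as.numeric(v == "F")
        else as.numeric(factor(v)) - 1
      } else as.numeric(v)
    }, numeric(n))
    Z <- as.matrix(Z)
    k <- ncol(Z)
  } else {
    Z <- NULL
    k <- 0L
  }
  if (n <= k + 2) stop("need n > n_covariates + 2", call. = FALSE)
  X <- cbind(rep(1, n), Z)
  qx <- qr(X)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  # residuals that are zero up to round-off leave the correlation undefined
  if (sqrt(sum(rx^2)) <= 1e-10 * max(1, sqrt(sum(x^2))) ||
      sqrt(sum(ry^2)) <= 1e-10 * max(1, sqrt(sum(y^2))))
    stop("zero residual variance: correlation undefined", call. = FALSE)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Without continuity correction, df = 1, two-sided.  Used for the
#' male/female group comparison of the demographics table.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `chi2` and `p`.
#' @examples
#' chi_square_2x2(rbind(c(15, 13), c(14, 14)))$p  # 0.789
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0))
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total", call. = FALSE)
  # asymptotic statistic is intended even at small counts
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Group test of a per-subject scalar
#'
#' The same GLM machinery as [fit_voxelwise_glm()] applied to one scalar
#' outcome per subject (age, a cognitive score, a cluster-mean CV, ...):
#' with no covariates it reduces exactly to the pooled-variance two-sample
#' t test.
#'
#' @param values Numeric vector, one value per subject.
#' @param group Factor/character with levels `control` / `patient`, or a
#'   0/1 vector (`1 = patient`).
#' @param covariates Optional data frame of covariates (see
#'   [build_design()]).
#' @return List with `statistic` (group t), `p` (two-sided) and `df`.
#' @export
group_scalar_test <- function(values, group, covariates = NULL) {
  if (is.numeric(group)) group <- ifelse(group == 1, "patient", "control")
  cdf <- data.frame(group = as.character(group))
  covars <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cdf <- cbind(cdf, covariates)
    covars <- names(covariates)
  }
  X <- build_design(cdf, covars = covars)
  fit <- fit_voxelwise_glm(matrix(values, nrow = 1), X, contrast = "group")
  tval <- fit$t_map[1]
  list(statistic = tval, p = 2 * pt(-abs(tval), fit$df), df = fit$df)
}

#' Dice overlap of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; a recovery score for comparing a surviving
#' cluster with the planted effect region.
#'
#' @param a,b Logical arrays of equal shape.
#' @return Scalar in `[0, 1]` (`NaN` when both masks are empty).
#' @export
dice_overlap <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
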