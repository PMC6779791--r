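#' Read / write a covariates table
#'
#' Comma-delimited text with header
#' `subject_id,group,age,sex,duration_years,updrs_iii,hy_stage,moca,mmse,mean_fd`.
#' `group` must be `patient` or `control`; `sex` must be `M` or `F`;
#' `duration_years` must be present for every patient and is ignored (with
#' a warning) for controls.
#'
#' @param path File path.
#' @return Data frame with typed columns, `group` as a factor with levels
#'   `control`, `patient`.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "mean_fd")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  if (!all(df$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'", call. = FALSE)
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  for (col in c("age", "mean_fd")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric %s at row(s): %s", col,
                   paste(which(is.na(v)), collapse = ", ")), call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$mean_fd < 0)) stop("mean_fd must be >= 0", call. = FALSE)
  if ("duration_years" %in% names(df)) {
    dur <- suppressWarnings(as.numeric(df$duration_years))
    ctrl_dur <- df$group == "control" & !is.na(dur)
    if (any(ctrl_dur)) {
      warning(sprintf("duration_years given for control(s) %s; ignored",
                      paste(df$subject_id[ctrl_dur], collapse = ", ")),
              call. = FALSE)
      dur[ctrl_dur] <- NA_real_
    }
    if (any(df$group == "patient" & is.na(dur)))
      stop("duration_years missing for one or more patients", call. = FALSE)
    df$duration_years <- dur
  }
  df$group <- factor(df$group, levels = c("control", "patient"))
  df
}

#' @rdname read_covariates
#' @param covariates Data frame to write.
#' @export
write_covariates <- function(covariates, path) {
  cols <- c("subject_id", "group", "age", "sex", "duration_years",
            "updrs_iii", "hy_stage", "moca", "mmse", "mean_fd")
  out <- covariates[, intersect(cols, names(covariates)), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Gathers every stage parameter with defaults matching the reference
#' protocol: discard 10 of 185 volumes, 0.01-0.08 Hz band, 50-TR window
#' with 1-TR step, 6 mm smoothing, GLM covariates age/sex/mean FD,
#' GRF correction at voxel p < 0.001 and cluster p < 0.05, leave-one-out
#' cross-validation and a 5,000-iteration label-permutation test.
#'
#' @param discard Leading volumes to drop.
#' @param band `(lo, hi)` pass band in Hz.
#' @param window A [window_spec()].
#' @param smooth_fwhm_mm Spatial smoothing FWHM (mm; 0 disables).
#' @param detrend Remove a linear trend during nuisance regression.
#' @param standardize Z-score each subject's map within the mask before the
#'   group GLM (the classification/correlation features always use the raw
#'   maps).
#' @param map Which variability map feeds group inference: `"cv"` (default)
#'   or `"sd"`.
#' @param covars GLM covariate columns.
#' @param voxel_p,cluster_p Voxel- and cluster-level thresholds.
#' @param correction `"grf"` or `"perm"`.
#' @param sided Sidedness of the voxel threshold (default two-sided).
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param cv_scheme `"loocv"` or `"kfold"`; `k` applies to the latter.
#' @param k Folds for k-fold CV.
#' @param C SVM cost.
#' @param n_perm Label permutations for classifier significance.
#' @param n_perm_cluster Permutations when `correction = "perm"`.
#' @param seed Seed for every stochastic stage (fold assignment, label
#'   shuffles, permutation correction).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(discard = 10L, band = c(0.01, 0.08),
                            window = window_spec(50L, 1L),
                            smooth_fwhm_mm = 6, detrend = TRUE,
                            standardize = TRUE, map = c("cv", "sd"),
                            covars = c("age", "sex", "mean_fd"),
                            voxel_p = 0.001, cluster_p = 0.05,
                            correction = c("grf", "perm"),
                            sided = c("two", "pos", "neg"),
                            connectivity = 26,
                            cv_scheme = c("loocv", "kfold"), k = 10L,
                            C = 1, n_perm = 5000L, n_perm_cluster = 199L,
                            seed = 1L) {
  cfg <- list(discard = as.integer(discard), band = band, window = window,
              smooth_fwhm_mm = smooth_fwhm_mm, detrend = detrend,
              standardize = standardize, map = match.arg(map),
              covars = covars, voxel_p = voxel_p, cluster_p = cluster_p,
              correction = match.arg(correction), sided = match.arg(sided),
              connectivity = connectivity,
              cv_scheme = match.arg(cv_scheme), k = as.integer(k), C = C,
              n_perm = as.integer(n_perm),
              n_perm_cluster = as.integer(n_perm_cluster),
              seed = as.integer(seed))
  stopifnot(inherits(window, "window_spec"))
  if (cfg$discard < 0) stop("discard must be >= 0", call. = FALSE)
  if (cfg$voxel_p <= 0 || cfg$voxel_p >= 1 ||
      cfg$cluster_p <= 0 || cfg$cluster_p >= 1)
    stop("voxel_p and cluster_p must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# Fused per-subject chain (discard -> smooth -> detrend -> band-pass ->
# windowed ALFF -> SD/CV), equivalent to composing the exported stage
# functions but without intermediate container copies; equality with the
# staged path is asserted in the test suite.
.subject_variability <- function(run, config) {
  arr <- run$data
  d4 <- dim(arr)
  vs <- .voxel_size_from_affine(run$affine)
  if (config$discard > 0)
    arr <- arr[, , , (config$discard + 1):d4[4], drop = FALSE]
  if (config$smooth_fwhm_mm > 0)
    arr <- .smooth_spatial(arr, config$smooth_fwhm_mm, vs[1])
  m <- .time_matrix(arr)                       # T x V
  Tn <- nrow(m)
  X <- if (config$detrend) cbind(1, seq_len(Tn) - (Tn + 1) / 2)
       else matrix(1, Tn, 1)
  m <- qr.resid(qr(X), m)
  f <- (seq_len(Tn) - 1) / (Tn * run$tr_s)
  f <- pmin(f, 1 / run$tr_s - f)
  keep <- f >= config$band[1] - 1e-12 & f <= config$band[2] + 1e-12
  Fm <- mvfft(m)
  Fm[!keep, ] <- 0
  m <- Re(mvfft(Fm, inverse = TRUE)) / Tn
  bins <- .inband_bins(config$window$length_tr, run$tr_s, config$band)
  A <- .stft_band_amplitude(m, config$window$length_tr,
                            config$window$step_tr, as.integer(bins))
  nwin <- ncol(A)
  mu <- rowMeans(A)
  sdv <- if (nwin > 1L)
    sqrt(pmax(rowSums(A * A) - nwin * mu^2, 0) / (nwin - 1))
  else rep(0, length(mu))
  v <- if (config$map == "cv") ifelse(mu < 1e-12, 0, sdv / mu) else sdv
  list(map = v, n_windows = nwin)
}

# Validate the config against a concrete run length / TR.
.validate_config <- function(cfg, n_vol, tr_s) {
  retained <- n_vol - cfg$discard
  if (retained < 1L)
    stop("discard leaves no volumes", call. = FALSE)
  if (cfg$window$length_tr > retained)
    stop(sprintf(
      "window length %d TR exceeds the %d volumes retained after discard",
      cfg$window$length_tr, retained), call. = FALSE)
  .check_band(cfg$band, tr_s)
  invisible(TRUE)
}

#' Per-subject variability maps for a whole cohort
#'
#' Runs the temporal chain on every subject -- discard, spatial smoothing,
#' detrending, ideal band-pass -- then [compute_dynamic_alff()], and returns
#' the raw and (optionally) standardised variability maps.
#'
#' @param cohort A `dalff_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return List with `raw` and `glm_input` (voxels-by-subjects matrices of
#'   the configured map), `mask`, `n_windows`, `affine`, `voxel_size_mm`.
#' @export
cohort_variability_maps <- function(cohort, config = pipeline_config()) {
  runs <- cohort$runs
  .validate_config(config, n_volumes(runs[[1]]), runs[[1]]$tr_s)
  mask <- runs[[1]]$mask
  n <- length(runs)
  raw <- NULL
  nwin <- NA_integer_
  for (i in seq_len(n)) {
    s <- .subject_variability(runs[[i]], config)
    nwin <- s$n_windows
    if (is.null(raw)) raw <- matrix(0, length(s$map), n)
    raw[, i] <- s$map
  }
  glm_input <- if (config$standardize) {
    apply(raw, 2, function(v)
      as.vector(standardize_map(array(v, dim(mask)), mask)))
  } else raw
  list(raw = raw, glm_input = glm_input, mask = mask, n_windows = nwin,
       affine = runs[[1]]$affine,
       voxel_size_mm = .voxel_size_from_affine(runs[[1]]$affine))
}

#' Run the full dynamic-ALFF analysis
#'
#' End-to-end orchestration on a cohort: per-subject preprocessing and
#' sliding-window variability maps, demographics tests, a covariate-adjusted
#' voxelwise group GLM with cluster-level correction, partial correlations
#' of the cluster-mean variability with clinical scores (patients only,
#' adjusting for age and sex), and linear-SVM classification of the
#' cluster-mean feature with cross-validation and a label-permutation test.
#' When no cluster survives correction, the correlation and classification
#' stages are skipped.
#'
#' @param cohort A `dalff_cohort`, or a directory path understood by
#'   [read_cohort()].
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress messages.
#' @return An object of class `dalff_report`; see the print method for the
#'   demographics block, cluster table and classification summary.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "dalff_cohort"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  cov <- cohort$covariates
  t0 <- proc.time()[3]

  say("maps: computing per-subject windowed-ALFF variability (%d subjects)",
      nrow(cov))
  maps <- cohort_variability_maps(cohort, config)

  say("demographics: group tests")
  sex_tab <- table(factor(cov$sex, levels = c("M", "F")),
                   factor(cov$group, levels = c("patient", "control")))
  demographics <- list(
    sex_table = sex_tab,
    sex_chisq = chi_square_2x2(t(sex_tab)),
    age = group_scalar_test(cov$age, cov$group),
    moca = if ("moca" %in% names(cov))
      group_scalar_test(cov$moca, cov$group) else NULL,
    mmse = if ("mmse" %in% names(cov))
      group_scalar_test(cov$mmse, cov$group) else NULL)

  say("glm: voxelwise group contrast with covariates (%s)",
      paste(config$covars, collapse = ", "))
  design <- build_design(cov, covars = config$covars)
  fit <- fit_voxelwise_glm(maps$glm_input, design, contrast = "group",
                           mask = maps$mask)
  fit$t_map <- array(fit$t_map, dim(maps$mask))
  fwhm <- estimate_fwhm(fit$residuals, maps$mask, maps$voxel_size_mm[1])
  say("glm: estimated residual smoothness %.2f/%.2f/%.2f mm",
      fwhm[1], fwhm[2], fwhm[3])

  clusters <- if (config$correction == "grf") {
    grf_cluster_correction(fit$t_map, fit$df, maps$mask, fwhm,
                           maps$voxel_size_mm[1],
                           voxel_p = config$voxel_p,
                           cluster_p = config$cluster_p,
                           sided = config$sided,
                           connectivity = config$connectivity,
                           affine = maps$affine)
  } else {
    permutation_cluster_correction(maps$glm_input, design, maps$mask,
                                   voxel_p = config$voxel_p,
                                   cluster_p = config$cluster_p,
                                   sided = config$sided,
                                   connectivity = config$connectivity,
                                   n_perm = config$n_perm_cluster,
                                   seed = config$seed,
                                   affine = maps$affine)
  }
  say("clusters: %d surviving at cluster p < %g", nrow(clusters),
      config$cluster_p)

  correlations <- NULL
  classification <- NULL
  permutation <- NULL
  cv_group <- NULL
  if (nrow(clusters) > 0L) {
    cmask <- attr(clusters, "label_map") == 1L   # largest surviving cluster
    feat <- extract_cluster_feature(maps$raw, cmask)
    y <- as.integer(cov$group == "patient")
    cv_group <- list(
      patient_mean = mean(feat[y == 1]), patient_sd = sd(feat[y == 1]),
      control_mean = mean(feat[y == 0]), control_sd = sd(feat[y == 0]),
      test = group_scalar_test(drop(feat), y))

    say("correlation: cluster-mean variability vs clinical scores (patients)")
    pats <- which(y == 1)
    zcov <- cov[pats, c("age", "sex")]
    corr_one <- function(col) {
      if (!col %in% names(cov) || all(is.na(cov[[col]][pats]))) return(NULL)
      tryCatch(partial_correlation(feat[pats], cov[[col]][pats], zcov),
               error = function(e) NULL)   # too few patients / degenerate
    }
    correlations <- Filter(Negate(is.null), list(
      duration = corr_one("duration_years"),
      updrs_iii = corr_one("updrs_iii"),
      hy_stage = corr_one("hy_stage"),
      moca = corr_one("moca"),
      mmse = corr_one("mmse")))

    say("classification: %s, C = %g, %d permutations",
        config$cv_scheme, config$C, config$n_perm)
    classification <- if (config$cv_scheme == "loocv")
      loocv_classify(feat, y, C = config$C)
    else kfold_classify(feat, y, k = config$k, seed = config$seed,
                        C = config$C)
    permutation <- label_permutation_test(feat, y, n_perm = config$n_perm,
                                          seed = config$seed,
                                          scheme = config$cv_scheme,
                                          k = config$k, C = config$C)
  } else {
    say("no surviving cluster: correlation and classification skipped")
  }

  structure(list(config = config, n_subjects = nrow(cov),
                 n_windows = maps$n_windows, demographics = demographics,
                 glm = list(df = fit$df, fwhm_mm = fwhm,
                            max_t = max(abs(fit$t_map[maps$mask]))),
                 t_map = fit$t_map, mask = maps$mask,
                 clusters = clusters, cluster_feature_stats = cv_group,
                 correlations = correlations,
                 classification = classification,
                 permutation = permutation,
                 elapsed_s = unname(proc.time()[3] - t0)),
            class = "dalff_report")
}

#' @export
print.dalff_report <- function(x, ...) {
  cat("== Dynamic ALFF analysis report ==\n\n")
  cat(sprintf("Subjects: %d; windows per run: %d (length %d TR, step %d TR)\n\n",
              x$n_subjects, x$n_windows, x$config$window$length_tr,
              x$config$window$step_tr))
  d <- x$demographics
  cat("Demographics\n")
  st <- d$sex_table
  cat(sprintf("  Sex (M/F): patients %d/%d, controls %d/%d; chi-square p = %.3f\n",
              st["M", "patient"], st["F", "patient"],
              st["M", "control"], st["F", "control"], d$sex_chisq$p))
  cat(sprintf("  Age: t = %.2f, p = %.3f\n", d$age$statistic, d$age$p))
  if (!is.null(d$moca))
    cat(sprintf("  MoCA: t = %.2f, p = %.3f\n", d$moca$statistic, d$moca$p))
  if (!is.null(d$mmse))
    cat(sprintf("  MMSE: t = %.2f, p = %.3f\n", d$mmse$statistic, d$mmse$p))
  if (!is.null(x$cluster_feature_stats)) {
    cs <- x$cluster_feature_stats
    cat(sprintf("  Cluster-mean %s: patients %.3f +/- %.3f, controls %.3f +/- %.3f, p = %.2g\n",
                toupper(x$config$map), cs$patient_mean, cs$patient_sd,
                cs$control_mean, cs$control_sd, cs$test$p))
  }
  cat(sprintf("\nGroup GLM: df = %d, residual FWHM %.1f/%.1f/%.1f mm, max |t| = %.2f\n",
              x$glm$df, x$glm$fwhm_mm[1], x$glm$fwhm_mm[2], x$glm$fwhm_mm[3],
              x$glm$max_t))
  cat(sprintf("Clusters (%s correction, voxel p < %g, cluster p < %g):\n",
              toupper(x$config$correction), x$config$voxel_p,
              x$config$cluster_p))
  print(x$clusters)
  if (!is.null(x$correlations) && length(x$correlations)) {
    cat("\nPartial correlations with cluster-mean variability (patients; age & sex adjusted)\n")
    for (nm in names(x$correlations)) {
      cr <- x$correlations[[nm]]
      cat(sprintf("  %-14s r = %+.3f, p = %.3g\n", nm, cr$r, cr$p))
    }
  }
  if (!is.null(x$classification)) {
    cat("\nClassification (linear SVM, cluster-mean feature)\n")
    cl <- x$classification
    cat(sprintf("  %s: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
                cl$scheme, 100 * cl$accuracy, 100 * cl$sensitivity,
                100 * cl$specificity, cl$auc))
    cat(sprintf("  permutation test (%d shuffles): p = %.4g\n",
                x$permutation$n_perm, x$permutation$p_value))
  }
  cat(sprintf("\nElapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
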