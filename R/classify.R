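#' Extract a region-mean classification feature
#'
#' The default feature for patient-vs-control classification: one value per
#' subject, the mean of that subject's variability map over the voxels of a
#' (significant) cluster mask.  `mode = "voxel"` instead returns one column
#' per cluster voxel.
#'
#' @param maps Per-subject 3D arrays (list; [compute_dynamic_alff()] results
#'   contribute their CV map) or a voxels-by-subjects matrix.
#' @param cluster_mask 3D logical array (or a label image; nonzero = in
#'   cluster), non-empty.
#' @param mode `"mean"` (single column) or `"voxel"` (one column per voxel).
#' @return Numeric matrix, subjects by features.
#' @export
extract_cluster_feature <- function(maps, cluster_mask,
                                    mode = c("mean", "voxel")) {
  mode <- match.arg(mode)
  sel <- which(as.vector(cluster_mask) != 0)
  if (length(sel) == 0L) stop("cluster mask is empty", call. = FALSE)
  Y <- .maps_to_matrix(maps)                     # V x n
  sub <- Y[sel, , drop = FALSE]
  if (mode == "mean") matrix(colMeans(sub), ncol = 1,
                             dimnames = list(NULL, "cluster_mean"))
  else t(sub)
}

#' Train a linear support-vector machine
#'
#' Maximum-margin linear classifier with hinge loss at cost `C` (libsvm via
#' \pkg{e1071}).  The decision rule is canonicalised so that positive
#' scores `w . x + b > 0` favour the patient class (label 1).
#'
#' @param x Numeric matrix, subjects by features.
#' @param y Labels: 0/1 (1 = patient) or a factor/character with levels
#'   `control` / `patient`.
#' @param C Regularisation cost (default 1).
#' @return An object of class `linear_svm`: list with `w`, `b`, `C`.
#' @export
train_linear_classifier <- function(x, y, C = 1) {
  x <- as.matrix(x)
  y01 <- .labels01(y)
  if (length(unique(y01)) < 2L)
    stop("both classes must be present for training", call. = FALSE)
  yf <- factor(ifelse(y01 == 1, "patient", "control"),
               levels = c("control", "patient"))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's positive decision side is its first internal label; flip so
  # that positive always means patient
  if (fit$levels[fit$labels[1]] != "patient") { w <- -w; b <- -b }
  structure(list(w = w, b = b, C = C), class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d feature(s), C = %g, b = %.4g\n",
              length(x$w), x$C, x$b))
  invisible(x)
}

#' @rdname train_linear_classifier
#' @param object A `linear_svm`.
#' @param newdata Matrix of observations to score.
#' @param ... Unused.
#' @return `predict()` returns a list with `score` (`w . x + b`) and `label`
#'   (1 = patient for positive scores; a score of exactly 0 is assigned to
#'   control).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% object$w) + object$b
  list(score = score, label = as.integer(score > 0))
}

.labels01 <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("control", "patient")))
      stop("labels must be 0/1 or control/patient", call. = FALSE)
    as.integer(y == "patient")
  } else {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L)))
      stop("numeric labels must be 0 or 1", call. = FALSE)
    y
  }
}

#' Area under the ROC curve
#'
#' Rank statistic: the probability that a randomly chosen patient scores
#' above a randomly chosen control, ties counting one half (equivalent to
#' the Mann-Whitney U scaled to `[0, 1]`).
#'
#' @param scores Numeric decision scores (higher = more patient-like).
#' @param labels 0/1 labels (1 = patient) or control/patient.
#' @return AUC in `[0, 1]`; all-tied scores give 0.5.
#' @export
roc_auc <- function(scores, labels) {
  y <- .labels01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity / 1-specificity pairs over all score thresholds.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- .labels01(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(u) {
    pred <- as.integer(scores >= u)
    data.frame(threshold = u,
               tpr = sum(pred == 1 & y == 1) / sum(y == 1),
               fpr = sum(pred == 1 & y == 0) / sum(y == 0))
  }))
}

# Shared cross-validation engine: `folds` is a list of held-out index
# vectors covering 1..n.  Per fold the features are standardised with the
# training fold's mean/SD, the SVM is fit on the training fold, and the
# held-out subjects are scored; metrics aggregate held-out predictions only.
.cv_engine <- function(x, y01, folds, C, standardize, scheme) {
  x <- as.matrix(x)
  n <- nrow(x)
  score <- numeric(n)
  pred <- integer(n)
  fold_id <- integer(n)
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    if (length(unique(y01[tr])) < 2L)
      stop("a training fold is missing a class", call. = FALSE)
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    clf <- train_linear_classifier(xtr, y01[tr], C = C)
    pr <- predict(clf, xte)
    score[te] <- pr$score
    pred[te] <- pr$label
    fold_id[te] <- f
  }
  tp <- sum(pred == 1 & y01 == 1); tn <- sum(pred == 0 & y01 == 0)
  fp <- sum(pred == 1 & y01 == 0); fn <- sum(pred == 0 & y01 == 1)
  structure(list(
    predictions = data.frame(index = seq_len(n), label = y01, pred = pred,
                             score = score, fold = fold_id),
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = roc_auc(score, y01),
    scheme = scheme), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> scheme %s: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
              x$scheme, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity, x$auc))
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' Each subject is predicted by a linear SVM trained on the remaining
#' `n - 1`; accuracy, sensitivity (patient = positive), specificity and the
#' AUC of pooled held-out decision scores are computed from the held-out
#' predictions only.
#'
#' @inheritParams train_linear_classifier
#' @param standardize Standardise features with the training fold's mean/SD
#'   (test fold transformed with the training parameters)?  Default `TRUE`.
#' @return An object of class `cv_result` with elements `predictions`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `scheme`.
#' @export
loocv_classify <- function(x, y, C = 1, standardize = TRUE) {
  y01 <- .labels01(y)
  n <- length(y01)
  .cv_engine(x, y01, as.list(seq_len(n)), C, standardize, "loocv")
}

#' Stratified k-fold cross-validated classification
#'
#' Subjects of each class are shuffled (from `seed`) and dealt into `k`
#' folds so class proportions are preserved; `k = n` reduces to
#' leave-one-out.
#'
#' @inheritParams loocv_classify
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return A `cv_result` (see [loocv_classify()]); `scheme` records `k` and
#'   the seed.
#' @export
kfold_classify <- function(x, y, k = 10, seed = 1, C = 1,
                           standardize = TRUE) {
  y01 <- .labels01(y)
  n <- length(y01)
  if (k > n) stop("k cannot exceed the number of subjects", call. = FALSE)
  if (min(table(y01)) < k && k < n)
    warning("a class has fewer members than folds; stratification is partial",
            call. = FALSE)
  set.seed(seed)
  # deal the class-shuffled subjects into folds in one continuous sequence:
  # folds stay class-balanced to within one subject, and k = n gives the
  # singleton folds of leave-one-out
  ord <- unlist(lapply(sort(unique(y01)), function(cls)
    sample(which(y01 == cls))), use.names = FALSE)
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(k), n)
  folds <- split(seq_len(n), fold_of)
  .cv_engine(x, y01, folds, C, standardize,
             sprintf("kfold(k=%d, seed=%d)", k, seed))
}

#' Label-permutation test of cross-validated accuracy
#'
#' Observed accuracy comes from the chosen cross-validation scheme with the
#' true labels; the null distribution re-runs the entire cross-validation
#' `n_perm` times with labels randomly reallocated to subjects (a plain
#' shuffle, preserving group sizes).  The p-value uses the add-one rule
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`, so it is never zero.
#'
#' @inheritParams loocv_classify
#' @param n_perm Number of label shuffles (>= 1).
#' @param seed Integer seed for the shuffles.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Folds when `scheme = "kfold"`.
#' @return An object of class `permutation_result`: list with
#'   `observed` (the true-label `cv_result`), `observed_accuracy`,
#'   `null_accuracies` (length `n_perm`) and `p_value`.
#' @export
label_permutation_test <- function(x, y, n_perm = 5000, seed = 1,
                                   scheme = c("loocv", "kfold"), k = 10,
                                   C = 1, standardize = TRUE) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  y01 <- .labels01(y)
  run_cv <- function(lab, s) {
    if (scheme == "loocv") loocv_classify(x, lab, C = C,
                                          standardize = standardize)
    else kfold_classify(x, lab, k = k, seed = s, C = C,
                        standardize = standardize)
  }
  obs <- run_cv(y01, seed)
  set.seed(seed)
  null_acc <- vapply(seq_len(n_perm), function(b) {
    run_cv(sample(y01), seed + b)$accuracy
  }, numeric(1))
  p <- (1 + sum(null_acc >= obs$accuracy)) / (1 + n_perm)
  structure(list(observed = obs, observed_accuracy = obs$accuracy,
                 null_accuracies = null_acc, p_value = p,
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.2f%%; %d shuffles; p = %.4g\n",
              100 * x$observed_accuracy, x$n_perm, x$p_value))
  cat(sprintf("  null accuracy: mean %.3f, 95th percentile %.3f\n",
              mean(x$null_accuracies),
              quantile(x$null_accuracies, 0.95)))
  invisible(x)
}
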