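test_that("cluster-mean feature extraction averages the right voxels", {
  d <- c(3, 3, 3)
  maps <- lapply(1:4, function(i) array(i / 10, d))
  mask1 <- array(FALSE, d); mask1[2, 2, 2] <- TRUE
  f1 <- extract_cluster_feature(maps, mask1)
  expect_equal(drop(f1), c(0.1, 0.2, 0.3, 0.4))
  # constant map -> feature = constant regardless of mask size
  mask_all <- array(TRUE, d)
  expect_equal(drop(extract_cluster_feature(maps, mask_all)),
               c(0.1, 0.2, 0.3, 0.4))
  # 2-voxel mask with values 0.1 and 0.3 -> 0.2
  m <- array(0, d); m[1, 1, 1] <- 0.1; m[3, 3, 3] <- 0.3
  mask2 <- array(FALSE, d); mask2[1, 1, 1] <- TRUE; mask2[3, 3, 3] <- TRUE
  expect_equal(unname(drop(extract_cluster_feature(list(m), mask2))), 0.2)
  # voxelwise mode: one column per voxel
  fv <- extract_cluster_feature(maps, mask2, mode = "voxel")
  expect_equal(dim(fv), c(4, 2))
  expect_error(extract_cluster_feature(maps, array(FALSE, d)), "empty")
})

test_that("linear SVM separates, flips with labels, and finds the midpoint margin", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  clf <- train_linear_classifier(x, y, C = 100)
  pr <- predict(clf, x)
  expect_equal(pr$label, y)
  expect_true(all(pr$score[y == 1] > 0), all(pr$score[y == 0] < 0))
  # flipping all labels flips the decision rule's sign
  clf2 <- train_linear_classifier(x, 1 - y, C = 100)
  expect_equal(clf2$w, -clf$w, tolerance = 1e-6)
  expect_equal(clf2$b, -clf$b, tolerance = 1e-6)
  # 4-point 1-D hand instance: hard-margin boundary midway between the
  # innermost opposite-class points (2 and 6 -> boundary 4), verified by a
  # brute-force grid search over (w, b) maximising the margin
  x4 <- matrix(c(0, 2, 6, 9), ncol = 1)
  y4 <- c(0, 0, 1, 1)
  clf4 <- train_linear_classifier(x4, y4, C = 1e4)
  boundary <- -clf4$b / clf4$w
  grid <- expand.grid(w = seq(0.05, 2, by = 0.005),
                      b = seq(-10, 10, by = 0.01))
  marg <- apply(grid, 1, function(p) {
    s <- p["w"] * x4 + p["b"]
    if (all(sign(s) == c(-1, -1, 1, 1))) min(abs(s)) / abs(p["w"]) else -Inf
  })
  best <- grid[which.max(marg), ]
  expect_equal(boundary, -best$b / best$w, tolerance = 0.05)
  expect_equal(boundary, 4, tolerance = 0.05)
  expect_error(train_linear_classifier(x, rep(1, 6)), "both classes")
})

test_that("LOOCV matches manual enumeration on a 6-subject hand instance", {
  # features chosen so two subjects are 'misplaced': each held-out fold's
  # hard-margin 1-D boundary is the midpoint of the innermost opposite pair
  # of the remaining five points
  x <- matrix(c(0, 1, 9, 2, 10, 11), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  res <- loocv_classify(x, y, C = 1e4, standardize = FALSE)
  manual <- integer(6)
  for (i in 1:6) {
    tr <- setdiff(1:6, i)
    ctrl <- x[tr[y[tr] == 0], 1]; pat <- x[tr[y[tr] == 1], 1]
    boundary <- (max(ctrl) + min(pat)) / 2    # innermost pair midpoint
    manual[i] <- as.integer(x[i, 1] > boundary)
  }
  # manual enumeration: subject 3 (value 9, control) -> boundary between
  # max(0,1)=1 and min(2,10,11)=2 is 1.5, predicted patient (wrong);
  # subject 4 (value 2, patient) -> boundary (9+10)/2 = 9.5, control (wrong)
  expect_equal(manual, c(0L, 0L, 1L, 0L, 1L, 1L))
  expect_equal(res$predictions$pred, manual)
  expect_equal(res$accuracy, 4 / 6)
  expect_equal(res$sensitivity, 2 / 3)
  expect_equal(res$specificity, 2 / 3)
})

test_that("LOOCV is invariant to subject ordering and perfect on separated data", {
  set.seed(21)
  x <- matrix(c(rnorm(10, 0), rnorm(10, 8)), ncol = 1)
  y <- rep(c(0, 1), each = 10)
  res <- loocv_classify(x, y)
  expect_equal(res$accuracy, 1)
  expect_equal(res$auc, 1)
  perm <- sample(20)
  res_p <- loocv_classify(x[perm, , drop = FALSE], y[perm])
  expect_equal(res_p$predictions$pred[order(perm)], res$predictions$pred)
  # metrics identity: accuracy = (sens*n_pos + spec*n_neg)/n
  expect_equal(res$accuracy,
               (res$sensitivity * 10 + res$specificity * 10) / 20)
})

test_that("k-fold reduces to LOOCV at k = n and is seed-deterministic", {
  set.seed(22)
  x <- matrix(rnorm(12), ncol = 1)
  y <- rep(c(0, 1), each = 6)
  lo <- loocv_classify(x, y)
  kf <- kfold_classify(x, y, k = 12, seed = 5)
  expect_equal(kf$predictions$pred, lo$predictions$pred)
  expect_equal(kf$predictions$score, lo$predictions$score)
  kf1 <- kfold_classify(x, y, k = 3, seed = 9)
  kf2 <- kfold_classify(x, y, k = 3, seed = 9)
  expect_identical(kf1$predictions, kf2$predictions)
  # separable data: accuracy 1 under 10-fold
  xs <- matrix(c(rnorm(10, 0), rnorm(10, 8)), ncol = 1)
  ys <- rep(c(0, 1), each = 10)
  expect_equal(kfold_classify(xs, ys, k = 10, seed = 1)$accuracy, 1)
  expect_warning(kfold_classify(xs, ys, k = 11, seed = 1), "fewer members")
})

test_that("AUC is the tie-aware pair-counting rank statistic", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  # 4-subject case with one inversion: pairs (3>1),(3>4),(2>1),(2>4)
  s <- c(1, 3, 2, 4); y <- c(0, 1, 1, 0)
  # brute force: count patient > control (+1), ties +0.5, over 4 pairs
  pairs <- expand.grid(p = which(y == 1), c = which(y == 0))
  bf <- mean(ifelse(s[pairs$p] > s[pairs$c], 1,
                    ifelse(s[pairs$p] == s[pairs$c], 0.5, 0)))
  expect_equal(roc_auc(s, y), bf)
  expect_equal(roc_auc(s, y), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  # roc_curve endpoints
  rc <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(rc$tpr[1], 0); expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1); expect_equal(rc$fpr[nrow(rc)], 1)
})

test_that("permutation test boundary cases and add-one rule", {
  set.seed(23)
  # perfectly separated: observed accuracy 1 beats (almost) all shuffles
  x <- matrix(c(rnorm(6, 0), rnorm(6, 10)), ncol = 1)
  y <- rep(c(0, 1), each = 6)
  pt1 <- label_permutation_test(x, y, n_perm = 49, seed = 3)
  expect_equal(pt1$observed_accuracy, 1)
  expect_length(pt1$null_accuracies, 49)
  expect_gt(pt1$p_value, 0)           # add-one: never exactly 0
  expect_lte(pt1$p_value, 0.1)
  # worst case: every null >= observed -> p = 1 exactly
  # (constant feature: every CV run gives identical accuracy)
  xc <- matrix(0, 12, 1)
  ptc <- label_permutation_test(xc, y, n_perm = 19, seed = 4)
  expect_equal(ptc$p_value, 1)
})

test_that("chance-level features give chance-level stratified-CV accuracy", {
  # stratified k-fold keeps training folds class-balanced, so a useless
  # feature yields chance accuracy without the pessimistic bias that
  # leave-one-out shows with balanced classes (the held-out subject's class
  # is always the training minority)
  set.seed(24)
  accs <- vapply(1:30, function(i) {
    x <- matrix(rnorm(40), ncol = 1)
    y <- sample(rep(c(0, 1), each = 20))
    kfold_classify(x, y, k = 5, seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.08)
  # leave-one-out on the same data sits at or below chance, never above
  acc_loo <- mean(vapply(1:10, function(i) {
    x <- matrix(rnorm(40), ncol = 1)
    y <- sample(rep(c(0, 1), each = 20))
    loocv_classify(x, y)$accuracy
  }, numeric(1)))
  expect_lt(acc_loo, 0.58)
})
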