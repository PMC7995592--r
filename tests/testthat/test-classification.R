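test_that("subtask binarization maps 0/2 to High-risk and 4 to Low-risk", {
  expect_equal(as.integer(binarize_subtask(c(0, 2, 4))), c(1, 1, 0))
  expect_identical(attr(binarize_subtask(4), "positive"), "High-risk")
  expect_error(binarize_subtask(3), class = "tug_argument_error")
})

test_that("confusion-matrix metrics follow their defining ratios", {
  perfect <- classification_metrics(confusion_matrix(5, 0, 0, 5))
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity", "f_score")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1, f_score = 1))

  m <- classification_metrics(confusion_matrix(tp = 5, fp = 2, fn = 3,
                                               tn = 10))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 5 / 7)
  expect_equal(m$sensitivity, 0.625)
  expect_equal(m$specificity, 10 / 12)
  expect_equal(m$f_score, 2 * (5 / 7) * 0.625 / (5 / 7 + 0.625))

  # harmonic-mean identity: precision = sensitivity = p implies F = p
  mm <- classification_metrics(confusion_matrix(tp = 6, fp = 2, fn = 2,
                                                tn = 5))
  expect_equal(mm$precision, mm$sensitivity)
  expect_equal(mm$f_score, mm$precision)

  # zero denominators are undefined, never zero
  nopos <- classification_metrics(confusion_matrix(0, 0, 0, 8))
  expect_true(is.na(nopos$precision))
  expect_true(is.na(nopos$sensitivity))
  expect_equal(nopos$accuracy, 1)
})

test_that("trapezoid AUC equals the Mann-Whitney concordance oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    # include ties among scores
    scores <- round(rnorm(n), 1)
    roc <- roc_auc(scores, labels)
    expect_equal(roc$auc, mw_auc_oracle(scores, labels), tolerance = 1e-12)
    # curve anchored at (0,0) and (1,1), monotone along the sweep
    pts <- roc$points
    expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
    expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    # reversing the score sign complements the AUC
    expect_equal(roc_auc(-scores, labels)$auc, 1 - roc$auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC hits the two calibration points: separation and independence", {
  # perfectly separated scores
  expect_equal(roc_auc(c(rnorm(20, 5), rnorm(20, -5)),
                       rep(c(1, 0), each = 20))$auc, 1)
  # independent scores, n = 2000: AUC 0.5 +/- 0.03
  set.seed(22)
  scores <- rnorm(2000); labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.03)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), class = "tug_argument_error")
})

test_that("penalized logistic classifier agrees with a direct optimizer", {
  set.seed(23)
  n <- 80
  X <- cbind(rnorm(n), rnorm(n))
  colnames(X) <- c("a", "b")
  eta <- 1.2 * X[, 1] - 0.6 * X[, 2]
  labels <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  spec <- enet_spec(alpha = 0.5, lambda = 0.05, standardize = FALSE)
  fit <- fit_subtask_classifier(X, labels, spec)

  # independent oracle: minimize the penalized negative log-likelihood
  # (glmnet's objective) with a general-purpose optimizer
  obj <- function(par) {
    et <- par[1] + X %*% par[2:3]
    -mean(labels * et - log(1 + exp(et))) +
      0.05 * (0.25 * sum(par[2:3]^2) + 0.5 * sum(abs(par[2:3])))
  }
  o <- optim(c(0, 0, 0), obj, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(unname(fit$coefficients), o$par[2:3], tolerance = 1e-3)
  expect_equal(fit$intercept, o$par[1], tolerance = 1e-3)

  # separable toy with tiny penalty classifies its training set perfectly
  Xs <- cbind(c(rnorm(20, 3), rnorm(20, -3)), rnorm(40))
  ls <- rep(c(1, 0), each = 20)
  fs <- fit_subtask_classifier(Xs, ls, enet_spec(0.5, 1e-4))
  expect_equal(predict(fs, Xs, type = "class"), ls)

  # infinite penalty: intercept-only majority model
  fsat <- fit_subtask_classifier(Xs, ls, enet_spec(1, 100))
  expect_true(all(fsat$coefficients == 0))

  expect_error(fit_subtask_classifier(Xs, rep(1, 40), spec),
               class = "tug_argument_error")
})

test_that("subtask protocol separates signal cohorts from permuted nulls", {
  ccf <- cached_cohort_features(n = 60, seed = 11)
  feats <- ccf$features
  X <- as.matrix(feats[, feature_registry()$name])
  n_iter <- 30  # protocol scaled down for the unit suite; full scale in
                # the acceptance tests

  # noise-free separable labels built from a strong feature
  sep_labels <- as.integer(feats$walk_gait_speed <
                             median(feats$walk_gait_speed))
  item_sep <- ifelse(sep_labels == 1, 0, 4)
  res_sep <- run_subtask_rsscv(X, item_sep, task = 7, n_iter = n_iter,
                               seed = 31)
  expect_gt(res_sep$pooled_auc, 0.9)

  # permuted labels: chance-level discrimination
  set.seed(32)
  item_perm <- sample(item_sep)
  res_perm <- run_subtask_rsscv(X, item_perm, task = 7, n_iter = n_iter,
                                seed = 33)
  expect_lt(abs(res_perm$pooled_auc - 0.5), 0.12)

  # per-iteration metric averages recomputed from the stored table
  it <- res_sep$result$iterations[res_sep$result$iterations$valid, ]
  expect_equal(res_sep$metrics_mean$accuracy, mean(it$accuracy, na.rm = TRUE))
  expect_equal(res_sep$metrics_mean$auc, mean(it$auc, na.rm = TRUE))
  # pooled confusion matrix equals the summed per-iteration counts
  expect_equal(res_sep$metrics_pooled$accuracy,
               (sum(it$tp) + sum(it$tn)) /
                 (sum(it$tp) + sum(it$fp) + sum(it$fn) + sum(it$tn)))
  # Eq-9 identity on every emitted record
  ok <- !is.na(it$precision) & !is.na(it$sensitivity) &
    (it$precision + it$sensitivity) > 0
  expect_equal(it$f_score[ok],
               2 * it$precision[ok] * it$sensitivity[ok] /
                 (it$precision[ok] + it$sensitivity[ok]))
})
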