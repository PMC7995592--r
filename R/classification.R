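#' Confusion matrix
#'
#' @param tp,fp,fn,tn non-negative counts: true/false positives/negatives,
#'   with High-risk as the positive class.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  v <- c(tp, fp, fn, tn)
  if (any(v < 0) || any(v != round(v)))
    abort_argument("confusion counts must be non-negative integers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = sum(v)),
            class = "confusion_matrix")
}

#' Classification performance metrics
#'
#' Accuracy (TP+TN)/(all), precision TP/(TP+FP), sensitivity TP/(TP+FN),
#' specificity TN/(FP+TN) and the F-score, the harmonic mean of precision
#' and sensitivity. Metrics with a zero denominator are flagged undefined
#' (`NA`), never reported as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return Object of class `classification_metrics` with fields `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `f_score`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0) abort_argument("empty confusion matrix")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(cm$tp, cm$tp + cm$fp)
  sensitivity <- div(cm$tp, cm$tp + cm$fn)
  f <- if (is.na(precision) || is.na(sensitivity) ||
           precision + sensitivity == 0) NA_real_
       else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(accuracy = (cm$tp + cm$tn) / cm$n,
                 precision = precision, sensitivity = sensitivity,
                 specificity = div(cm$tn, cm$fp + cm$tn),
                 f_score = f),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "<classification_metrics> acc %.3f, prec %.3f, sens %.3f, spec %.3f, F %.3f\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity, x$f_score))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique risk scores and traces
#' (false positive rate, true positive rate) pairs from (0,0) to (1,1);
#' the AUC is computed by the trapezoid rule and equals the Mann-Whitney
#' concordance probability with ties counted 1/2.
#'
#' @param scores continuous risk scores (higher = more likely positive).
#' @param labels 0/1 labels (1 = positive, High-risk).
#' @return Object of class `roc_curve`: data.frame `points` with columns
#'   `threshold`, `fpr`, `tpr`, and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort_argument("length mismatch")
  if (!all(labels %in% c(0, 1))) abort_argument("labels must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    abort_argument("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0) / n_neg
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Fit a penalized binomial classifier for one SFBBS subtask
#'
#' Elastic-net-penalized logistic regression producing continuous risk
#' scores in (0, 1); class decisions use a 0.5 threshold by default. A
#' linear-probability fallback (gaussian loss on the 0/1 labels) is
#' available for sensitivity analysis.
#'
#' @param X numeric n x p design matrix.
#' @param labels 0/1 labels (1 = High-risk).
#' @param spec an [enet_spec()].
#' @param link `"logit"` (default) or `"linear"` for the
#'   linear-probability fallback.
#' @return Object of class `subtask_classifier` with `intercept`,
#'   `coefficients`, `spec`, `link`.
#' @export
fit_subtask_classifier <- function(X, labels, spec = enet_spec(),
                                   link = c("logit", "linear")) {
  link <- match.arg(link)
  X <- as.matrix(X)
  if (!all(labels %in% c(0, 1))) abort_argument("labels must be 0/1")
  if (length(unique(labels)) < 2)
    abort_argument("both classes must be present to fit a classifier")
  if (link == "linear") {
    f <- fit_elastic_net(X, labels, spec)
    return(structure(list(intercept = f$intercept,
                          coefficients = f$coefficients, spec = spec,
                          link = link), class = "subtask_classifier"))
  }
  fit <- glmnet::glmnet(X, labels, family = "binomial", alpha = spec$alpha,
                        lambda = lambda_path(spec$lambda, 1),
                        standardize = spec$standardize,
                        thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(stats::coef(fit, s = spec$lambda))
  beta <- cf[-1]; names(beta) <- colnames(X)
  structure(list(intercept = cf[1], coefficients = beta, spec = spec,
                 link = link), class = "subtask_classifier")
}

#' @export
#' @rdname fit_subtask_classifier
#' @param object a `subtask_classifier`.
#' @param newx matrix with the same columns as the training design.
#' @param type `"score"` for continuous risk scores, `"class"` for 0/1
#'   decisions at threshold 0.5.
#' @param ... unused.
predict.subtask_classifier <- function(object, newx,
                                       type = c("score", "class"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$coefficients))
    abort_argument("newx has the wrong number of columns")
  eta <- object$intercept + as.numeric(newx %*% object$coefficients)
  score <- if (object$link == "logit") 1 / (1 + exp(-eta)) else eta
  if (type == "score") score else as.integer(score >= 0.5)
}

#' Subtask risk classification under the shuffle-split protocol
#'
#' Binarizes one SFBBS item (scores 0 and 2 are High-risk, 4 is Low-risk)
#' and runs the same 100-iteration 80/20 shuffle-split protocol with inner
#' 10-fold tuning, using penalized logistic regression. Iterations whose
#' training split lacks a class are skipped; at least 90% of iterations
#' must be valid. Both per-iteration-averaged metrics and metrics pooled
#' over all held-out predictions are reported, together with the pooled
#' ROC curve.
#'
#' @param X numeric n x p feature matrix.
#' @param item_scores the item's ordinal scores in {0, 2, 4}.
#' @param task subtask identifier kept in the report (e.g. 3, 6 or 7).
#' @param ... protocol arguments passed to [run_rsscv()] (`n_iter`,
#'   `test_frac`, `inner_folds`, `alpha_grid`, `seed`, ...).
#' @return Object of class `subtask_rsscv`: the underlying `rsscv` result
#'   plus `task`, `metrics_mean` (per-iteration averages),
#'   `metrics_pooled` (from the pooled confusion matrix) and `roc`
#'   (pooled).
#' @export
run_subtask_rsscv <- function(X, item_scores, task = NA, ...) {
  labels <- as.integer(binarize_subtask(item_scores))
  res <- run_rsscv(X, labels, family = "binomial", ...)
  if (res$n_valid < 0.9 * res$n_iter)
    abort_protocol(sprintf(
      "only %d of %d iterations had both classes in training",
      res$n_valid, res$n_iter))
  it <- res$iterations[res$iterations$valid, , drop = FALSE]
  metrics_mean <- list(accuracy = mean(it$accuracy, na.rm = TRUE),
                       precision = mean(it$precision, na.rm = TRUE),
                       sensitivity = mean(it$sensitivity, na.rm = TRUE),
                       specificity = mean(it$specificity, na.rm = TRUE),
                       f_score = mean(it$f_score, na.rm = TRUE),
                       auc = mean(it$auc, na.rm = TRUE))
  cm <- confusion_matrix(tp = sum(it$tp), fp = sum(it$fp),
                         fn = sum(it$fn), tn = sum(it$tn))
  pooled_scores <- unlist(res$scores[res$iterations$valid])
  pooled_labels <- unlist(res$labels[res$iterations$valid])
  roc <- roc_auc(pooled_scores, pooled_labels)
  structure(list(result = res, task = task, metrics_mean = metrics_mean,
                 metrics_pooled = classification_metrics(cm),
                 pooled_auc = roc$auc, roc = roc),
            class = "subtask_rsscv")
}

#' @export
print.subtask_rsscv <- function(x, ...) {
  m <- x$metrics_mean
  cat(sprintf(paste0(
    "<subtask_rsscv> SFBBS item %s, %d valid iterations\n",
    "  per-iteration means: acc %.3f, sens %.3f, prec %.3f, spec %.3f, ",
    "F %.3f, AUC %.3f\n  pooled AUC %.3f\n"),
    as.character(x$task), x$result$n_valid,
    m$accuracy, m$sensitivity, m$precision, m$specificity, m$f_score,
    m$auc, x$pooled_auc))
  invisible(x)
}
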