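#' Random-shuffle-split cross-validation of penalized models
#'
#' The evaluation protocol for balance estimation: `n_iter` times (default
#' 100), a random 80/20 train/test shuffle-split is drawn; on the training
#' portion the elastic-net mixing weight and penalty strength are tuned by
#' inner k-fold (default 10-fold) cross-validation; the tuned model is
#' refit on the whole training portion and evaluated on the held-out test
#' portion. Per-iteration test metrics, selected-feature masks and
#' coefficient vectors are retained so that feature selection frequency and
#' accumulated-coefficient importance can be aggregated afterwards.
#'
#' Missing feature values are mean-imputed using training-split statistics
#' only (the test portion is imputed with training means), and glmnet
#' standardizes within each inner-fold fit, so no information flows from
#' test to train. Iteration seeds are derived deterministically from the
#' master seed (`seed + iteration`), making the whole protocol reproducible
#' end to end.
#'
#' For `family = "binomial"` the response must be a 0/1 label vector
#' (1 = positive class); iterations whose training split lacks one of the
#' classes are skipped and flagged invalid.
#'
#' @param X numeric n x p feature matrix (may contain `NA`).
#' @param y response: numeric (gaussian) or 0/1 labels (binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param n_iter number of shuffle-split iterations.
#' @param test_frac held-out fraction per iteration.
#' @param inner_folds inner cross-validation folds for tuning.
#' @param alpha_grid candidate mixing weights.
#' @param n_lambda,lambda_decades penalty grid: `n_lambda` log-spaced values
#'   from the data-driven lambda_max down `lambda_decades` decades.
#' @param alpha optional fixed mixing weight (e.g. `0` for pure ridge,
#'   `1` for pure lasso); overrides `alpha_grid`.
#' @param cv_thresh coordinate-descent convergence threshold used inside
#'   the inner tuning loop. Model selection does not need solver-grade
#'   precision, and the relaxed default makes the protocol several times
#'   faster; the final refit of each iteration uses glmnet's default.
#' @param seed master seed.
#' @return Object of class `rsscv` with elements `iterations`
#'   (per-iteration data.frame of metrics and chosen hyper-parameters),
#'   `coef_raw`, `coef_std` (p x n_iter matrices of original-scale and
#'   standardized coefficients), `selected` (logical p x n_iter mask),
#'   `test_index` (list of held-out index vectors), `scores`/`labels`
#'   (binomial only, per-iteration test scores for pooled ROC),
#'   `feature_names`, `family`, `seed`, `n_valid`.
#' @seealso [selection_frequency()], [relative_importance()]
#' @export
run_rsscv <- function(X, y, family = c("gaussian", "binomial"),
                      n_iter = 100, test_frac = 0.2, inner_folds = 10,
                      alpha_grid = seq(0, 1, 0.1), n_lambda = 50,
                      lambda_decades = 4, alpha = NULL, cv_thresh = 1e-5,
                      seed = 1) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (length(y) != n) abort_argument("X and y sizes differ")
  if (n < 10) abort_argument("need at least 10 participants")
  if (inner_folds < 2) abort_argument("inner_folds must be >= 2")
  if (length(unique(y[!is.na(y)])) < 2)
    abort_protocol("degenerate response: y is constant")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    abort_argument("binomial response must be 0/1 labels")
  if (!is.null(alpha)) alpha_grid <- alpha
  n_test <- max(1L, round(test_frac * n))
  if (n_test >= n) abort_argument("test_frac leaves no training data")

  iters <- vector("list", n_iter)
  coef_raw <- matrix(NA_real_, p, n_iter,
                     dimnames = list(colnames(X), NULL))
  coef_std <- coef_raw
  selected <- matrix(NA, p, n_iter)
  test_index <- vector("list", n_iter)
  scores <- vector("list", n_iter)
  labels <- vector("list", n_iter)
  type_measure <- if (family == "gaussian") "mae" else "deviance"

  for (i in seq_len(n_iter)) {
    set.seed(seed + i)
    idx_test <- sort(sample.int(n, n_test))
    test_index[[i]] <- idx_test
    Xtr <- X[-idx_test, , drop = FALSE]; ytr <- y[-idx_test]
    Xte <- X[idx_test, , drop = FALSE]; yte <- y[idx_test]

    # binomial fits need both classes (and glmnet needs >= 2 per class,
    # also within inner folds); any such failure invalidates the iteration
    if (length(unique(ytr)) < 2 ||
        (family == "binomial" && min(table(ytr)) < 2)) {
      iters[[i]] <- iteration_row(i, seed + i, valid = FALSE, family)
      next
    }

    # training-split imputation statistics, applied to both portions
    mu <- colMeans(Xtr, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    Xtr <- impute_cols(Xtr, mu)
    Xte <- impute_cols(Xte, mu)

    foldid <- sample(rep(seq_len(inner_folds), length.out = nrow(Xtr)))
    cf <- tryCatch({
      lam_grid <- lambda_grid(Xtr, ytr, family, n_lambda, lambda_decades)
      best <- NULL
      for (a in alpha_grid) {
        cv <- glmnet::cv.glmnet(Xtr, ytr, family = family, alpha = a,
                                lambda = lam_grid, foldid = foldid,
                                type.measure = type_measure,
                                standardize = TRUE, thresh = cv_thresh)
        k <- which.min(cv$cvm)  # grid is decreasing: ties -> larger lambda
        if (is.null(best) || cv$cvm[k] < best$cvm) {
          best <- list(alpha = a, lambda = cv$lambda[k], cvm = cv$cvm[k])
        }
      }
      fit <- glmnet::glmnet(Xtr, ytr, family = family, alpha = best$alpha,
                            lambda = lam_grid, standardize = TRUE)
      as.numeric(stats::coef(fit, s = best$lambda))
    }, error = function(e) NULL)
    if (is.null(cf)) {   # degenerate split (e.g. a one-class inner fold)
      iters[[i]] <- iteration_row(i, seed + i, valid = FALSE, family)
      next
    }
    beta <- cf[-1]
    sds <- apply(Xtr, 2, stats::sd)
    coef_raw[, i] <- beta
    coef_std[, i] <- beta * sds
    selected[, i] <- beta != 0

    if (family == "gaussian") {
      pred <- cf[1] + as.numeric(Xte %*% beta)
      m <- evaluate(yte, pred)
      iters[[i]] <- iteration_row(i, seed + i, TRUE, family,
                                  alpha = best$alpha, lambda = best$lambda,
                                  mae = m$mae, rmse = m$rmse)
    } else {
      eta <- cf[1] + as.numeric(Xte %*% beta)
      prob <- 1 / (1 + exp(-eta))
      cls <- as.integer(prob >= 0.5)
      cm <- confusion_matrix(tp = sum(cls == 1 & yte == 1),
                             fp = sum(cls == 1 & yte == 0),
                             fn = sum(cls == 0 & yte == 1),
                             tn = sum(cls == 0 & yte == 0))
      cmm <- classification_metrics(cm)
      auc_i <- if (length(unique(yte)) == 2) roc_auc(prob, yte)$auc
               else NA_real_
      scores[[i]] <- prob; labels[[i]] <- yte
      iters[[i]] <- iteration_row(i, seed + i, TRUE, family,
                                  alpha = best$alpha, lambda = best$lambda,
                                  accuracy = cmm$accuracy,
                                  precision = cmm$precision,
                                  sensitivity = cmm$sensitivity,
                                  specificity = cmm$specificity,
                                  f_score = cmm$f_score, auc = auc_i,
                                  tp = cm$tp, fp = cm$fp, fn = cm$fn,
                                  tn = cm$tn)
    }
  }

  iterations <- do.call(rbind, iters)
  structure(list(iterations = iterations, coef_raw = coef_raw,
                 coef_std = coef_std, selected = selected,
                 test_index = test_index,
                 scores = scores, labels = labels,
                 feature_names = colnames(X), family = family,
                 n_iter = n_iter, seed = seed,
                 n_valid = sum(iterations$valid)),
            class = "rsscv")
}

impute_cols <- function(M, mu) {
  for (j in which(colSums(is.na(M)) > 0)) M[is.na(M[, j]), j] <- mu[j]
  M
}

# lambda grid shared across the alpha grid, anchored at the lasso lambda_max
# (the smallest penalty zeroing all coefficients at alpha = 1)
lambda_grid <- function(X, y, family, n_lambda, decades) {
  f0 <- glmnet::glmnet(X, y, family = family, alpha = 1,
                       standardize = TRUE, nlambda = 5)
  lam_max <- max(f0$lambda)
  lam_max * 10^seq(0, -decades, length.out = n_lambda)
}

iteration_row <- function(i, iter_seed, valid, family, alpha = NA_real_,
                          lambda = NA_real_, ...) {
  extra <- list(...)
  base <- data.frame(iter = i, seed = iter_seed, valid = valid,
                     alpha = alpha, lambda = lambda)
  if (family == "gaussian") {
    base$mae <- if (!is.null(extra$mae)) extra$mae else NA_real_
    base$rmse <- if (!is.null(extra$rmse)) extra$rmse else NA_real_
  } else {
    for (f in c("accuracy", "precision", "sensitivity", "specificity",
                "f_score", "auc", "tp", "fp", "fn", "tn"))
      base[[f]] <- if (!is.null(extra[[f]])) extra[[f]] else NA_real_
  }
  base
}

#' Per-feature selection frequency across the protocol
#'
#' Counts, for each feature, the iterations in which it entered the model
#' with a nonzero coefficient.
#'
#' @param result an [run_rsscv()] result.
#' @return Named integer vector of counts in `0..n_valid`.
#' @export
selection_frequency <- function(result) {
  stopifnot(inherits(result, "rsscv"))
  ok <- result$iterations$valid
  counts <- rowSums(result$selected[, ok, drop = FALSE])
  stats::setNames(as.integer(counts), result$feature_names)
}

#' Relative feature importance across the protocol
#'
#' Importance of feature j is the accumulated magnitude of its standardized
#' regression coefficients over all protocol iterations, rescaled so the
#' top feature scores 100. (Magnitudes are accumulated rather than signed
#' sums, which could cancel.)
#'
#' @param result an [run_rsscv()] result.
#' @param top_k how many features to list in the ranked report.
#' @return Object of class `importance_report`: data.frame with columns
#'   `index`, `name`, `selection_count`, `importance` (0-100 scale), plus
#'   attribute `top` (indices of the `top_k` highest-importance features).
#' @export
relative_importance <- function(result, top_k = 10) {
  stopifnot(inherits(result, "rsscv"))
  ok <- result$iterations$valid
  imp <- rowSums(abs(result$coef_std[, ok, drop = FALSE]))
  if (all(imp == 0))
    abort_protocol("all models empty: no nonzero coefficients")
  imp <- 100 * imp / max(imp)
  out <- data.frame(index = seq_along(imp), name = result$feature_names,
                    selection_count = as.integer(selection_frequency(result)),
                    importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  attr(out, "top") <- order(-out$importance)[seq_len(min(top_k, nrow(out)))]
  class(out) <- c("importance_report", "data.frame")
  out
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> top features by accumulated |coefficient|:\n")
  print.data.frame(x[attr(x, "top"), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.rsscv <- function(x, ...) {
  it <- x$iterations[x$iterations$valid, , drop = FALSE]
  cat(sprintf("<rsscv> %s, %d iterations (%d valid), seed %d\n",
              x$family, x$n_iter, x$n_valid, x$seed))
  if (x$family == "gaussian") {
    cat(sprintf("  test MAE  %.3f (SD %.3f)\n  test RMSE %.3f (SD %.3f)\n",
                mean(it$mae), stats::sd(it$mae),
                mean(it$rmse), stats::sd(it$rmse)))
  } else {
    cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
                mean(it$accuracy, na.rm = TRUE),
                mean(it$sensitivity, na.rm = TRUE),
                mean(it$specificity, na.rm = TRUE),
                mean(it$auc, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.rsscv <- function(object, top_k = 10, ...) {
  print(object)
  imp <- relative_importance(object, top_k)
  print(imp)
  invisible(imp)
}

#' @export
coef.rsscv <- function(object, ...) {
  ok <- object$iterations$valid
  rowMeans(object$coef_raw[, ok, drop = FALSE])
}

#' @export
plot.rsscv <- function(x, ...) {
  it <- x$iterations[x$iterations$valid, , drop = FALSE]
  if (x$family == "gaussian") {
    graphics::boxplot(list(MAE = it$mae, RMSE = it$rmse),
                      ylab = "test error (SFBBS points)",
                      main = "Random-shuffle-split test error", ...)
  } else {
    graphics::boxplot(list(AUC = it$auc, accuracy = it$accuracy),
                      ylab = "metric", main = "Per-iteration classification",
                      ...)
  }
  invisible(x)
}
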