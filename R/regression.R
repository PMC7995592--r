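#' Elastic-net specification
#'
#' The penalized least-squares objective is the Lagrangian form of the
#' mixed-norm constraint `(1 - alpha)/2 ||beta||_2^2 + alpha ||beta||_1 <=
#' t`: squared loss plus `lambda * ((1 - alpha)/2 ||beta||_2^2 +
#' alpha ||beta||_1)`. `alpha = 0` is ridge, `alpha = 1` is the lasso.
#'
#' @param alpha mixing weight in [0, 1].
#' @param lambda penalty strength, >= 0.
#' @param standardize standardize columns (mean 0, SD 1) inside the fitting
#'   routine; coefficients are always returned on the original scale.
#' @return Object of class `enet_spec`.
#' @export
enet_spec <- function(alpha = 0.5, lambda = 1, standardize = TRUE) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    abort_argument("alpha must lie in [0, 1]")
  if (!is.numeric(lambda) || lambda < 0)
    abort_argument("lambda must be >= 0")
  structure(list(alpha = alpha, lambda = lambda,
                 standardize = isTRUE(standardize)), class = "enet_spec")
}

# decreasing lambda path ending at the target value; glmnet solutions are
# more accurate when warm-started along a path than at a single lambda
lambda_path <- function(lambda, lam_max) {
  top <- max(lam_max, lambda * 10, 1e-3)
  if (lambda <= 0) c(exp(seq(log(top), log(top * 1e-6), length.out = 30)), 0)
  else exp(seq(log(top), log(lambda), length.out = 30))
}

#' Fit a penalized linear model
#'
#' Gaussian elastic net / ridge / lasso fit at a fixed `(alpha, lambda)`.
#' The solver is glmnet, driven along a warm-start path down to the target
#' lambda with a tight convergence threshold; coefficients are reported on
#' the original feature scale.
#'
#' @param X numeric n x p design matrix.
#' @param y numeric response of length n.
#' @param spec an [enet_spec()].
#' @return Object of class `enet_fit`: `intercept`, `coefficients` (named,
#'   original scale), `nonzero` (logical mask) and `spec`.
#' @export
fit_elastic_net <- function(X, y, spec = enet_spec()) {
  X <- as.matrix(X)
  stopifnot(inherits(spec, "enet_spec"))
  if (nrow(X) != length(y)) abort_argument("X and y sizes differ")
  if (anyNA(X) || anyNA(y)) abort_argument("X and y must be complete")
  if (spec$alpha == 0 && spec$lambda == 0 && qr(X)$rank < ncol(X))
    abort_numeric("rank-deficient design with no regularization")
  ymean <- mean(y)
  sds <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sds, 1e-12), "/")
  lam_max <- max(abs(crossprod(Xs, y - ymean))) / nrow(X) /
    max(spec$alpha, 1e-3)
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  fit <- glmnet::glmnet(X, y, alpha = spec$alpha,
                        lambda = lambda_path(spec$lambda, lam_max),
                        standardize = spec$standardize,
                        thresh = 1e-14, maxit = 1e7)
  cf <- as.numeric(stats::coef(fit, s = spec$lambda))
  beta <- cf[-1]
  names(beta) <- colnames(X)
  structure(list(intercept = cf[1], coefficients = beta,
                 nonzero = beta != 0, spec = spec),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("<enet_fit> alpha %.2f, lambda %.4g: %d of %d nonzero\n",
              x$spec$alpha, x$spec$lambda, sum(x$nonzero),
              length(x$coefficients)))
  invisible(x)
}

#' @export
coef.enet_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict from a fitted penalized linear model
#'
#' @param object an `enet_fit`.
#' @param newx matrix with the same columns as the training design.
#' @param ... unused.
#' @return Numeric predictions `intercept + newx %*% beta`.
#' @export
predict.enet_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$coefficients))
    abort_argument("newx has the wrong number of columns")
  as.numeric(object$intercept + newx %*% object$coefficients)
}

#' @rdname predict.enet_fit
#' @param model an `enet_fit`.
#' @export
predict_linear <- function(model, newx) predict.enet_fit(model, newx)

#' Prediction-error metrics
#'
#' Mean absolute error and root mean square error of predictions against
#' observations:
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((y - yhat)^2))`.
#'
#' @param y observed values.
#' @param y_hat predicted values, same length.
#' @return Object of class `eval_metrics`: `mae`, `rmse`, `n`.
#' @export
evaluate <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort_argument("length mismatch")
  if (length(y) < 1L) abort_argument("need at least one observation")
  e <- y - y_hat
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 n = length(y)), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n %d, MAE %.4g, RMSE %.4g\n",
              x$n, x$mae, x$rmse))
  invisible(x)
}
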