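test_that("ridge fit matches the closed form in the matched parameterization", {
  set.seed(11)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  y <- X[, 1] * 2 - X[, 3] + rnorm(n, 0, 0.5)
  lam <- 0.3

  fit <- fit_elastic_net(X, y, enet_spec(alpha = 0, lambda = lam,
                                         standardize = FALSE))
  # closed-form oracle: glmnet's gaussian loss is scaled by the population
  # SD of y, so its ridge solution solves (X'X + n lam / s_y I) b = X'y
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  s_y <- sqrt(mean(yc^2))
  beta_cf <- solve(crossprod(Xc) + n * lam / s_y * diag(p), crossprod(Xc, yc))
  expect_equal(unname(fit$coefficients), as.numeric(beta_cf),
               tolerance = 1e-6)
  expect_equal(fit$intercept,
               mean(y) - sum(colMeans(X) * beta_cf), tolerance = 1e-6)
})

test_that("lasso saturates above lambda_max and reduces to OLS at lambda 0", {
  set.seed(12)
  n <- 50; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 2] - 0.5 * X[, 5] + rnorm(n, 0, 0.3)

  # all coefficients zero above the max-gradient threshold
  big <- fit_elastic_net(X, y, enet_spec(alpha = 1, lambda = 10))
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(y), tolerance = 1e-8)

  # orthonormal columns, lambda 0: OLS by the normal equations
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  y2 <- Q %*% c(3, -1, 0.5, 0, 2, 0) + rnorm(n, 0, 0.1)
  ols <- fit_elastic_net(Q, as.numeric(y2),
                         enet_spec(alpha = 1, lambda = 0,
                                   standardize = FALSE))
  Qc <- scale(Q, center = TRUE, scale = FALSE)
  y2c <- y2 - mean(y2)
  beta_ols <- solve(crossprod(Qc), crossprod(Qc, y2c))
  expect_equal(unname(ols$coefficients), as.numeric(beta_ols),
               tolerance = 1e-6)

  # unpenalized rank-deficient design is rejected
  Xr <- cbind(X, X[, 1])
  expect_error(fit_elastic_net(Xr, y, enet_spec(alpha = 0, lambda = 0)),
               class = "tug_numeric_error")
})

test_that("linear prediction is the stated affine map", {
  set.seed(13)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  fit <- fit_elastic_net(X, y, enet_spec(alpha = 0.5, lambda = 0.05))
  Xn <- matrix(rnorm(10 * 5), 10, 5)
  expect_equal(predict(fit, Xn),
               as.numeric(fit$intercept + Xn %*% fit$coefficients),
               tolerance = 1e-12)
  expect_equal(predict_linear(fit, Xn), predict(fit, Xn))
  expect_error(predict(fit, Xn[, 1:3]), class = "tug_argument_error")

  # all-zero coefficients predict a constant
  sat <- fit_elastic_net(X, y, enet_spec(alpha = 1, lambda = 100))
  expect_equal(predict(sat, Xn), rep(sat$intercept, 10))
})

test_that("MAE and RMSE follow their definitions with RMSE >= MAE", {
  m0 <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$mae, 0); expect_equal(m0$rmse, 0)

  m <- evaluate(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))

  set.seed(14)
  for (i in 1:10) {
    y <- rnorm(30); yh <- rnorm(30)
    mm <- evaluate(y, yh)
    expect_gte(mm$rmse, mm$mae)
    expect_gte(mm$mae, 0)
  }
  expect_error(evaluate(1:3, 1:4), class = "tug_argument_error")
})

test_that("regression tree maximizes the sum-of-squares split gain", {
  # y perfectly separated by feature 1 at 0: pure leaves
  set.seed(15)
  x1 <- c(runif(15, -1, -0.1), runif(15, 0.1, 1))
  X <- cbind(x1, rnorm(30))
  y <- ifelse(x1 < 0, 1, 5)
  tree <- fit_regression_tree(X, y, min_leaf = 5, max_depth = 3)
  expect_false(tree$root$is_leaf)
  expect_equal(tree$root$feature, 1)
  expect_lt(abs(tree$root$threshold), 0.12)
  expect_equal(sort(unique(predict(tree, X))), c(1, 5))

  # constant response: a single leaf
  flat <- fit_regression_tree(X, rep(2, 30), min_leaf = 5)
  expect_true(flat$root$is_leaf)
  expect_equal(predict(flat, X), rep(2, 30))
})

test_that("tree root split equals exhaustive enumeration on random toys", {
  set.seed(16)
  for (i in 1:8) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    y <- X[, sample(3, 1)] * runif(1, 0.5, 2) + rnorm(30, 0, 0.5)
    tree <- fit_regression_tree(X, y, min_leaf = 5, max_depth = 1)
    oracle <- tree_split_oracle(X, y, min_leaf = 5)
    expect_equal(tree$root$feature, oracle$feature)
    expect_equal(tree$root$threshold, oracle$threshold)
    expect_equal(tree$root$gain, oracle$gain, tolerance = 1e-9)
    # chosen gain is positive and equals the between-groups sum of squares
    left <- X[, oracle$feature] <= oracle$threshold
    nl <- sum(left); nr <- sum(!left)
    bg <- nl * (mean(y[left]) - mean(y))^2 + nr * (mean(y[!left]) - mean(y))^2
    expect_equal(oracle$gain, bg, tolerance = 1e-9)
    expect_gt(oracle$gain, 0)
  }
})

test_that("tree training error never exceeds the single-leaf baseline", {
  set.seed(17)
  X <- matrix(rnorm(80 * 4), 80, 4)
  y <- X[, 1] + 0.5 * X[, 2]^2 + rnorm(80, 0, 0.2)
  tree <- fit_regression_tree(X, y, min_leaf = 5, max_depth = 4)
  sse <- sum((y - predict(tree, X))^2)
  expect_lte(sse, sum((y - mean(y))^2))
  expect_error(fit_regression_tree(X[1:6, ], y[1:6], min_leaf = 5),
               class = "tug_argument_error")
})

test_that("elastic-net penalty nests ridge and lasso coherently", {
  set.seed(18)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(1, -1, 0.5, 0, 0) + rnorm(n, 0, 0.3)
  y <- as.numeric(y)
  lam <- 0.2
  pen_loss <- function(fit, alpha) {
    r <- y - predict(fit, X)
    b <- fit$coefficients
    mean(r^2) / 2 + lam * ((1 - alpha) / 2 * sum(b^2) + alpha * sum(abs(b)))
  }
  f_r <- fit_elastic_net(X, y, enet_spec(0, lam, standardize = FALSE))
  f_m <- fit_elastic_net(X, y, enet_spec(0.5, lam, standardize = FALSE))
  f_l <- fit_elastic_net(X, y, enet_spec(1, lam, standardize = FALSE))
  # each fit minimizes its own objective: evaluating the mixed objective at
  # the pure-ridge and pure-lasso solutions can only do worse
  obj_mid <- pen_loss(f_m, 0.5)
  expect_lte(obj_mid, pen_loss(f_r, 0.5) + 1e-8)
  expect_lte(obj_mid, pen_loss(f_l, 0.5) + 1e-8)

  # coefficients shrink monotonically in lambda on an orthonormal design
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)
  yq <- as.numeric(Q %*% c(2, -1, 0.5, 0.2, 0) + rnorm(n, 0, 0.1))
  lams <- c(0.02, 0.1, 0.5)
  mags <- sapply(lams, function(l)
    abs(fit_elastic_net(Q, yq, enet_spec(1, l, standardize = FALSE))$coefficients))
  for (j in 1:p) expect_true(all(diff(mags[j, ]) <= 1e-8))
})
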