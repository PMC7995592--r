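#' Regression tree with sum-of-squares splitting
#'
#' Greedy recursive partitioning for a continuous response. Each split
#' maximizes the reduction in node sum of squares,
#' `SS_A - (SS_AL + SS_AR)` with `SS_A = sum((y_i - ybar)^2)`, over all
#' features and all thresholds (midpoints between sorted distinct values);
#' this gain equals the between-groups sum of squares of the induced
#' two-group ANOVA. Splitting stops at `min_leaf`, `max_depth` or zero
#' gain. Gain ties break toward the lower feature index, then the lower
#' threshold.
#'
#' @param X numeric n x p design matrix.
#' @param y numeric response of length n.
#' @param min_leaf minimum observations in any leaf.
#' @param max_depth maximum tree depth (root = depth 0).
#' @return Object of class `balance_tree`. Nodes are nested lists with
#'   either `split` (`feature`, `threshold`, `gain`, children `left`,
#'   `right`; rows with `x[feature] <= threshold` go left) or a leaf mean
#'   `value`; every node carries `n` and its sum of squares `ss`.
#' @export
fit_regression_tree <- function(X, y, min_leaf = 5, max_depth = 5) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) abort_argument("X and y sizes differ")
  if (nrow(X) < 2 * min_leaf)
    abort_argument("need at least 2 * min_leaf observations")
  node <- grow_node(X, y, min_leaf, max_depth, depth = 0L)
  structure(list(root = node, min_leaf = min_leaf, max_depth = max_depth,
                 feature_names = colnames(X)),
            class = "balance_tree")
}

node_ss <- function(y) sum((y - mean(y))^2)

# best (feature, threshold) by SS gain; NULL when no admissible positive-gain
# split exists
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  ss_a <- node_ss(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    csum <- cumsum(ys); csq <- cumsum(ys^2)
    tot <- csum[n]; totsq <- csq[n]
    # candidate split after position i (left = 1..i) where the value changes
    for (i in seq_len(n - 1L)) {
      if (xs[i] == xs[i + 1L]) next
      if (i < min_leaf || n - i < min_leaf) next
      ss_l <- csq[i] - csum[i]^2 / i
      ss_r <- (totsq - csq[i]) - (tot - csum[i])^2 / (n - i)
      gain <- ss_a - (ss_l + ss_r)
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = j, threshold = (xs[i] + xs[i + 1L]) / 2,
                     gain = gain)
      }
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

grow_node <- function(X, y, min_leaf, max_depth, depth) {
  base <- list(n = length(y), value = mean(y), ss = node_ss(y))
  if (depth >= max_depth || length(y) < 2 * min_leaf)
    return(c(base, list(is_leaf = TRUE)))
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp)) return(c(base, list(is_leaf = TRUE)))
  left <- X[, sp$feature] <= sp$threshold
  c(base, list(is_leaf = FALSE, feature = sp$feature,
               threshold = sp$threshold, gain = sp$gain,
               left = grow_node(X[left, , drop = FALSE], y[left],
                                min_leaf, max_depth, depth + 1L),
               right = grow_node(X[!left, , drop = FALSE], y[!left],
                                 min_leaf, max_depth, depth + 1L)))
}

#' @export
#' @rdname fit_regression_tree
#' @param object a `balance_tree`.
#' @param newx matrix with the same columns as the training design.
#' @param ... unused.
predict.balance_tree <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  apply(newx, 1, function(row) {
    node <- object$root
    while (!node$is_leaf)
      node <- if (row[node$feature] <= node$threshold) node$left
              else node$right
    node$value
  })
}

tree_depth <- function(node) {
  if (node$is_leaf) 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.balance_tree <- function(x, ...) {
  count_leaves <- function(node)
    if (node$is_leaf) 1L else count_leaves(node$left) + count_leaves(node$right)
  cat(sprintf("<balance_tree> %d leaves, depth %d, root n = %d\n",
              count_leaves(x$root), tree_depth(x$root), x$root$n))
  invisible(x)
}
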