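# Shared fixtures and independent oracles for the suite.

# rotation-matrix oracle: pitch about ML then roll about AP, in degrees;
# built directly from the elementary rotation matrices, independent of the
# package's tilt estimation
rot_pitch_roll <- function(pitch_deg, roll_deg) {
  th <- pitch_deg * pi / 180
  ph <- roll_deg * pi / 180
  Rp <- rbind(c(cos(th), 0, sin(th)),
              c(0, 1, 0),
              c(-sin(th), 0, cos(th)))
  Rr <- rbind(c(cos(ph), sin(ph), 0),
              c(-sin(ph), cos(ph), 0),
              c(0, 0, 1))
  Rr %*% Rp
}

# gravity-aligned quiet-sitting recording (V = 1 g) with tiny noise
still_recording <- function(n_s = 4, rate = 45, noise = 0.001, seed = 1) {
  set.seed(seed)
  n <- n_s * rate
  tug_recording(cbind(1 + rnorm(n, 0, noise),
                      rnorm(n, 0, noise),
                      rnorm(n, 0, noise)), rate)
}

# brute-force centered moving average with truncated edges
ma_oracle <- function(x, w) {
  h <- floor(w / 2)
  n <- length(x)
  sapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]))
}

# O(n^2) Mann-Whitney concordance with ties counted 1/2
mw_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive best regression-tree split: all features, all midpoints,
# same tie-breaking contract (lower feature index, then lower threshold)
tree_split_oracle <- function(X, y, min_leaf) {
  ss <- function(v) sum((v - mean(v))^2)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (th in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- X[, j] <= th
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- ss(y) - (ss(y[left]) + ss(y[!left]))
      if (is.null(best) || gain > best$gain + 1e-12)
        best <- list(feature = j, threshold = th, gain = gain)
    }
  }
  best
}

# default simulated recording, calibrated, with its ground truth
sim_calibrated <- function(seed = 1, ...) {
  sim <- simulate_recording(sim_config(seed = seed, ...))
  rec <- calibrate(sim$recording,
                   still_window = c(0, sim$truth$config$rest_pre * 0.9))
  list(rec = rec, truth = sim$truth)
}

# small cohort feature table for protocol tests (cached per session)
cached_cohort_features <- local({
  cache <- NULL
  function(n = 60, seed = 11) {
    key <- paste(n, seed)
    if (!is.null(cache) && cache$key == key) return(cache$val)
    cohort <- simulate_cohort(cohort_config(n = n, seed = seed))
    feats <- extract_cohort_features(cohort$participants,
                                     still_window = c(0, 1.8))
    cache <<- list(key = key, val = list(features = feats, cohort = cohort))
    cache$val
  }
})
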