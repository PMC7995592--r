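#' Registry of the 67 TUG features
#'
#' Canonical bijection between feature indices 1..67 and names, grouped by
#' task: overall TUG duration (1); sit-to-stand amplitude, jerk and duration
#' (2-23); walking amplitude, spatial, temporal and frequency features
#' (24-42); stand-to-sit amplitude, jerk and duration (43-64); the SD of the
#' two transition durations (65); and demographics (66-67). Per-axis
#' features are always in V, ML, AP order.
#'
#' @return A data.frame with columns `index` and `name`.
#' @export
feature_registry <- function() {
  ax <- c("v", "ml", "ap")
  nm <- c(
    "tug_duration",
    paste0("sist_max_", ax), paste0("sist_min_", ax),
    paste0("sist_range_", ax), paste0("sist_rms_", ax),
    paste0("sist_max_jerk_", ax), paste0("sist_mean_jerk_", ax),
    paste0("sist_delta_jerk_", ax),
    "sist_duration",
    paste0("walk_rms_", ax),
    "walk_step_length_m", "walk_cadence", "walk_gait_speed",
    "walk_step_time", "walk_stride_time",
    "walk_cv_step_time", "walk_cv_stride_time",
    paste0("walk_fft_dominant_", ax), paste0("walk_fft_first_quartile_", ax),
    paste0("walk_reoh_", ax),
    paste0("stsi_max_", ax), paste0("stsi_min_", ax),
    paste0("stsi_range_", ax), paste0("stsi_rms_", ax),
    paste0("stsi_max_jerk_", ax), paste0("stsi_mean_jerk_", ax),
    paste0("stsi_delta_jerk_", ax),
    "stsi_duration", "transition_duration_sd",
    "age", "gender")
  data.frame(index = seq_along(nm), name = nm, stringsAsFactors = FALSE)
}

#' Amplitude descriptive statistics of a signal segment
#'
#' @param segment numeric series (one axis, one phase).
#' @return Named list `max`, `min`, `range` (= max - min) and `rms`
#'   (root-mean-square).
#' @export
amplitude_stats <- function(segment) {
  if (length(segment) == 0L) abort_argument("empty segment")
  mx <- max(segment); mn <- min(segment)
  list(max = mx, min = mn, range = mx - mn,
       rms = sqrt(mean(segment^2)))
}

#' Split a postural transition into its two biomechanical parts
#'
#' A sit-to-stand transition divides into trunk lean (part 1) and active
#' rise (part 2); a stand-to-sit into controlled lowering and final
#' descent. The split point is the interior extremum of opposite sign to
#' the hill apex, searched between the phase boundary and the apex; when no
#' opposite-sign extremum exists the segment midpoint is used.
#'
#' @param segment one-axis series over the transition (half-open phase).
#' @param kind `"sist"` (apex at the segment end) or `"stsi"` (apex at the
#'   start).
#' @param rate sampling frequency in Hz.
#' @return Strictly interior 1-based split index: part 1 is
#'   `[1, split)`, part 2 `[split, n]`.
#' @export
split_transition <- function(segment, kind = c("sist", "stsi"), rate) {
  kind <- match.arg(kind)
  n <- length(segment)
  if (n < 0.4 * rate) abort_argument("transition segment shorter than 0.4 s")
  apex <- if (kind == "sist") which.max(segment) else which.max(segment)
  search <- if (kind == "sist") seq_len(max(apex - 1L, 0L))
            else if (apex < n) seq(apex + 1L, n) else integer()
  split <- NA_integer_
  if (length(search) > 1L) {
    cand <- search[which.min(segment[search])]
    opposite <- sign(segment[cand]) != sign(segment[apex]) &&
      segment[cand] != 0
    interior <- cand > 1L && cand < n
    # an endpoint minimum is a boundary, not a turning point
    at_turn <- cand != search[1L] && cand != search[length(search)]
    if (opposite && interior && at_turn) split <- cand
  }
  if (is.na(split)) split <- max(2L, min(n - 1L, floor(n / 2)))
  split
}

#' Jerk features of a two-part postural transition
#'
#' Jerk is the rate of change of acceleration; here each part's jerk is the
#' least-squares slope (in g/s) of a linear fit of acceleration on time
#' over that part.
#'
#' @param segment one-axis series over the transition.
#' @param split interior split index from [split_transition()]; part 1 is
#'   samples `[1, split)`, part 2 `[split, n]`.
#' @param rate sampling frequency in Hz.
#' @return Named list `max_jerk` (= max of the two slopes), `mean_jerk`
#'   (their mean) and `delta_jerk` (part 2 minus part 1).
#' @export
jerk_features <- function(segment, split, rate) {
  n <- length(segment)
  if (split < 4L || n - split + 1L < 3L)
    abort_argument("both transition parts need at least 3 samples")
  slope <- function(y) {
    t <- (seq_along(y) - 1) / rate
    vt <- stats::var(t)
    if (vt == 0) abort_numeric("degenerate part in jerk fit")
    stats::cov(t, y) / vt
  }
  j1 <- slope(segment[seq_len(split - 1L)])
  j2 <- slope(segment[seq(split, n)])
  list(max_jerk = max(j1, j2), mean_jerk = (j1 + j2) / 2,
       delta_jerk = j2 - j1)
}

#' Detect step events from the vertical axis during walking
#'
#' Each vertical-acceleration peak is one step event. Peaks must exceed an
#' adaptive prominence threshold (a fraction of the segment's peak-to-peak
#' amplitude) and be separated by at least `min_step_interval` seconds.
#'
#' @param v_walk vertical-axis series over the walking phase (mean need not
#'   be removed; it is removed internally).
#' @param rate sampling frequency in Hz.
#' @param min_step_interval minimum separation of step events, s.
#' @param prom_frac prominence threshold as a fraction of peak-to-peak
#'   amplitude.
#' @return Object of class `step_series`: `events` (times in s from the
#'   start of the segment, strictly increasing), `step_times` (successive
#'   differences) and `stride_times` (lag-2 differences).
#' @export
detect_steps <- function(v_walk, rate, min_step_interval = 0.3,
                         prom_frac = 0.25) {
  if (length(v_walk) < rate) abort_argument("walking segment shorter than 1 s")
  x <- v_walk - mean(v_walk)
  ptp <- max(x) - min(x)
  peaks <- local_maxima(x)
  if (length(peaks) < 2L)
    abort_step("fewer than two step events detected")
  prom <- peak_prominence(x, peaks)
  keep <- prom >= prom_frac * ptp
  peaks <- peaks[keep]; prom <- prom[keep]
  # greedy acceptance in prominence order enforcing the refractory spacing
  accepted <- integer()
  for (i in order(-prom, peaks)) {
    p <- peaks[i]
    if (all(abs(accepted - p) >= min_step_interval * rate))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  if (length(accepted) < 2L)
    abort_step("fewer than two step events detected")
  step_series((accepted - 1L) / rate)
}

#' @rdname detect_steps
#' @param event_times strictly increasing step-event times in s.
#' @export
step_series <- function(event_times) {
  if (any(diff(event_times) <= 0))
    abort_argument("step event times must be strictly increasing")
  structure(list(events = event_times,
                 step_times = diff(event_times),
                 stride_times = if (length(event_times) >= 3L)
                   diff(event_times, lag = 2L) else numeric()),
            class = "step_series")
}

#' Spatiotemporal gait features of the walking phase
#'
#' Step length divides the walked path length by the number of steps;
#' cadence is 60 times the number of steps over the walking duration (in
#' steps/min); gait speed divides path length by walking duration. Step and
#' stride time coefficients of variation (CV = sample SD / mean) quantify
#' gait variability and require at least 4 step events; otherwise they are
#' returned as `NA` (missing, to be imputed by the modelling protocol).
#'
#' @param steps a [step_series()].
#' @param walk_duration walking-phase duration in s.
#' @param path_length walked distance in m (3 m out + 3 m back = 6 m).
#' @return Named list `step_length`, `cadence`, `gait_speed`,
#'   `mean_step_time`, `mean_stride_time`, `cv_step`, `cv_stride`.
#' @export
gait_spatiotemporal <- function(steps, walk_duration, path_length = 6) {
  stopifnot(inherits(steps, "step_series"))
  n_steps <- length(steps$events)
  if (n_steps < 2L) abort_argument("need at least 2 step events")
  if (walk_duration <= 0) abort_argument("walk_duration must be positive")
  enough <- n_steps >= 4L
  cv <- function(x) if (enough && mean(x) > 0) stats::sd(x) / mean(x)
                    else NA_real_
  list(step_length = path_length / n_steps,
       cadence = 60 * n_steps / walk_duration,
       gait_speed = path_length / walk_duration,
       mean_step_time = mean(steps$step_times),
       mean_stride_time = if (length(steps$stride_times))
         mean(steps$stride_times) else NA_real_,
       cv_step = cv(steps$step_times),
       cv_stride = if (length(steps$stride_times) >= 2L)
         cv(steps$stride_times) else NA_real_)
}

# one-sided magnitude spectrum, DC excluded, frequencies up to Nyquist
spectrum_bins <- function(x, rate) {
  n <- length(x)
  mag <- Mod(stats::fft(x - mean(x)))
  k <- seq(2L, floor(n / 2) + 1L)
  list(freq = (k - 1) * rate / n, mag = mag[k])
}

#' Dominant FFT frequency of a segment
#'
#' The non-DC frequency bin (up to Nyquist) with maximal spectral
#' magnitude, after mean removal.
#'
#' @param segment one-axis series, at least 2 s long.
#' @param rate sampling frequency in Hz.
#' @return Frequency in Hz.
#' @export
fft_dominant <- function(segment, rate) {
  if (length(segment) < 2 * rate) abort_argument("segment shorter than 2 s")
  sp <- spectrum_bins(segment, rate)
  if (all(sp$mag < 1e-12)) abort_numeric("flat segment has no spectrum")
  sp$freq[which.max(sp$mag)]
}

#' Spectral mass in the first quartile of the frequency range
#'
#' Percentage of total spectral magnitude (DC excluded) lying at
#' frequencies at or below one quarter of the Nyquist frequency. Lower
#' values have been linked to instability.
#'
#' @inheritParams fft_dominant
#' @return Percentage in [0, 100].
#' @export
fft_first_quartile <- function(segment, rate) {
  if (length(segment) < 2 * rate) abort_argument("segment shorter than 2 s")
  sp <- spectrum_bins(segment, rate)
  tot <- sum(sp$mag)
  if (tot < 1e-12) abort_numeric("flat segment has no spectrum")
  100 * sum(sp$mag[sp$freq <= rate / 8]) / tot
}

#' Ratio of even to odd harmonics (REOH)
#'
#' The ratio of summed spectral magnitudes at even versus odd multiples of
#' the stride frequency, reflecting the portion of the acceleration signal
#' in phase with the stride; low values indicate step-to-step asymmetry.
#' Harmonics 1..2*n_harmonics are used, each magnitude read at the nearest
#' FFT bin; harmonics at or above Nyquist are dropped.
#'
#' @param segment one-axis series.
#' @param rate sampling frequency in Hz.
#' @param stride_freq stride frequency in Hz (typically 1 / mean stride
#'   time).
#' @param n_harmonics number of even (and odd) harmonics, default 10.
#' @return Non-negative ratio (denominator guarded by machine epsilon).
#' @export
reoh <- function(segment, rate, stride_freq, n_harmonics = 10) {
  n <- length(segment)
  if (!is.finite(stride_freq) || stride_freq <= 0)
    abort_argument("stride_freq must be positive")
  if (stride_freq < rate / n)
    abort_argument("stride frequency unresolvable at this segment length")
  harm <- seq_len(2L * n_harmonics)
  harm <- harm[harm * stride_freq < rate / 2]
  if (length(harm) < 2L)
    abort_argument("too few resolvable harmonics below Nyquist")
  mag <- Mod(stats::fft(segment - mean(segment)))
  bin <- pmax(2L, pmin(round(harm * stride_freq * n / rate) + 1L,
                       floor(n / 2) + 1L))
  m <- mag[bin]
  even <- sum(m[harm %% 2L == 0L])
  odd <- sum(m[harm %% 2L == 1L])
  even / max(odd, .Machine$double.eps)
}

#' Feature-extraction configuration
#'
#' @param path_length walked distance in m (default 6: 3 m out + 3 m back).
#' @param subtract_gravity mean-subtract the vertical axis within the
#'   walking segment before RMS, FFT and step detection (default TRUE).
#' @param min_step_interval,prom_frac step-detection parameters, see
#'   [detect_steps()].
#' @param n_harmonics REOH harmonic count, see [reoh()].
#' @return Named list of parameters for [extract_features()].
#' @export
feature_config <- function(path_length = 6, subtract_gravity = TRUE,
                           min_step_interval = 0.3, prom_frac = 0.25,
                           n_harmonics = 10) {
  list(path_length = path_length, subtract_gravity = subtract_gravity,
       min_step_interval = min_step_interval, prom_frac = prom_frac,
       n_harmonics = n_harmonics)
}

# NA on failure of an optional sub-feature; never silently zero
try_feature <- function(expr) {
  tryCatch(expr, tug_error = function(e) NA_real_)
}

#' Extract the 67-feature vector for one participant
#'
#' Computes every feature of the registry from a calibrated, segmented
#' recording plus demographics. Sub-features that cannot be computed (for
#' example gait-variability CVs when too few steps are detected) are
#' recorded as `NA`, to be mean-imputed within training folds by the
#' cross-validation protocol — never silently zero.
#'
#' @param participant a [participant_record()] with a calibrated recording.
#' @param seg a [tug_segmentation()] of that recording.
#' @param config list from [feature_config()].
#' @return Object of class `tug_features`: a named numeric vector of length
#'   67 (names per [feature_registry()]).
#' @export
extract_features <- function(participant, seg, config = feature_config()) {
  stopifnot(inherits(participant, "participant_record"),
            inherits(seg, "tug_segmentation"))
  rec <- participant$recording
  if (!rec$calibrated) abort_argument("recording must be calibrated")
  rate <- rec$rate
  S <- rec$samples
  sist <- S[seq(seg$p1, seg$p2 - 1L), , drop = FALSE]
  walk <- S[seq(seg$p2, seg$p3 - 1L), , drop = FALSE]
  stsi <- S[seq(seg$p3, seg$p4 - 1L), , drop = FALSE]

  out <- stats::setNames(rep(NA_real_, 67), feature_registry()$name)
  out["tug_duration"] <- seg$durations$tug

  transition_block <- function(seg_mat, kind, prefix) {
    for (a in c("v", "ml", "ap")) {
      x <- seg_mat[, a]
      st <- amplitude_stats(x)
      out[paste0(prefix, "_max_", a)] <<- st$max
      out[paste0(prefix, "_min_", a)] <<- st$min
      out[paste0(prefix, "_range_", a)] <<- st$range
      out[paste0(prefix, "_rms_", a)] <<- st$rms
      jk <- try_feature({
        sp <- split_transition(x, kind, rate)
        jerk_features(x, sp, rate)
      })
      if (!is.list(jk)) jk <- list(max_jerk = NA_real_, mean_jerk = NA_real_,
                                   delta_jerk = NA_real_)
      out[paste0(prefix, "_max_jerk_", a)] <<- jk$max_jerk
      out[paste0(prefix, "_mean_jerk_", a)] <<- jk$mean_jerk
      out[paste0(prefix, "_delta_jerk_", a)] <<- jk$delta_jerk
    }
  }
  transition_block(sist, "sist", "sist")
  transition_block(stsi, "stsi", "stsi")
  out["sist_duration"] <- seg$durations$sist
  out["stsi_duration"] <- seg$durations$stsi
  # population SD of the two transition durations: |a - b| / 2
  out["transition_duration_sd"] <-
    abs(seg$durations$sist - seg$durations$stsi) / 2

  wv <- if (isTRUE(config$subtract_gravity)) walk[, "v"] - mean(walk[, "v"])
        else walk[, "v"]
  walk_axes <- list(v = wv, ml = walk[, "ml"], ap = walk[, "ap"])
  for (a in c("v", "ml", "ap")) {
    out[paste0("walk_rms_", a)] <- sqrt(mean(walk_axes[[a]]^2))
    out[paste0("walk_fft_dominant_", a)] <-
      try_feature(fft_dominant(walk_axes[[a]], rate))
    out[paste0("walk_fft_first_quartile_", a)] <-
      try_feature(fft_first_quartile(walk_axes[[a]], rate))
  }

  steps <- try_feature(detect_steps(wv, rate, config$min_step_interval,
                                    config$prom_frac))
  if (inherits(steps, "step_series")) {
    g <- gait_spatiotemporal(steps, seg$durations$walk, config$path_length)
    out["walk_step_length_m"] <- g$step_length
    out["walk_cadence"] <- g$cadence
    out["walk_gait_speed"] <- g$gait_speed
    out["walk_step_time"] <- g$mean_step_time
    out["walk_stride_time"] <- g$mean_stride_time
    out["walk_cv_step_time"] <- g$cv_step
    out["walk_cv_stride_time"] <- g$cv_stride
    stride_freq <- if (is.finite(g$mean_stride_time) && g$mean_stride_time > 0)
      1 / g$mean_stride_time else NA_real_
    if (is.finite(stride_freq)) {
      for (a in c("v", "ml", "ap"))
        out[paste0("walk_reoh_", a)] <-
          try_feature(reoh(walk_axes[[a]], rate, stride_freq,
                           config$n_harmonics))
    }
  } else {
    # gait speed needs no step events
    out["walk_gait_speed"] <- config$path_length / seg$durations$walk
  }

  out["age"] <- participant$age
  out["gender"] <- participant$gender
  structure(out, class = "tug_features")
}

#' @export
print.tug_features <- function(x, ...) {
  cat(sprintf("<tug_features> %d features (%d missing)\n",
              length(x), sum(is.na(x))))
  print(unclass(x), ...)
  invisible(x)
}

#' Extract a feature table for a cohort
#'
#' Runs calibrate / segment / extract for each participant and assembles a
#' one-row-per-participant feature table. Per-participant failures are
#' caught and reported in the `failures` attribute rather than aborting the
#' whole cohort.
#'
#' @param participants list of [participant_record()]s (recordings may be
#'   uncalibrated; each is calibrated against `still_window`).
#' @param still_window still-sitting window passed to [calibrate()].
#' @param params segmentation parameters, see [seg_params()].
#' @param config feature configuration, see [feature_config()].
#' @return data.frame with `id`, the 67 feature columns, and, when SFBBS
#'   scores are present, `sfbbs_total` and `sfbbs_item1..7`; attribute
#'   `failures` names participants that could not be processed.
#' @export
extract_cohort_features <- function(participants, still_window = c(0, 1),
                                    params = seg_params(),
                                    config = feature_config()) {
  rows <- list(); fails <- character()
  for (p in participants) {
    res <- tryCatch({
      rec <- if (p$recording$calibrated) p$recording
             else calibrate(p$recording, still_window)
      pc <- p; pc$recording <- rec
      seg <- segment_tug(rec, params)
      fv <- extract_features(pc, seg, config)
      row <- as.data.frame(as.list(unclass(fv)))
      row <- cbind(data.frame(id = p$id, stringsAsFactors = FALSE), row)
      if (!is.null(p$sfbbs)) {
        row$sfbbs_total <- p$sfbbs$total
        for (j in 1:7) row[[paste0("sfbbs_item", j)]] <- p$sfbbs$items[j]
      }
      row
    }, tug_error = function(e) {
      fails <<- c(fails, stats::setNames(conditionMessage(e), p$id))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- fails
  out
}
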