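#' Centered moving-average smoothing of the AP axis
#'
#' Pre-conditioning for peak detection: removes step-frequency ripple while
#' preserving the sub-1-Hz postural-transition hills. Edge samples use
#' truncated windows, so the output has the same length as the input.
#'
#' @param x numeric series.
#' @param window window length in seconds.
#' @param rate sampling frequency in Hz.
#' @return Smoothed series of the same length.
#' @export
smooth_ap <- function(x, window = 0.25, rate) {
  n <- length(x)
  w <- max(2L, round(window * rate))
  if (w > n) abort_argument("smoothing window longer than series")
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict local maxima (first sample of any plateau).
local_maxima <- function(x) {
  if (length(x) < 3L) return(integer())
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
}

# Topographic prominence of each peak: height above the higher of the two
# key saddles found walking out to the nearest higher terrain (or the ends).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(p - 1L)])
              else min(left, h)
    right <- x[seq((p + 1L), length(x))]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
              else min(right, h)
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Locate the two hills of the "M"-shaped AP signal
#'
#' During a TUG test the anterior-posterior axis traces an "M": a first hill
#' at the sit-to-stand transition and a second at stand-to-sit. The two
#' M-like maxima (landmark points 2 and 3) are taken as the two most
#' prominent local maxima of the smoothed AP series that are separated by
#' at least `min_separation` seconds; height ties break toward earlier
#' time.
#'
#' @param ap_smooth smoothed AP series (see [smooth_ap()]).
#' @param rate sampling frequency in Hz.
#' @param min_separation minimum peak separation in seconds; the default
#'   3 s is below any plausible 6 m walk time.
#' @return Integer vector `c(p2, p3)` of 1-based sample indices, time
#'   ordered.
#' @export
detect_m_peaks <- function(ap_smooth, rate, min_separation = 3) {
  if (length(ap_smooth) < min_separation * rate)
    abort_argument("series shorter than min_separation")
  peaks <- local_maxima(ap_smooth)
  if (length(peaks) < 2L)
    abort_segmentation("fewer than two local maxima in AP signal")
  prom <- peak_prominence(ap_smooth, peaks)
  ord <- order(-prom, peaks)            # prominence desc, earlier time first
  first <- peaks[ord[1L]]
  rest <- ord[-1L]
  ok <- rest[abs(peaks[rest] - first) >= min_separation * rate]
  if (length(ok) == 0L)
    abort_segmentation("no second peak at the required separation")
  second <- peaks[ok[1L]]
  sort(c(first, second))
}

#' Locate the steady-state boundaries of the TUG (landmarks 1 and 4)
#'
#' Landmark 1 is the time the AP signal starts to rise from steady state
#' before the first M peak; landmark 4 is the time it settles back to
#' steady state after the second peak. "Steady state" is a band
#' `baseline mean +/- k * baseline SD` estimated from the initial rest
#' segment; landmark 4 additionally requires the signal to dwell inside the
#' band for at least `dwell` seconds.
#'
#' @param ap_smooth smoothed AP series.
#' @param p2,p3 indices of the two M peaks (see [detect_m_peaks()]).
#' @param rate sampling frequency in Hz.
#' @param k band half-width in baseline SDs (default 3).
#' @param baseline_window length in seconds of the initial rest segment used
#'   to estimate the baseline (default 1 s).
#' @param dwell minimum duration in seconds of an out-of-band run for it to
#'   count as a departure from steady state; shorter excursions are treated
#'   as noise. Landmark 1 is the last in-band sample before the first
#'   sustained departure preceding the first peak; landmark 4 is the first
#'   in-band sample after the last sustained departure following the second
#'   peak (so the signal then stays in the band for at least `dwell`).
#' @param baseline_sd optional noise SD of `ap_smooth` to use for the band.
#'   By default it is estimated from the smoothed baseline segment, which
#'   is fine for clean fixtures; [segment_tug()] estimates it from the raw
#'   AP baseline scaled by the moving-average noise reduction, which is
#'   robust to the sample correlation smoothing introduces.
#' @return Integer vector `c(p1, p4)` of 1-based sample indices.
#' @export
detect_phase_bounds <- function(ap_smooth, p2, p3, rate, k = 3,
                                baseline_window = 1, dwell = 0.5,
                                baseline_sd = NULL) {
  n <- length(ap_smooth)
  if (!(p2 < p3)) abort_argument("p2 must precede p3")
  if (p2 <= rate || n - p3 < rate)
    abort_argument("need at least 1 s of signal before p2 and after p3")
  nb <- max(2L, round(baseline_window * rate))
  base <- ap_smooth[seq_len(nb)]
  mu <- mean(base)
  if (is.null(baseline_sd)) baseline_sd <- stats::sd(base)
  half <- k * baseline_sd + 1e-12
  in_band <- abs(ap_smooth - mu) <= half
  need <- max(1L, round(dwell * rate))

  # steady state is interrupted only by *sustained* (>= dwell) out-of-band
  # runs; shorter excursions are noise and stay part of the steady state
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dep <- which(!r$values & r$lengths >= need)
  dep_starts <- starts[dep]
  dep_ends <- ends[dep]

  before <- which(dep_starts <= p2)
  if (length(before) == 0L || dep_starts[min(before)] == 1L)
    abort_segmentation("no steady state found before the first peak")
  p1 <- dep_starts[min(before)] - 1L

  after <- which(dep_ends > p3)
  if (length(after) == 0L || dep_ends[max(after)] >= n)
    abort_segmentation("signal never re-enters steady state after second peak")
  p4 <- dep_ends[max(after)] + 1L
  c(p1, p4)
}

#' Segmentation parameters
#'
#' @param smooth_window AP smoothing window, s.
#' @param min_peak_sep minimum separation of the two M peaks, s.
#' @param band_k steady-state band half-width in baseline SDs.
#' @param baseline_window rest segment used for the baseline, s.
#' @param dwell dwell requirement for landmark 4, s.
#' @return A named list of parameters for [segment_tug()].
#' @export
seg_params <- function(smooth_window = 0.25, min_peak_sep = 3, band_k = 3,
                       baseline_window = 1, dwell = 0.5) {
  list(smooth_window = smooth_window, min_peak_sep = min_peak_sep,
       band_k = band_k, baseline_window = baseline_window, dwell = dwell)
}

#' Segment a calibrated TUG recording into transition and walking phases
#'
#' Detects the four landmark points on the AP axis and partitions the
#' recording into half-open phases: sit-to-stand `[p1, p2)`, walking
#' `[p2, p3)` and stand-to-sit `[p3, p4)`. Indices are 1-based; durations
#' are `(end - start) / rate`, so the three phase durations sum exactly to
#' the TUG duration.
#'
#' @param rec a calibrated [tug_recording()].
#' @param params list from [seg_params()].
#' @return Object of class `tug_segmentation`: landmarks `p1..p4`,
#'   `durations` (named list `tug`, `sist`, `walk`, `stsi` in s) and `rate`.
#' @export
segment_tug <- function(rec, params = seg_params()) {
  stopifnot(inherits(rec, "tug_recording"))
  if (!rec$calibrated)
    abort_argument("recording must be calibrated before segmentation")
  ap <- rec$samples[, "ap"]
  sm <- smooth_ap(ap, params$smooth_window, rec$rate)
  pk <- detect_m_peaks(sm, rec$rate, params$min_peak_sep)
  # band noise level: raw baseline SD reduced by the w-sample moving average
  w <- max(2L, round(params$smooth_window * rec$rate))
  nb <- max(2L, round(params$baseline_window * rec$rate))
  sd_sm <- stats::sd(ap[seq_len(nb)]) / sqrt(w)
  bd <- detect_phase_bounds(sm, pk[1], pk[2], rec$rate, params$band_k,
                            params$baseline_window, params$dwell,
                            baseline_sd = sd_sm)
  tug_segmentation(bd[1], pk[1], pk[2], bd[2], rec$rate,
                   n = nrow(rec$samples))
}

#' @rdname segment_tug
#' @param p1,p2,p3,p4 landmark sample indices (1-based).
#' @param rate sampling frequency in Hz.
#' @param n number of samples in the recording (for validation).
#' @export
tug_segmentation <- function(p1, p2, p3, p4, rate, n = Inf) {
  p <- c(p1, p2, p3, p4)
  if (any(p < 1) || any(diff(p) <= 0) || p4 > n + 1)
    abort_segmentation("landmarks must satisfy 1 <= p1 < p2 < p3 < p4 <= n")
  durations <- list(tug = (p4 - p1) / rate, sist = (p2 - p1) / rate,
                    walk = (p3 - p2) / rate, stsi = (p4 - p3) / rate)
  if (min(durations$sist, durations$walk, durations$stsi) <= 0.2)
    abort_segmentation("a detected phase is implausibly short (<= 0.2 s)")
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, rate = rate,
                 durations = durations),
            class = "tug_segmentation")
}

#' @export
print.tug_segmentation <- function(x, ...) {
  d <- x$durations
  cat(sprintf(paste0("<tug_segmentation> landmarks %d/%d/%d/%d @ %.4g Hz\n",
                     "  TUG %.2f s = SiSt %.2f + walk %.2f + StSi %.2f\n"),
              x$p1, x$p2, x$p3, x$p4, x$rate,
              d$tug, d$sist, d$walk, d$stsi))
  invisible(x)
}

#' Serialize a segmentation to JSON
#'
#' @param seg a `tug_segmentation`.
#' @return A JSON string with the landmarks and phase durations.
#' @export
segmentation_json <- function(seg) {
  stopifnot(inherits(seg, "tug_segmentation"))
  jsonlite::toJSON(list(p1 = seg$p1, p2 = seg$p2, p3 = seg$p3, p4 = seg$p4,
                        durations_s = seg$durations),
                   auto_unbox = TRUE, digits = NA)
}
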