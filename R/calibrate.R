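#' Tilt-calibrate a recording into the horizontal-vertical frame
#'
#' Estimates sensor tilt from the mean acceleration vector over a still
#' (quiet sitting) window and applies the rigid rotation that maps that mean
#' onto the vertical axis, so gravity rests entirely on V. This reproduces
#' the classic trunk-accelerometry tilt correction for the quasi-static case
#' of a seated start: a pitch rotation (V-AP plane) followed by a roll
#' rotation (V-ML plane).
#'
#' The rotation is rigid, so per-sample vector norms are preserved, and the
#' operation is idempotent: calibrating an already-calibrated recording is a
#' no-op up to numerical noise.
#'
#' @param rec a [tug_recording()].
#' @param still_window half-open time interval `c(start_s, end_s)` of quiet
#'   sitting used to estimate the gravity direction.
#' @param max_still_sd staticness guard: per-axis standard deviation over
#'   the still window must be below this value (g). Default 0.05 g
#'   separates quiet sitting from movement at 45 Hz.
#' @return A calibrated [tug_recording()].
#' @export
calibrate <- function(rec, still_window = c(0, 1), max_still_sd = 0.05) {
  stopifnot(inherits(rec, "tug_recording"))
  idx <- window_index(rec, still_window)
  still <- rec$samples[idx, , drop = FALSE]
  sds <- apply(still, 2, stats::sd)
  if (any(sds >= max_still_sd))
    abort_calibration(sprintf(
      "still window is not static (per-axis SD %s g, threshold %.3g g)",
      paste(sprintf("%.3g", sds), collapse = "/"), max_still_sd))
  m <- colMeans(still)
  if (sqrt(sum(m^2)) < 1e-6)
    abort_calibration("near-zero mean acceleration in still window")
  R <- tilt_rotation(m)
  out <- rec$samples %*% t(R)
  colnames(out) <- colnames(rec$samples)
  tug_recording(out, rec$rate, calibrated = TRUE)
}

# Rigid rotation mapping vector m = (v, ml, ap) onto the +V axis:
# pitch about ML to null AP, then roll about AP to null ML.
tilt_rotation <- function(m) {
  theta <- atan2(m[3], m[1])                     # pitch, V-AP plane
  Rp <- rbind(c(cos(theta), 0, sin(theta)),
              c(0,          1, 0),
              c(-sin(theta), 0, cos(theta)))
  m2 <- as.numeric(Rp %*% m)
  phi <- atan2(m2[2], m2[1])                     # roll, V-ML plane
  Rr <- rbind(c(cos(phi), sin(phi), 0),
              c(-sin(phi), cos(phi), 0),
              c(0,        0,        1))
  Rr %*% Rp
}
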