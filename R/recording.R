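#' Tri-axial TUG accelerometer recording
#'
#' Container for a waist-worn tri-axial accelerometer recording taken during
#' a Timed Up and Go test. Columns follow the fixed axis convention:
#' vertical (V, downward positive), medial-lateral (ML, right positive) and
#' anterior-posterior (AP, anterior positive), all in units of g.
#'
#' @param samples numeric n x 3 matrix of acceleration in g, columns
#'   (V, ML, AP).
#' @param rate sampling frequency in Hz (nominally 45 Hz for the supported
#'   sensor).
#' @param calibrated logical; `TRUE` once the recording has been rotated
#'   into the horizontal-vertical frame by [calibrate()].
#' @return An object of class `tug_recording`: a list with elements
#'   `samples` (matrix with columns `v`, `ml`, `ap`), `rate` and
#'   `calibrated`.
#' @seealso [read_recording()], [calibrate()], [simulate_recording()]
#' @export
tug_recording <- function(samples, rate, calibrated = FALSE) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) != 3L)
    abort_format("samples must be a numeric n x 3 matrix (V, ML, AP)")
  if (anyNA(samples))
    abort_format("samples contain missing values")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    abort_argument("rate must be a single positive number (Hz)")
  if (nrow(samples) < 2 * rate)
    abort_length(sprintf(
      "recording too short: %d samples < 2 s at %.4g Hz", nrow(samples), rate))
  colnames(samples) <- c("v", "ml", "ap")
  structure(list(samples = samples, rate = rate,
                 calibrated = isTRUE(calibrated)),
            class = "tug_recording")
}

#' @export
print.tug_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<tug_recording> %d samples @ %.4g Hz (%.2f s), %s\n",
              n, x$rate, n / x$rate,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  invisible(x)
}

#' Default column dialect for recording files
#'
#' @param time,v,ml,ap column names in the delimited file.
#' @param sep field separator.
#' @param rate optional sampling rate in Hz; when supplied it overrides
#'   rate inference from the time column (and permits files with no time
#'   column).
#' @return A named list understood by [read_recording()].
#' @export
recording_dialect <- function(time = "time_s", v = "acc_v_g", ml = "acc_ml_g",
                              ap = "acc_ap_g", sep = ",", rate = NULL) {
  list(time = time, v = v, ml = ml, ap = ap, sep = sep, rate = rate)
}

#' Read a tri-axial recording from delimited text
#'
#' Reads a headered delimited-text file holding one TUG recording. The
#' sampling rate is taken from the dialect if given, otherwise inferred as
#' the reciprocal of the median inter-sample interval of the time column.
#'
#' @param path file path.
#' @param dialect column-name map from [recording_dialect()].
#' @return An uncalibrated [tug_recording()].
#' @export
read_recording <- function(path, dialect = recording_dialect()) {
  if (!file.exists(path)) abort_argument(paste("no such file:", path))
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          check.names = FALSE)
  for (col in c(dialect$v, dialect$ml, dialect$ap))
    if (!col %in% names(df))
      abort_format(paste("missing acceleration column:", col))
  rate <- dialect$rate
  if (is.null(rate)) {
    if (!dialect$time %in% names(df))
      abort_format(paste("missing time column:", dialect$time,
                         "(and no rate given in dialect)"))
    tt <- df[[dialect$time]]
    dt <- diff(tt)
    if (any(dt <= 0)) abort_format("timestamps are not strictly increasing")
    rate <- 1 / stats::median(dt)
  }
  samples <- cbind(df[[dialect$v]], df[[dialect$ml]], df[[dialect$ap]])
  if (anyNA(samples)) abort_format("missing values in acceleration columns")
  if (nrow(samples) < 2 * rate)
    abort_length("recording shorter than 2 s")
  tug_recording(samples, rate, calibrated = FALSE)
}

#' Write a recording to delimited text
#'
#' Writes the canonical dialect (`time_s, acc_v_g, acc_ml_g, acc_ap_g`,
#' comma-separated) with enough digits that a read/write/read cycle
#' round-trips samples bit-identically.
#'
#' @param rec a [tug_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tug_recording"))
  n <- nrow(rec$samples)
  tt <- (seq_len(n) - 1) / rec$rate
  lines <- c("time_s,acc_v_g,acc_ml_g,acc_ap_g",
             sprintf("%.17g,%.17g,%.17g,%.17g",
                     tt, rec$samples[, 1], rec$samples[, 2], rec$samples[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# sample indices (1-based) covered by a half-open time window [start, end)
window_index <- function(rec, window) {
  if (!is.numeric(window) || length(window) != 2L)
    abort_argument("window must be c(start_s, end_s)")
  if (window[2] <= window[1]) abort_argument("zero or negative length window")
  n <- nrow(rec$samples)
  tt <- (seq_len(n) - 1) / rec$rate
  idx <- which(tt >= window[1] & tt < window[2])
  if (length(idx) == 0L) abort_argument("window lies outside the recording")
  idx
}
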