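# Classed conditions so callers can distinguish argument misuse from data
# problems (format, length, calibration, segmentation, ...).

stop_tug <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "tug_error"), call = call))
}

abort_argument     <- function(msg) stop_tug(msg, "tug_argument_error")
abort_format       <- function(msg) stop_tug(msg, "tug_format_error")
abort_length       <- function(msg) stop_tug(msg, "tug_length_error")
abort_calibration  <- function(msg) stop_tug(msg, "tug_calibration_error")
abort_segmentation <- function(msg) stop_tug(msg, "tug_segmentation_error")
abort_step         <- function(msg) stop_tug(msg, "tug_step_error")
abort_numeric      <- function(msg) stop_tug(msg, "tug_numeric_error")
abort_protocol     <- function(msg) stop_tug(msg, "tug_protocol_error")
abort_data         <- function(msg) stop_tug(msg, "tug_data_error")
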