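#' Standard 12-channel IMU layout
#'
#' Two sensor sites (chest, abdomen), each recording a tri-axial accelerometer
#' (in g) and a tri-axial gyroscope (in deg/s) at 125 Hz, giving 12 channels in
#' the fixed order `chest_accel_x ... abdomen_gyro_z`.
#'
#' @return An object of class `channel_layout` with fields `names` (12 channel
#'   identifiers) and `sample_rate` (Hz).
#' @export
#' @examples
#' channel_layout()$names
channel_layout <- function() {
  nm <- paste(rep(c("chest", "abdomen"), each = 6L),
              rep(rep(c("accel", "gyro"), each = 3L), 2L),
              rep(c("x", "y", "z"), 4L),
              sep = "_")
  structure(list(names = nm, sample_rate = SAMPLE_RATE),
            class = "channel_layout")
}

#' Construct an annotated recording
#'
#' A recording is a `T x 12` numeric matrix of sensor samples plus a table of
#' event annotations with half-open sample spans `[start_sample, end_sample)`
#' in 0-based sample units (matching the on-disk JSON convention).
#'
#' @param data Numeric matrix with one column per channel of [channel_layout()].
#' @param subject_id Subject identifier string.
#' @param annotations Data frame with columns `label`, `start_sample`,
#'   `end_sample` (0-based, half-open); may be empty.
#' @param layout A `channel_layout`; defaults to the standard layout.
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, subject_id = "anon",
                          annotations = empty_annotations(),
                          layout = channel_layout()) {
  rec <- structure(list(data = data, layout = layout,
                        subject_id = subject_id,
                        annotations = annotations),
                   class = "recording")
  validate_recording(rec)
  rec
}

empty_annotations <- function() {
  data.frame(label = character(), start_sample = integer(),
             end_sample = integer(), stringsAsFactors = FALSE)
}

#' Validate the structural invariants of a recording
#'
#' Checks channel count/names, finiteness, and that annotations are sorted,
#' in-range, non-overlapping and drawn from the six-class label set.
#'
#' @param rec A `recording`.
#' @return `rec`, invisibly; errors with a diagnostic otherwise.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "recording")) stop_bd("not a recording object")
  d <- rec$data
  if (!is.matrix(d) || !is.numeric(d)) stop_bd("recording data must be a numeric matrix")
  if (nrow(d) < 1L) stop_bd("recording must contain at least one sample")
  if (ncol(d) != length(rec$layout$names)) {
    stop_bd("recording has %d channels, expected %d", ncol(d), length(rec$layout$names))
  }
  if (anyNA(d) || !all(is.finite(d))) stop_bd("recording contains non-finite values")
  an <- rec$annotations
  if (nrow(an)) {
    if (!all(an$label %in% EVENT_CLASSES)) {
      stop_bd("unknown annotation label(s): %s",
              paste(setdiff(an$label, EVENT_CLASSES), collapse = ", "))
    }
    if (any(an$start_sample < 0L) || any(an$end_sample > nrow(d)) ||
        any(an$start_sample >= an$end_sample)) {
      stop_bd("annotation spans must satisfy 0 <= start < end <= n_samples")
    }
    if (is.unsorted(an$start_sample)) stop_bd("annotations must be sorted by start_sample")
    if (nrow(an) > 1L && any(an$start_sample[-1L] < an$end_sample[-nrow(an)])) {
      stop_bd("annotations must not overlap")
    }
  }
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<recording> subject %s: %d samples (%.1f s at %d Hz), %d channels\n",
              x$subject_id, n, n / x$layout$sample_rate, x$layout$sample_rate,
              ncol(x$data)))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$label)
    cat("  annotations:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# Extract rows of a 0-based half-open span [start, end) as a matrix.
span_rows <- function(data, start_sample, end_sample) {
  data[(start_sample + 1L):end_sample, , drop = FALSE]
}
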