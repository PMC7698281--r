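#' Extract an event pool from annotated recordings
#'
#' Excises every annotated non-normal span into an event clip, grouped by
#' class, and collects the annotated normal spans into a reservoir of normal
#' breathing used as injection background.
#'
#' @param recordings A list of `recording` objects (or a single recording).
#' @return An object of class `event_pool` with fields `clips_by_class`
#'   (named list over the five event classes; each element a list of clips
#'   with fields `label`, `data`, `source_subject`) and `normal_reservoir`
#'   (list of `T x 12` matrices).
#' @export
#' @examples
#' ses <- simulate_subject_session(seed = 1)
#' pool <- extract_event_pool(list(ses))
#' lengths(pool$clips_by_class)
extract_event_pool <- function(recordings) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  classes <- EVENT_CLASSES[-1L]
  clips <- stats::setNames(vector("list", length(classes)), classes)
  clips[] <- list(list())
  reservoir <- list()
  for (rec in recordings) {
    validate_recording(rec)
    an <- rec$annotations
    if (!nrow(an)) {
      warning(sprintf("recording '%s' has no annotations; skipped", rec$subject_id))
      next
    }
    for (i in seq_len(nrow(an))) {
      seg <- span_rows(rec$data, an$start_sample[i], an$end_sample[i])
      if (an$label[i] == "normal") {
        reservoir[[length(reservoir) + 1L]] <- seg
      } else {
        cls <- an$label[i]
        if (nrow(seg) < SAMPLE_RATE) {
          warning(sprintf("dropping %s clip of %d samples (< 1 s) from '%s'",
                          cls, nrow(seg), rec$subject_id))
          next
        }
        clips[[cls]][[length(clips[[cls]]) + 1L]] <-
          list(label = cls, data = seg, source_subject = rec$subject_id)
      }
    }
  }
  structure(list(clips_by_class = clips, normal_reservoir = reservoir),
            class = "event_pool")
}

#' @export
print.event_pool <- function(x, ...) {
  cnt <- lengths(x$clips_by_class)
  cat("<event_pool>", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "),
      sprintf("| %d normal reservoir spans\n", length(x$normal_reservoir)))
  invisible(x)
}

pool_counts <- function(pool) lengths(pool$clips_by_class)

# Draw a contiguous n-sample normal-breathing background from the reservoir.
draw_normal_span <- function(pool, n_samples) {
  ok <- which(vapply(pool$normal_reservoir, nrow, integer(1)) >= n_samples)
  if (!length(ok)) {
    stop_bd("no normal reservoir span of >= %d samples available", n_samples)
  }
  i <- ok[sample.int(length(ok), 1L)]
  span <- pool$normal_reservoir[[i]]
  off <- sample_int_range(0L, nrow(span) - n_samples)
  span[(off + 1L):(off + n_samples), , drop = FALSE]
}
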