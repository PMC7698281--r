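# Rule-based event injection into 30-s normal-breathing segments.

SEGMENT_S <- 30L
SEGMENT_SAMPLES <- SEGMENT_S * SAMPLE_RATE  # 3750

# Admissible central-apnea durations (seconds): when a segment carries a
# single CSA event vs when CSA is one of two events.
CSA_DURATIONS_SINGLE <- c(10L, 20L, 23L)
CSA_DURATIONS_DOUBLE <- c(10L, 11L, 13L)
NONCSA_MAX_S <- 14L

#' Draw a seeded injection plan for one 30-s segment
#'
#' Chooses which events to inject and where. Event classes are drawn uniformly
#' from the five event classes. A single CSA event gets a duration drawn from
#' \{10, 20, 23\} s; when two events are injected a CSA duration is drawn from
#' \{10, 11, 13\} s. Other classes use their clip's full duration rounded up
#' to whole seconds (capped at 14 s). Single events are placed uniformly over
#' admissible integer start seconds anywhere in the segment; with two events
#' the first is placed within the first 15 s and the second within the second
#' 15 s, so they can never overlap.
#'
#' @param n_events 0, 1 or 2.
#' @param pool An [extract_event_pool()] result.
#' @param seed Integer seed.
#' @param max_retries Bounded redraws when a drawn clip cannot be placed.
#' @return An object of class `injection_plan`: a data frame `entries` with
#'   columns `label`, `start_second`, `duration_s`, `clip_index`, plus
#'   `n_events`.
#' @export
#' @examples
#' pool <- extract_event_pool(list(simulate_subject_session(seed = 1)))
#' draw_injection_plan(2, pool, seed = 9)$entries
draw_injection_plan <- function(n_events, pool, seed = 1L, max_retries = 20L) {
  if (!n_events %in% 0:2) stop_bd("`n_events` must be 0, 1 or 2")
  classes <- EVENT_CLASSES[-1L]
  empty <- classes[lengths(pool$clips_by_class) == 0L]
  entries <- data.frame(label = character(), start_second = integer(),
                        duration_s = integer(), clip_index = integer(),
                        stringsAsFactors = FALSE)
  plan <- structure(list(entries = entries, n_events = as.integer(n_events)),
                    class = "injection_plan")
  if (n_events == 0L) return(plan)
  with_seed(seed, {
    for (slot in seq_len(n_events)) {
      # placement window: whole segment for single events, one 15-s half each
      # for two-event segments
      win <- if (n_events == 1L) c(0L, SEGMENT_S) else if (slot == 1L) c(0L, 15L) else c(15L, 30L)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cls <- classes[sample.int(length(classes), 1L)]
        if (cls %in% empty) stop_bd("event pool is empty for class '%s'", cls)
        clip_index <- sample.int(length(pool$clips_by_class[[cls]]), 1L)
        dur <- if (cls == "csa") {
          set <- if (n_events == 1L) CSA_DURATIONS_SINGLE else CSA_DURATIONS_DOUBLE
          set[sample.int(length(set), 1L)]
        } else {
          clip_len <- nrow(pool$clips_by_class[[cls]][[clip_index]]$data)
          min(NONCSA_MAX_S, as.integer(ceiling(clip_len / SAMPLE_RATE)))
        }
        if (dur <= win[2L] - win[1L]) {
          start <- sample_int_range(win[1L], win[2L] - dur)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_bd("could not place an event in [%d, %d) s after %d retries",
                       win[1L], win[2L], max_retries)
      plan$entries[slot, ] <- list(cls, start, as.integer(dur), clip_index)
    }
  })
  plan
}

validate_plan <- function(plan) {
  e <- plan$entries
  if (nrow(e) != plan$n_events) stop_bd("plan entry count disagrees with n_events")
  if (!nrow(e)) return(invisible(plan))
  if (any(e$start_second < 0L) || any(e$start_second + e$duration_s > SEGMENT_S)) {
    stop_bd("plan spans must fall within [0, %d) s", SEGMENT_S)
  }
  if (nrow(e) == 2L) {
    if (!(e$start_second[1L] < 15L && e$start_second[2L] >= 15L)) {
      stop_bd("two-event plans require first start < 15 s and second start >= 15 s")
    }
    if (e$start_second[1L] + e$duration_s[1L] > e$start_second[2L]) {
      stop_bd("plan entries overlap")
    }
  }
  invisible(plan)
}

#' Average the edges of an injected span into the surrounding signal
#'
#' Boundary smoothing: on each of the 12 channels the first sample of the
#' injected span is replaced by its average with the preceding normal sample,
#' and the last sample by its average with the following normal sample. A span
#' touching a segment edge is smoothed only on its interior side. Labels are
#' untouched (the averaged samples keep the event label).
#'
#' @param segment_data Numeric `T x 12` matrix (event already spliced in).
#' @param span Integer pair `c(start_sample, end_sample)`, 0-based half-open.
#' @return The smoothed matrix.
#' @export
smooth_boundary <- function(segment_data, span) {
  s <- span[1L]; e <- span[2L]
  if (s < 0L || e > nrow(segment_data) || s >= e) {
    stop_bd("invalid span [%d, %d) for %d rows", s, e, nrow(segment_data))
  }
  if (s > 0L) {
    segment_data[s + 1L, ] <- (segment_data[s + 1L, ] + segment_data[s, ]) / 2
  }
  if (e < nrow(segment_data)) {
    segment_data[e, ] <- (segment_data[e, ] + segment_data[e + 1L, ]) / 2
  }
  segment_data
}

#' Inject planned events into a 30-s normal segment
#'
#' Replaces the planned spans of the base segment with event-clip samples.
#' CSA clips are cropped (seeded random offset) to the planned duration;
#' other clips are placed at the start of their span, the remainder of the
#' final second keeping the normal background as padding. Each spliced span is
#' boundary-smoothed with [smooth_boundary()], and the seconds covered by each
#' plan entry are labeled with its event class (all others stay `normal`).
#'
#' @param base 3750 x 12 matrix (or `recording`) of normal breathing.
#' @param plan An [draw_injection_plan()] result.
#' @param pool The event pool the plan indexes into.
#' @param seed Integer seed (used for CSA crop offsets).
#' @param segment_id Identifier stored on the segment.
#' @return An object of class `labeled_segment`: fields `data` (3750 x 12),
#'   `labels` (30 per-second labels), `plan`, `segment_id`.
#' @export
inject_events <- function(base, plan, pool, seed = 1L, segment_id = "seg") {
  if (inherits(base, "recording")) base <- base$data
  if (!is.matrix(base) || nrow(base) != SEGMENT_SAMPLES || ncol(base) != 12L) {
    stop_bd("`base` must be a %d x 12 matrix", SEGMENT_SAMPLES)
  }
  validate_plan(plan)
  data <- base
  labels <- rep("normal", SEGMENT_S)
  with_seed(seed, {
    e <- plan$entries
    for (i in seq_len(nrow(e))) {
      clip <- pool$clips_by_class[[e$label[i]]][[e$clip_index[i]]]
      target <- e$duration_s[i] * SAMPLE_RATE
      cd <- clip$data
      if (e$label[i] == "csa") {
        if (nrow(cd) < target) {
          stop_bd("csa clip %d from '%s' has %d samples, shorter than the planned %d",
                  e$clip_index[i], clip$source_subject, nrow(cd), target)
        }
        off <- sample_int_range(0L, nrow(cd) - target)
        cd <- cd[(off + 1L):(off + target), , drop = FALSE]
      } else if (nrow(cd) > target) {
        # clip longer than its (capped) planned duration: keep the center
        off <- (nrow(cd) - target) %/% 2L
        cd <- cd[(off + 1L):(off + target), , drop = FALSE]
      }
      s0 <- e$start_second[i] * SAMPLE_RATE            # 0-based sample offset
      span <- c(s0, s0 + nrow(cd))
      data[(span[1L] + 1L):span[2L], ] <- cd
      data <- smooth_boundary(data, span)
      labels[(e$start_second[i] + 1L):(e$start_second[i] + e$duration_s[i])] <- e$label[i]
    }
  })
  structure(list(data = data, labels = labels, plan = plan,
                 segment_id = segment_id),
            class = "labeled_segment")
}

#' @export
print.labeled_segment <- function(x, ...) {
  cat(sprintf("<labeled_segment> %s: %d x %d, labels: %s\n", x$segment_id,
              nrow(x$data), ncol(x$data), paste(rle(x$labels)$values, collapse = " -> ")))
  invisible(x)
}
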