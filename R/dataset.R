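# Detection and classification dataset assembly.

#' Seeded train/validation/test partition
#'
#' Uniform random split at the item level (unstratified), with sizes rounded
#' to within one item of the requested fractions.
#'
#' @param ids Character vector of item ids (or an integer count).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return Object of class `dataset_split`: list with `train`, `validation`,
#'   `test` id vectors and `fractions`.
#' @export
make_split <- function(ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- sprintf("item%06d", seq_len(ids))
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    stop_bd("`fractions` must be three values summing to 1")
  }
  n <- length(ids)
  n_tr <- round(fractions[1L] * n)
  n_va <- round(fractions[2L] * n)
  n_te <- n - n_tr - n_va
  if (n_te < 0L) { n_va <- n_va + n_te; n_te <- 0L }
  with_seed(seed, {
    perm <- sample.int(n)
    structure(list(train = ids[perm[seq_len(n_tr)]],
                   validation = ids[perm[n_tr + seq_len(n_va)]],
                   test = ids[perm[n_tr + n_va + seq_len(n_te)]],
                   fractions = fractions),
              class = "dataset_split")
  })
}

#' Build a per-second detection dataset
#'
#' Draws `n_segments` 30-s backgrounds of normal breathing from the pool's
#' reservoir, injects 0, 1 or 2 events per segment according to `event_mix`,
#' and partitions the segments 60/20/20 into train/validation/test.
#'
#' @param pool An [extract_event_pool()] result covering all five classes.
#' @param n_segments Number of 30-s segments to build (> 0).
#' @param event_mix Proportions of 0-, 1- and 2-event segments.
#' @param seed Integer seed; the whole dataset is deterministic in
#'   `(pool, n_segments, event_mix, seed)`.
#' @param fractions Split fractions, defaulting to 60/20/20.
#' @return List with `segments` (named list of `labeled_segment`) and `split`
#'   (a `dataset_split`).
#' @export
#' @examples
#' pool <- extract_event_pool(list(simulate_subject_session(seed = 1)))
#' ds <- build_detection_dataset(pool, n_segments = 4, seed = 2)
#' lengths(ds$split[1:3])
build_detection_dataset <- function(pool, n_segments,
                                    event_mix = c(0.1, 0.6, 0.3),
                                    seed = 1L,
                                    fractions = c(0.6, 0.2, 0.2)) {
  if (!is.numeric(n_segments) || n_segments <= 0) {
    stop_bd("`n_segments` must be a positive integer")
  }
  n_segments <- as.integer(n_segments)
  if (length(event_mix) != 3L || any(event_mix < 0) || sum(event_mix) <= 0) {
    stop_bd("`event_mix` must be three non-negative proportions")
  }
  missing_cls <- names(which(lengths(pool$clips_by_class) == 0L))
  if (length(missing_cls)) {
    stop_bd("pool has no clips for class(es): %s", paste(missing_cls, collapse = ", "))
  }
  with_seed(seed, {
    n_events <- sample(0:2, n_segments, replace = TRUE,
                       prob = event_mix / sum(event_mix))
    sub <- matrix(draw_subseeds(3L * n_segments), ncol = 3L)
    split_seed <- draw_subseeds(1L)
    segments <- vector("list", n_segments)
    ids <- sprintf("seg%06d", seq_len(n_segments))
    for (i in seq_len(n_segments)) {
      base <- with_seed(sub[i, 1L], draw_normal_span(pool, SEGMENT_SAMPLES))
      plan <- draw_injection_plan(n_events[i], pool, seed = sub[i, 2L])
      segments[[i]] <- inject_events(base, plan, pool, seed = sub[i, 3L],
                                     segment_id = ids[i])
    }
    names(segments) <- ids
    list(segments = segments,
         split = make_split(ids, fractions, seed = split_seed))
  })
}

#' Build a fixed-length window classification dataset
#'
#' Extracts one window per event occurrence in the pool, centered on the
#' event; shorter events are embedded (with boundary smoothing) in normal
#' breathing drawn from the reservoir, longer events are center-cropped with a
#' warning. Normal-class windows are sampled from reservoir positions. With
#' `balance = TRUE` every class is down-sampled to the size of the smallest
#' class.
#'
#' @param pool An [extract_event_pool()] result.
#' @param window_s Window length in seconds; `window_s * 125` must be integral
#'   (default 7 s = 875 time steps).
#' @param balance Down-sample all classes to the minimum class count?
#' @param seed Integer seed.
#' @param n_normal Number of normal windows before balancing (default: the
#'   mean event-class count).
#' @param fractions Split fractions.
#' @return List with `windows` (named list; each has `data` `(window_s*125) x
#'   12` and `label`) and `split` (a `dataset_split`).
#' @export
build_classification_dataset <- function(pool, window_s = 7, balance = TRUE,
                                         seed = 1L, n_normal = NULL,
                                         fractions = c(0.6, 0.2, 0.2)) {
  win <- window_s * SAMPLE_RATE
  if (abs(win - round(win)) > 1e-9) stop_bd("`window_s` * 125 must be an integer")
  win <- as.integer(round(win))
  with_seed(seed, {
    windows <- list()
    for (cls in names(pool$clips_by_class)) {
      for (clip in pool$clips_by_class[[cls]]) {
        cd <- clip$data
        if (nrow(cd) > win) {
          warning(sprintf("%s clip (%d samples) longer than the %d-sample window; center-cropped",
                          cls, nrow(cd), win))
          off <- (nrow(cd) - win) %/% 2L
          wdat <- cd[(off + 1L):(off + win), , drop = FALSE]
        } else if (nrow(cd) == win) {
          wdat <- cd
        } else {
          # center the event inside a normal-breathing background
          wdat <- draw_normal_span(pool, win)
          off <- (win - nrow(cd)) %/% 2L
          wdat[(off + 1L):(off + nrow(cd)), ] <- cd
          wdat <- smooth_boundary(wdat, c(off, off + nrow(cd)))
        }
        windows[[length(windows) + 1L]] <- list(data = wdat, label = cls)
      }
    }
    counts <- lengths(pool$clips_by_class)
    n_normal <- n_normal %||% max(1L, round(mean(counts[counts > 0])))
    for (i in seq_len(n_normal)) {
      windows[[length(windows) + 1L]] <- list(data = draw_normal_span(pool, win),
                                              label = "normal")
    }
    labs <- vapply(windows, `[[`, character(1), "label")
    if (balance) {
      m <- min(table(factor(labs, levels = unique(labs))))
      keep <- unlist(lapply(split(seq_along(labs), labs), function(ix) {
        if (length(ix) > m) sort(sample(ix, m)) else ix
      }), use.names = FALSE)
      windows <- windows[sort(keep)]
      labs <- labs[sort(keep)]
    }
    ids <- sprintf("win%06d", seq_along(windows))
    names(windows) <- ids
    list(windows = windows,
         split = make_split(ids, fractions, seed = draw_subseeds(1L)))
  })
}
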