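# Plain-text readers/writers: recordings as CSV (time + 12 channels) with a
# JSON annotation sidecar.

annotation_path_for <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to CSV + JSON
#'
#' The CSV has 13 columns: `t` (seconds) followed by the 12 channels in
#' layout order. Annotations go to a JSON sidecar (same path with `.json`) as
#' a list of `{label, start_sample, end_sample}` objects.
#'
#' @param rec A `recording`.
#' @param path CSV output path.
#' @param annotations_path JSON sidecar path (default: `path` with `.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, annotations_path = annotation_path_for(path)) {
  validate_recording(rec)
  n <- nrow(rec$data)
  df <- data.table::data.table(t = (seq_len(n) - 1L) / rec$layout$sample_rate)
  df <- cbind(df, data.table::as.data.table(rec$data))
  data.table::fwrite(df, path)
  jsonlite::write_json(
    list(subject_id = rec$subject_id,
         sample_rate = rec$layout$sample_rate,
         annotations = rec$annotations),
    annotations_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from CSV (+ optional JSON sidecar)
#'
#' Validates the 13-column layout and numeric content, reporting the missing
#' or offending columns on failure.
#'
#' @param path CSV path written by [write_recording()].
#' @param annotations_path JSON sidecar; if missing, the recording is loaded
#'   without annotations.
#' @return A `recording`.
#' @export
read_recording <- function(path, annotations_path = annotation_path_for(path)) {
  dt <- data.table::fread(path)
  expected <- c("t", channel_layout()$names)
  missing <- setdiff(expected, names(dt))
  if (length(missing)) {
    stop_bd("file '%s' is missing column(s): %s", path, paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(dt), expected)
  if (length(extra)) {
    stop_bd("file '%s' has unexpected column(s): %s", path, paste(extra, collapse = ", "))
  }
  non_num <- names(dt)[!vapply(dt, is.numeric, logical(1))]
  if (length(non_num)) {
    stop_bd("file '%s' has non-numeric column(s): %s", path,
            paste(non_num, collapse = ", "))
  }
  data <- as.matrix(dt[, channel_layout()$names, with = FALSE])
  subject_id <- "anon"
  annotations <- empty_annotations()
  if (!is.null(annotations_path) && file.exists(annotations_path)) {
    meta <- jsonlite::read_json(annotations_path, simplifyVector = TRUE)
    subject_id <- meta$subject_id %||% "anon"
    if (!is.null(meta$annotations) && NROW(meta$annotations)) {
      annotations <- as.data.frame(meta$annotations, stringsAsFactors = FALSE)
      annotations$start_sample <- as.integer(annotations$start_sample)
      annotations$end_sample <- as.integer(annotations$end_sample)
    }
  }
  new_recording(data, subject_id = subject_id, annotations = annotations)
}

#' Write a labeled segment (CSV data + JSON labels/plan sidecar)
#' @param seg A `labeled_segment`.
#' @param dir Output directory (created if needed).
#' @return The CSV path, invisibly.
#' @export
write_segment <- function(seg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(seg$segment_id, ".csv"))
  data.table::fwrite(data.table::as.data.table(seg$data), csv)
  jsonlite::write_json(
    list(segment_id = seg$segment_id, labels = seg$labels,
         plan = seg$plan$entries),
    file.path(dir, paste0(seg$segment_id, ".json")),
    auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Write a detection dataset to a split-per-directory tree with a manifest
#' @param ds A [build_detection_dataset()] result.
#' @param dir Output root.
#' @param seed Seed recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir, seed = NA_integer_) {
  for (part in c("train", "validation", "test")) {
    sub <- file.path(dir, part)
    for (id in ds$split[[part]]) write_segment(ds$segments[[id]], sub)
  }
  manifest <- list(seed = seed, n_segments = length(ds$segments),
                   fractions = ds$split$fractions,
                   ids = list(train = ds$split$train,
                              validation = ds$split$validation,
                              test = ds$split$test))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
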