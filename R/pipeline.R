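# End-to-end pipeline: simulate -> pool -> dataset -> train -> evaluate.

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. The `desk` scale preset keeps
#' simulation and training small enough for a single CPU; `full` mirrors the
#' full-scale study layout (40,000 segments, large detector) and is intended
#' for compute clusters.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param n_subjects Number of simulated acquisition sessions.
#' @param n_segments Number of 30-s detection segments.
#' @param event_mix Proportions of 0/1/2-event segments.
#' @param window_s Classification window length (seconds).
#' @param scale `"desk"` or `"full"` model preset.
#' @param profile A [subject_profile()].
#' @param detector_hyper,out_dir Further knobs: training overrides and an
#'   optional output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 8L, n_segments = 200L,
                            event_mix = c(0.1, 0.6, 0.3), window_s = 7,
                            scale = c("desk", "full"),
                            profile = subject_profile(),
                            detector_hyper = list(epochs = 10L, batch_size = 16L),
                            out_dir = NULL) {
  scale <- match.arg(scale)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_segments = as.integer(n_segments), event_mix = event_mix,
                 window_s = window_s, scale = scale, profile = profile,
                 detector_hyper = detector_hyper, out_dir = out_dir),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Simulates `n_subjects` annotated sessions, extracts the event pool, builds
#' the per-second detection dataset, trains the detector at the configured
#' scale, evaluates per-second performance on the held-out test split, and
#' assembles a manifest (seeds, config hash, artifact checksums) from which
#' the run can be regenerated. If `out_dir` is set, the dataset, evaluation
#' report and manifest are written there.
#'
#' @param config A [pipeline_config()].
#' @return List with `pool`, `dataset`, `model`, `evaluation` (an
#'   `eval_report`), `lag` (a `lag_report`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_bd("`config` must be a pipeline_config")
  if (!is.null(config$out_dir) && !dir.exists(dirname(config$out_dir))) {
    stop_bd("parent of out_dir '%s' does not exist", config$out_dir)
  }
  seeds <- with_seed(config$seed, draw_subseeds(4L))
  message(sprintf("[1/4] simulating %d subject sessions", config$n_subjects))
  t0 <- Sys.time()
  sessions <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject_session(config$profile, seed = seeds[1L] + i - 1L,
                             subject_id = sprintf("S%03d", i))
  })
  pool <- extract_event_pool(sessions)
  message(sprintf("      pool: %s (%.1f s)",
                  paste(sprintf("%s=%d", names(pool_counts(pool)), pool_counts(pool)),
                        collapse = " "),
                  as.numeric(Sys.time() - t0, units = "secs")))
  message(sprintf("[2/4] building %d detection segments", config$n_segments))
  ds <- build_detection_dataset(pool, config$n_segments,
                                event_mix = config$event_mix, seed = seeds[2L])
  message(sprintf("[3/4] training %s-scale detector", config$scale))
  model <- build_detector(detector_config(config$scale))
  fit <- train_model(model,
                     train = ds$segments[ds$split$train],
                     val = ds$segments[ds$split$validation],
                     hyper = config$detector_hyper, seed = seeds[3L])
  message("[4/4] evaluating on the test split")
  test_segs <- ds$segments[ds$split$test]
  ev <- evaluate_detector(fit, test_segs)
  lag <- detection_lag(
    labels_to_spans(unlist(lapply(test_segs, `[[`, "labels"), use.names = FALSE)),
    labels_to_spans(ev$predicted))
  manifest <- list(seed = config$seed, stage_seeds = seeds,
                   config_md5 = config_digest(config),
                   n_subjects = config$n_subjects,
                   n_segments = config$n_segments,
                   pool_counts = as.list(pool_counts(pool)),
                   split_sizes = lengths(ds$split[1:3]),
                   macro_f1 = ev$report$macro_f1)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(ds, file.path(config$out_dir, "dataset"), seed = seeds[2L])
    jsonlite::write_json(ev$report$per_class,
                         file.path(config$out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(pool = pool, dataset = ds, model = fit, evaluation = ev$report,
       lag = lag, manifest = manifest)
}
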