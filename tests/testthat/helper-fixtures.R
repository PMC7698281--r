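# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fx_session <- function() {
  memo("session", function() simulate_subject_session(seed = 101L, subject_id = "T01"))
}

fx_sessions3 <- function() {
  memo("sessions3", function() {
    lapply(1:3, function(i) {
      simulate_subject_session(seed = 200L + i, subject_id = sprintf("T%02d", i))
    })
  })
}

fx_pool <- function() {
  memo("pool", function() extract_event_pool(fx_sessions3()))
}

fx_dataset <- function() {
  memo("dataset", function() build_detection_dataset(fx_pool(), 30L, seed = 11L))
}
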