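# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Draw one integer uniformly from a:b (inclusive); robust for b == a.
sample_int_range <- function(a, b) {
  stopifnot(b >= a)
  a + sample.int(b - a + 1L, 1L) - 1L
}

# Derive reproducible sub-seeds (< 2^31) from the current RNG stream.
draw_subseeds <- function(n) sample.int(.Machine$integer.max, n)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bd <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bd("`%s` must be a single finite number", name)
  }
}
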