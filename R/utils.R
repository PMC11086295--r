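# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic operations route through this so
# that identical seeds give identical outputs.
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# round() halves to even; allocation arithmetic wants the conventional
# half-away-from-zero so printed count tables reproduce.
round_half_up <- function(x) floor(x + 0.5)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}
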