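# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive reproducible sub-seeds from the current stream (kept < 2^31).
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s0, 1%s",
                              if (open_left) "(" else "[",
                              if (open_right) ")" else "]"))
  x
}

check_scalar <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (if (strict) x <= lower else x < lower)
    stop_field(field, sprintf("must be %s %g", if (strict) ">" else ">=",
                              lower))
  x
}

# Circular distance between cycle fractions (shortest arc, in cycles).
circ_dist <- function(a, b) {
  d <- abs((a - b) %% 1)
  pmin(d, 1 - d)
}
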