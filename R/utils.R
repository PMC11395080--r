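`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

assert_positive <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  as.numeric(x)
}

assert_fraction <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be in [0, 1]")
  as.numeric(x)
}

assert_range <- function(x, field) {
  if (length(x) != 2L || !is.numeric(x) || any(is.na(x)) || any(x <= 0) ||
      x[1] > x[2])
    stop_field(field, "must be an increasing pair of positive numbers")
  as.numeric(x)
}

# Seed handling: every generator takes an explicit seed and restores the
# caller's RNG state on exit, so no global state leaks between stages.
with_seed <- function(seed, code) {
  seed <- assert_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
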