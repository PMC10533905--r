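# Internal helpers shared across modules.

# Fail with a caller-friendly message.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Scalar checks ---------------------------------------------------------------

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_num(x)) stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper) {
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

# Seed sub-streams ------------------------------------------------------------

# Deterministic per-item seed so that increasing n leaves earlier items
# untouched. Folds (seed, item) into a 31-bit integer.
substream_seed <- function(seed, item) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(item) * 16807
  as.integer(s %% 2147483647)
}

# Run an expression with a local RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Angles ----------------------------------------------------------------------

# Wrap an axial angle (period 180 degrees) into (-90, 90].
wrap_axial <- function(deg) {
  out <- ((deg + 90) %% 180) - 90
  out[out == -90] <- 90
  out
}
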