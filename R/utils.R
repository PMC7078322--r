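# Internal helpers shared across modules.

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
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

# Derive a child seed from a base seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629) + 1L
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  as.integer(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "Column%s %s missing from `%s`.",
      if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", "), what
    ))
  }
  invisible(data)
}

# Extract a numeric column selected by a quosure; errors with a clear name.
pull_numeric <- function(data, quo, what) {
  col <- as_name(quo)
  check_columns(data, col, what = what)
  x <- data[[col]]
  if (!is.numeric(x) && !is.logical(x)) {
    abort(sprintf("Column `%s` must be numeric.", col))
  }
  as.numeric(x)
}

# Sample standard deviation that is 0 (not NA) for a single value.
sample_sd <- function(x) if (length(x) < 2) 0 else sd(x)
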