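# Internal helpers shared across the package.

# Complementary error function in terms of the normal CDF.
erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

#' Deterministic 31-bit seed from a key string
#'
#' Derives an independent, reproducible RNG seed for a keyed random stream
#' (e.g. one stream per simulated profile) from a base seed and a set of key
#' components. Uses an FNV-1a-style accumulation over the UTF-8 bytes of the
#' collapsed key, reduced modulo 2^31 - 1 so the result is always a valid,
#' positive 32-bit integer seed.
#'
#' @param seed Integer base seed.
#' @param ... Key components (coerced to character and collapsed).
#' @return A single integer in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "CP2", 3, 48)
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  m <- 2^31 - 1
  for (b in bytes) {
    h <- (h %% m) * 16777619 %% m
    h <- (h + b) %% m
  }
  as.integer(h %% m + 1)
}

# Validate that a data frame has the given columns; error names the missing.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "dicect_schema_error")
  }
  invisible(df)
}

# Uniform spacing of a strictly increasing position vector; errors otherwise.
uniform_spacing <- function(x, tol = 1e-6, context = "positions") {
  if (length(x) < 2 || any(diff(x) <= 0)) {
    abort(sprintf("%s must be strictly increasing", context),
          class = "dicect_validation_error")
  }
  d <- diff(x)
  h <- stats::median(d)
  if (any(abs(d - h) > tol * h)) {
    abort(sprintf("%s must be uniformly spaced (tolerance %g of spacing)",
                  context, tol),
          class = "dicect_validation_error")
  }
  h
}

# n-1 standard deviation that returns NA for a single value instead of error.
sd_or_na <- function(x) if (length(x) < 2) NA_real_ else sd(x)
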