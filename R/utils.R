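# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  expr
}

# Derive a child seed from a root seed; deterministic, < 2^31, and exact in
# double arithmetic (69069 * 2^31 < 2^53, so no precision loss).
derive_seed <- function(seed, ...) {
  key <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (k in key) h <- (h * 69069 + k + 12345) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  invisible(x)
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
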