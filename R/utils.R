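# Small shared helpers. Nothing here is user-facing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Reporting convention used throughout: `round()` in R rounds half to even,
#' which does not match how percentages are conventionally reported.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Clip to [lo, hi] and round half up to the nearest integer (bounded Likert
# scales are integer-valued).
clip_round <- function(x, lo, hi) {
  pmax(pmin(floor(x + 0.5), hi), lo)
}

# Deterministic per-unit substream seed: adding units never perturbs earlier
# ones, and distinct `offset`s decouple distinct uses of the same unit.
substream_seed <- function(seed, index, offset = 0L) {
  s <- (as.double(seed) + 9973 * as.double(index) + as.double(offset)) %%
    2147483647
  as.integer(s)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# Sample skewness (moment estimator); used for regression diagnostics.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}
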