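# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the ambient stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Ordinary least squares on (x, y) via closed form; returns slope,
# intercept and R^2. R^2 is defined as 0 when y has zero variance
# (a flat signal carries no linear trend to explain).
ols_line <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("zero variance in x; cannot fit a line", call. = FALSE)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) 0 else (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r_squared = r2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
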