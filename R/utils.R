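#' Round half away from zero
#'
#' Report-style rounding: exact halves round up (2.5 -> 3), unlike base R's
#' banker's rounding. Used wherever percentages are printed to a fixed number
#' of decimals.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a fixed, version-stable configuration, runs `expr`, and
#' restores the caller's RNG state, so package functions are deterministic
#' given a seed without disturbing the user's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Derive child seeds from a master seed
#'
#' Deterministic derivation used to give independent, reproducible random
#' streams to samples, replicates and pipeline stages: the master seed seeds
#' a Mersenne-Twister stream from which `n` integers in \[1, 2^31 - 2\] are
#' drawn.
#'
#' @param seed master seed
#' @param n number of child seeds
#' @return integer vector of length `n`
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# stop() with a consistent prefix-free message; keeps call noise out of errors
qc_stop <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
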