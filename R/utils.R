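#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (0.005 -> 0.01,
#' -0.005 -> -0.01), the convention used throughout the reported tables.
#' Base [round()] uses round-half-to-even, which disagrees on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.125, 2)   # 0.13
#' round_half_up(-0.125, 2)  # -0.13
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exact halves in decimal
  # but stored just below .5 in binary still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Derive a stream of child seeds from one master seed
#'
#' The pipeline takes a single user seed and fans it out deterministically to
#' its stages, so stages can be re-run in isolation with the same randomness.
#' Children are kept below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  a <- 1103515245
  c <- 12345
  m <- 2^31 - 1
  out <- integer(n)
  s <- as.double(seed %% m)
  for (i in seq_len(n)) {
    s <- (a * s + c) %% m
    out[i] <- as.integer(s %% (m - 2) + 1)
  }
  out
}

# run expr under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
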