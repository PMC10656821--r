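#' Round half away from zero
#'
#' Rounding used for every printed percentage: .5 always rounds up in
#' magnitude, unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded half-up to an integer
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @return integer percentage.
#' @export
pct <- function(k, n) {
  if (any(n <= 0)) stop("denominator must be positive")
  round_half_up(100 * k / n)
}

# Stable per-stage seed substream: hash the stage name into an offset so a
# stage's randomness does not depend on which stages ran before it.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003L
  as.integer((as.numeric(seed) %% 1000003L) * 1009 + h) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument check: numeric matrix with row/col names
check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop(what, " has duplicated row or column names")
  invisible(x)
}
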