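#' @importFrom rlang .data
#' @importFrom stats predict rnorm runif rpois rgamma rlnorm sd median quantile
NULL

#' Modal value of a character vector with an explicit tie rule
#'
#' Returns the most frequent label; when two or more labels tie for the
#' maximum count the supplied `tie` label is returned if it is among the
#' tied labels, otherwise the earliest tied label in `levels` order (first
#' appearance order when `levels` is NULL).
#'
#' @param x character vector of labels (no NA)
#' @param tie label preferred on ties (typically the window's centre label)
#' @return single label
#' @keywords internal
label_mode <- function(x, tie = NULL) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L && !is.null(tie) && tie %in% top) return(tie)
  top[1L]
}

#' Centred rolling mean with shrunken edge windows
#'
#' @param x numeric vector
#' @param width window width in samples (odd widths are centred exactly;
#'   even widths take one extra trailing sample)
#' @keywords internal
rolling_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  before <- floor((width - 1) / 2)
  after <- width - 1L - before
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Hour of day in [0, 24) from seconds since local midnight
#' @keywords internal
hour_of_day <- function(t_s) {
  (t_s / 3600) %% 24
}

#' Derive a child RNG seed from a base seed and a stream index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard gravity used for g <-> m/s^2 conversion
#' @keywords internal
GRAVITY <- 9.81
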