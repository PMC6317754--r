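# Numerical helpers shared across the engine and oracles.

#' Numerically stable log-sum-exp
#' @param x numeric vector.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Softmax from log space
#' @param x numeric vector of (unnormalized) log weights; -Inf entries get
#'   exactly zero mass.
#' @keywords internal
softmax_log <- function(x) {
  p <- exp(x - logsumexp(x))
  p / sum(p)
}

# x * log(x) with the measure-theoretic convention 0 * log(0) = 0.
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

# Entropy of a discrete distribution (nats).
entropy <- function(p) -sum(xlogx(p))

# Column-normalize a non-negative matrix.
norm_cols <- function(m) sweep(m, 2, colSums(m), "/")

# log with a floor substituting for exact zeros; entries that are genuinely
# positive but tiny are left untouched so that informative near-deterministic
# mappings keep their full log-precision.
log_floored <- function(x, floor = exp(-16)) log(pmax(x, floor))

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
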