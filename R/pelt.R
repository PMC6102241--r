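## Exact penalized changepoint detection for piecewise-constant means.
## PELT (Killick et al. style pruning) over the squared-error segment cost;
## returns the same optimum as the unpruned O(n^2) dynamic program.

#' Exact changepoint detection by PELT
#'
#' Minimizes sum of within-segment squared deviations plus `penalty` per
#' changepoint, with a minimum segment length. The solution is exact (the
#' pruning never discards an optimal candidate for this cost).
#'
#' @param x numeric signal (ordered observations).
#' @param penalty per-changepoint penalty; default is an MBIC-like
#'   `2 * log(n) * sigma^2` with `sigma` estimated from the median absolute
#'   deviation of first differences.
#' @param min_segment minimum observations per segment.
#' @return integer vector of changepoint positions: the index of the last
#'   observation of each segment except the final one (empty when the best
#'   model is a single segment).
#' @export
pelt_changepoints <- function(x, penalty = NULL, min_segment = 2L) {
  n <- length(x)
  min_segment <- max(1L, as.integer(min_segment))
  if (n < 2L * min_segment) return(integer(0))
  if (is.null(penalty)) penalty <- default_segment_penalty(x)
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x * x))
  cost_to <- function(tau, t) {
    ## segment cost of x[(tau+1)..t], vectorized over tau
    len <- t - tau
    (S2[t + 1L] - S2[tau + 1L]) - (S1[t + 1L] - S1[tau + 1L])^2 / len
  }
  F <- rep(Inf, n + 1L)
  F[1L] <- -penalty
  last <- integer(n + 1L)
  cand <- 0L  # candidate values of tau (segment start - 1)
  for (t in seq_len(n)) {
    elig <- cand[cand <= t - min_segment]
    if (!length(elig)) next
    vals <- F[elig + 1L] + cost_to(elig, t) + penalty
    b <- which.min(vals)
    F[t + 1L] <- vals[b]
    last[t + 1L] <- elig[b]
    keep <- (vals - penalty) <= F[t + 1L]
    cand <- c(elig[keep], cand[cand > t - min_segment])
    if (is.finite(F[t + 1L]) && t + min_segment <= n) cand <- c(cand, t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    tau <- last[t + 1L]
    if (tau > 0L) cps <- c(tau, cps)
    t <- tau
  }
  cps
}

#' @rdname pelt_changepoints
#' @export
default_segment_penalty <- function(x) {
  sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-3
  2 * log(length(x)) * sigma^2
}
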