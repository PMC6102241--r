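## Independent oracles. These deliberately share no code with the package:
## the changepoint oracle is the unpruned O(n^2) dynamic program, the
## liftover oracle projects every base one at a time, and the Venn oracle
## recounts categories with per-unit flags.

dp_changepoints_oracle <- function(x, penalty, min_segment = 2L) {
  n <- length(x)
  seg_cost <- function(i, j) {
    v <- x[i:j]
    sum((v - mean(v))^2)
  }
  F <- c(-penalty, rep(Inf, n))
  prev <- integer(n + 1L)
  for (t in seq_len(n)) {
    for (tau in 0:(t - min_segment)) {
      if (tau != 0L && tau < min_segment) next
      cand <- F[tau + 1L] + seg_cost(tau + 1L, t) + penalty
      if (cand < F[t + 1L]) {
        F[t + 1L] <- cand
        prev[t + 1L] <- tau
      }
    }
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    tau <- prev[t + 1L]
    if (tau > 0L) cps <- c(tau, cps)
    t <- tau
  }
  list(changepoints = cps, cost = F[n + 1L])
}

liftover_oracle <- function(iv, chains, min_match = 0.5) {
  ch <- as.character(GenomicRanges::seqnames(iv))
  s <- GenomicRanges::start(iv)
  e <- GenomicRanges::end(iv)
  t_chroms <- character(0)
  t_pos <- numeric(0)
  for (cn in chains) {
    if (cn$s_chrom != ch) next
    for (k in seq_len(nrow(cn$blocks))) {
      b <- cn$blocks[k, ]
      lo <- max(s, b$s_start)
      hi <- min(e, b$s_start + b$len - 1)
      if (lo > hi) next
      for (p in lo:hi) {
        t_chroms <- c(t_chroms, cn$t_chrom)
        t_pos <- c(t_pos, b$t_start + (p - b$s_start))
      }
    }
  }
  if (!length(t_pos)) return(NULL)
  if (length(unique(t_chroms)) > 1L) return(NULL)
  if (length(t_pos) / (e - s + 1) < min_match) return(NULL)
  c(chrom = t_chroms[1], start = min(t_pos), end = max(t_pos))
}

venn_recount_oracle <- function(meth, hyper) {
  meth <- as.matrix(meth)
  sp <- colnames(meth)
  counts <- list()
  n_any <- 0L
  for (r in seq_len(nrow(meth))) {
    row <- meth[r, ]
    if (any(is.na(row))) next
    flags <- row > hyper
    if (!any(flags)) next
    n_any <- n_any + 1L
    key <- paste(sp[flags], collapse = "+")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  list(counts = unlist(counts), n_hyper_any = n_any)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
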