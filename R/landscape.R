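## Methylome landscape: coverage-filtered bin scores, segmentation into
## methylation domains, class fractions, gene-body methylation and anchored
## profiles.

#' Score fixed-width genomic bins from per-CpG calls
#'
#' Each bin's `mean_meth` is the unweighted mean of per-CpG fractional
#' methylation over CpGs at depth `>= min_depth`; bins with fewer than
#' `min_cpgs` such CpGs are flagged `passes_filter = FALSE` and excluded
#' from downstream denominators. The published coverage rules translate to
#' `min_cpgs = 5, min_depth = 5` (high-resolution libraries) and
#' `min_cpgs = 4, min_depth = 1` (low-resolution strain libraries).
#'
#' @param meth a `MethTable` (see [read_cpg_report()]).
#' @param bin_width bin width in bp (1 kb and 2 kb used in practice).
#' @param min_cpgs minimum covered CpGs per passing bin.
#' @param min_depth minimum reads for a CpG to count as covered.
#' @param seqlens named chromosome lengths; defaults to the `MethTable`'s
#'   `seqlengths`, else the last covered position per chromosome.
#' @return `GRanges` of bins with metadata `mean_meth`, `n_cpgs_pass`,
#'   `passes_filter`.
#' @export
score_bins <- function(meth, bin_width = 1000L, min_cpgs = 5L, min_depth = 5L,
                       seqlens = NULL) {
  stopifnot(bin_width > 0L)
  if (is.null(seqlens)) {
    sl <- seqlengths(meth)
    if (any(is.na(sl))) {
      obs <- vapply(split(end(meth), as.character(seqnames(meth))), max, 1)
      sl[names(obs)] <- pmax(obs, sl[names(obs)], na.rm = TRUE)
    }
    seqlens <- sl
  }
  if (!length(seqlens) || any(is.na(seqlens))) {
    .lm_stop("score_bins: chromosome lengths unavailable")
  }
  bins <- tileGenome(seqlens, tilewidth = bin_width,
                     cut.last.tile.in.chrom = TRUE)
  covered <- meth[mcols(meth)$total >= min_depth]
  f <- .meth_frac(covered)
  ov <- findOverlaps(bins, covered)
  dt <- data.table(bin = queryHits(ov), f = f[subjectHits(ov)])
  agg <- dt[, list(n_pass = .N, mean_meth = mean(f)), by = bin]
  mean_meth <- rep(NA_real_, length(bins))
  n_pass <- integer(length(bins))
  mean_meth[agg$bin] <- agg$mean_meth
  n_pass[agg$bin] <- agg$n_pass
  passes <- n_pass >= min_cpgs
  mean_meth[!passes] <- NA_real_
  mcols(bins) <- DataFrame(mean_meth = mean_meth, n_cpgs_pass = n_pass,
                           passes_filter = passes)
  bins
}

#' Classify a methylation level
#'
#' Strict inequalities mirror the published wording: below `lo` is "hypo",
#' above `hi` is "hyper", everything else (boundaries included) is
#' "intermediate".
#'
#' @param value methylation fraction(s) in `[0, 1]`.
#' @param lo,hi class thresholds (defaults 0.30 / 0.70).
#' @return character vector of classes.
#' @export
classify_meth <- function(value, lo = 0.30, hi = 0.70) {
  stopifnot(lo < hi)
  .check_fraction(value, "methylation value")
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value < lo] <- "hypo"
  out[!is.na(value) & value > hi] <- "hyper"
  out[!is.na(value) & value >= lo & value <= hi] <- "intermediate"
  out
}

#' Segment binned methylation into domains
#'
#' Runs exact penalized changepoint detection ([pelt_changepoints()]) on the
#' ordered series of passing bins per chromosome (non-passing bins are
#' bridged: the observation series skips them but the genomic gap is
#' retained inside the resulting domain spans). Each domain carries its
#' segment mean, bin count and hypo/intermediate/hyper class.
#'
#' @param bins output of [score_bins()].
#' @param penalty per-changepoint penalty; `NULL` for the MBIC-like default.
#' @param min_segment minimum bins per domain.
#' @param lo,hi class thresholds passed to [classify_meth()].
#' @return `GRanges` of domains with metadata `mean_meth`, `meth_class`,
#'   `n_bins`.
#' @export
segment_domains <- function(bins, penalty = NULL, min_segment = 2L,
                            lo = 0.30, hi = 0.70) {
  pass <- bins[mcols(bins)$passes_filter]
  if (length(pass) == 0L) return(GRanges(mean_meth = numeric(0)))
  out <- list()
  for (chr in as.character(unique(seqnames(pass)))) {
    b <- pass[seqnames(pass) == chr]
    x <- mcols(b)$mean_meth
    cps <- if (length(x) < 2L * min_segment) integer(0) else
      pelt_changepoints(x, penalty = penalty, min_segment = min_segment)
    bounds <- c(0L, cps, length(x))
    seg_from <- head(bounds, -1L) + 1L
    seg_to <- bounds[-1L]
    means <- vapply(seq_along(seg_from),
                    function(k) mean(x[seg_from[k]:seg_to[k]]), 0)
    dom <- GRanges(chr, IRanges(start(b)[seg_from], end(b)[seg_to]))
    mcols(dom) <- DataFrame(mean_meth = means,
                            meth_class = classify_meth(means, lo, hi),
                            n_bins = seg_to - seg_from + 1L)
    out[[chr]] <- dom
  }
  dom <- unlist(GRangesList(out), use.names = FALSE)
  seqlevels(dom) <- seqlevels(bins)
  seqlengths(dom) <- seqlengths(bins)
  sort(sortSeqlevels(dom))
}

#' Genome fraction per methylation class
#'
#' Territory-weighted fractions over passing territory only; fractions sum
#' to 1. Accepts domains (from [segment_domains()]) or scored bins (class
#' then computed per bin).
#'
#' @param x `GRanges` with either a `meth_class` or a
#'   `mean_meth`/`passes_filter` metadata pair.
#' @param lo,hi thresholds for on-the-fly bin classification.
#' @return named numeric: fraction of territory in each class.
#' @export
genome_fraction_by_class <- function(x, lo = 0.30, hi = 0.70) {
  if (!"meth_class" %in% names(mcols(x))) {
    x <- x[mcols(x)$passes_filter]
    mcols(x)$meth_class <- classify_meth(mcols(x)$mean_meth, lo, hi)
  }
  w <- tapply(width(x), mcols(x)$meth_class, sum)
  out <- setNames(rep(0, 3), c("hypo", "intermediate", "hyper"))
  out[names(w)] <- w / sum(width(x))
  out
}

#' Mean methylation over arbitrary regions
#'
#' The workhorse "average DNAme over a given set of genomic coordinates":
#' unweighted mean of per-CpG fractions over CpGs at depth `>= min_depth`,
#' `NA` (not 0) when fewer than `min_cpgs` such CpGs fall in the region.
#'
#' @param regions `GRanges` of regions.
#' @param meth a `MethTable`.
#' @param min_depth,min_cpgs coverage rule (defaults: >=5 CpGs at >=5x).
#' @return data.frame with `mean_meth` and `n_cpgs` per region.
#' @export
region_methylation <- function(regions, meth, min_depth = 5L, min_cpgs = 5L) {
  covered <- meth[mcols(meth)$total >= min_depth]
  if (length(regions)) .check_shared_chroms(regions, covered, "regions vs methylome")
  f <- .meth_frac(covered)
  ov <- findOverlaps(regions, covered)
  dt <- data.table(r = queryHits(ov), f = f[subjectHits(ov)])
  agg <- dt[, list(n = .N, m = mean(f)), by = r]
  n <- integer(length(regions)); m <- rep(NA_real_, length(regions))
  n[agg$r] <- agg$n
  m[agg$r] <- agg$m
  m[n < min_cpgs] <- NA_real_
  data.frame(mean_meth = m, n_cpgs = n)
}

#' Gene-body methylation
#'
#' Mean per-CpG methylation over the TSS..TTS span of each transcript.
#'
#' @param genes a `TranscriptSet` or a `GRanges` of gene spans.
#' @param meth a `MethTable`.
#' @param min_depth,min_cpgs coverage rule.
#' @return numeric vector of fractions (`NA` where coverage is insufficient).
#' @export
gene_body_methylation <- function(genes, meth, min_depth = 5L, min_cpgs = 5L) {
  spans <- if (is(genes, "GRangesList")) tx_spans(genes) else genes
  region_methylation(spans, meth, min_depth, min_cpgs)$mean_meth
}

#' Methylation profile around anchor points
#'
#' Strand-oriented matrix of mean methylation in `n_bins` windows across
#' `anchor +/- flank`; rows are anchors, columns run 5'->3' so transcribed
#' ("downstream") territory is rightward. Rows with no covered CpG anywhere
#' in the flank are all-`NA`.
#'
#' @param anchors stranded `GRanges` anchor points (e.g. LIT TSSs).
#' @param meth a `MethTable`.
#' @param flank half-window in bp (default 20 kb, as in TSS +/- 20 kb maps).
#' @param n_bins number of profile bins.
#' @param min_depth minimum CpG depth.
#' @return numeric matrix `length(anchors) x n_bins`.
#' @export
profile_around <- function(anchors, meth, flank = 20000L, n_bins = 40L,
                           min_depth = 1L) {
  covered <- meth[mcols(meth)$total >= min_depth]
  f <- .meth_frac(covered)
  prof <- matrix(NA_real_, nrow = length(anchors), ncol = n_bins)
  if (!length(anchors)) return(prof)
  mid <- start(resize(anchors, width = 1L, fix = "center"))
  win <- GRanges(seqnames(anchors),
                 IRanges(pmax(1L, mid - flank), mid + flank - 1L))
  ov <- findOverlaps(win, covered)
  if (length(ov)) {
    a <- queryHits(ov); s <- subjectHits(ov)
    off <- start(covered)[s] - (mid[a] - flank)
    col <- pmin(n_bins, pmax(1L, ceiling(off / (2 * flank / n_bins))))
    col[off <= 0L] <- 1L
    neg <- as.character(strand(anchors))[a] == "-"
    col[neg] <- n_bins + 1L - col[neg]
    dt <- data.table(a = a, col = col, f = f[s])
    agg <- dt[, list(m = mean(f)), by = c("a", "col")]
    prof[cbind(agg$a, agg$col)] <- agg$m
  }
  prof
}
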