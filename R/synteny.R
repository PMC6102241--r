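## Cross-species coordinate projection: liftover through chain alignments,
## reciprocal-best syntenic bins through a hub species, CGI identity scoring,
## and genomic-context classification.

## Flatten a chain_set into a block-level GRanges on the source genome with
## target bookkeeping columns; built once per chain set and memoized on the
## object would be overkill at these sizes.
.chain_blocks <- function(chains) {
  if (!length(chains)) return(GRanges())
  bl <- rbindlist(lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    data.table(s_chrom = ch$s_chrom, s_start = ch$blocks$s_start,
               t_chrom = ch$t_chrom, t_start = ch$blocks$t_start,
               len = ch$blocks$len, chain = i)
  }))
  gr <- GRanges(bl$s_chrom, IRanges(bl$s_start, width = bl$len))
  mcols(gr) <- DataFrame(t_chrom = bl$t_chrom, t_start = bl$t_start,
                         s_start = bl$s_start, chain = bl$chain)
  gr
}

#' Project intervals through chain alignments
#'
#' Projects each interval base-wise through the aligned blocks of `chains`
#' and returns the minimal target interval covering all projected bases.
#' An interval maps to nothing (`NA` row) when the mapped fraction of its
#' bases falls below `min_match` or when its bases project to more than one
#' target chromosome.
#'
#' @param gr `GRanges` to project (strand is ignored; colinear chains only).
#' @param chains a `chain_set` from [read_chain()].
#' @param min_match minimum mapped fraction (default 0.5).
#' @return data.frame with `chrom`, `start`, `end` (NA when unmapped),
#'   `mapped_fraction`, and `mapped` flag, one row per input interval.
#' @export
liftover <- function(gr, chains, min_match = 0.5) {
  blocks <- .chain_blocks(chains)
  n <- length(gr)
  out <- data.frame(chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
                    end = rep(NA_integer_, n),
                    mapped_fraction = numeric(n), mapped = logical(n))
  if (!n || !length(blocks)) return(out)
  ov <- findOverlaps(gr, blocks, ignore.strand = TRUE)
  if (!length(ov)) return(out)
  q <- queryHits(ov); s <- subjectHits(ov)
  ov_start <- pmax(start(gr)[q], start(blocks)[s])
  ov_end <- pmin(end(gr)[q], end(blocks)[s])
  t0 <- mcols(blocks)$t_start[s] + (ov_start - mcols(blocks)$s_start[s])
  t1 <- mcols(blocks)$t_start[s] + (ov_end - mcols(blocks)$s_start[s])
  dt <- data.table(q = q, t_chrom = mcols(blocks)$t_chrom[s],
                   n_mapped = ov_end - ov_start + 1L, t0 = t0, t1 = t1)
  agg <- dt[, list(n_chrom = length(unique(t_chrom)),
                   t_chrom = t_chrom[1],
                   n_mapped = sum(n_mapped),
                   t_min = min(t0), t_max = max(t1)), by = q]
  frac <- agg$n_mapped / width(gr)[agg$q]
  ok <- agg$n_chrom == 1L & frac >= min_match
  out$mapped_fraction[agg$q] <- frac
  idx <- agg$q[ok]
  out$chrom[idx] <- agg$t_chrom[ok]
  out$start[idx] <- as.integer(agg$t_min[ok])
  out$end[idx] <- as.integer(agg$t_max[ok])
  out$mapped[idx] <- TRUE
  out
}

## liftover result as a GRanges subset (mapped rows only), keeping the
## source index
.liftover_gr <- function(gr, chains, min_match = 0.5) {
  lo <- liftover(gr, chains, min_match)
  keep <- which(lo$mapped)
  if (!length(keep)) return(GRanges(src = integer(0)))
  out <- GRanges(lo$chrom[keep], IRanges(lo$start[keep], lo$end[keep]))
  mcols(out)$src <- keep
  out
}

## best-overlap partner of each projected source bin among target bins;
## returns an integer map (NA where unmapped/no overlap), ties broken by
## the first (leftmost) target bin
.best_partner <- function(bins_from, bins_to, chains, min_match) {
  proj <- .liftover_gr(bins_from, chains, min_match)
  best <- rep(NA_integer_, length(bins_from))
  if (!length(proj)) return(best)
  ov <- findOverlaps(proj, bins_to, ignore.strand = TRUE)
  if (!length(ov)) return(best)
  w <- width(pintersect(proj[queryHits(ov)], bins_to[subjectHits(ov)]))
  dt <- data.table(src = mcols(proj)$src[queryHits(ov)],
                   to = subjectHits(ov), w = w)
  setorder(dt, src, -w, to)
  dt <- dt[!duplicated(dt$src)]
  best[dt$src] <- dt$to
  best
}

#' Reciprocal-best syntenic bins
#'
#' Pairs fixed-width bins across species by the reciprocal best method:
#' bin `a` in the hub species and bin `b` in another species form a pair iff
#' `a`'s projection overlaps `b` more than any other bin *and* `b`'s
#' back-projection overlaps `a` more than any other bin. With more than two
#' species, units are anchored on the hub (pairwise reciprocity through the
#' hub's chains, matching the mouse-centered chain sets used in practice).
#'
#' @param bins named list of per-species bin `GRanges` (tiled, fixed width).
#' @param chains_fwd named list: for each non-hub species, the hub->species
#'   `chain_set`.
#' @param chains_rev named list: species->hub `chain_set`s.
#' @param hub name of the hub species (default the first of `bins`).
#' @param min_match liftover mapped-fraction threshold.
#' @return data.frame with one row per syntenic unit: `unit` (hub bin
#'   index) and an `<species>_bin` index column per species (NA rows are
#'   dropped: every returned unit is present in all species).
#' @export
reciprocal_best_bins <- function(bins, chains_fwd, chains_rev,
                                 hub = names(bins)[1], min_match = 0.5) {
  others <- setdiff(names(bins), hub)
  res <- data.frame(unit = seq_along(bins[[hub]]))
  res[[paste0(hub, "_bin")]] <- res$unit
  for (sp in others) {
    fwd <- .best_partner(bins[[hub]], bins[[sp]], chains_fwd[[sp]], min_match)
    rev <- .best_partner(bins[[sp]], bins[[hub]], chains_rev[[sp]], min_match)
    mutual <- !is.na(fwd) & rev[ifelse(is.na(fwd), 1L, fwd)] == res$unit
    mutual[is.na(mutual)] <- FALSE
    col <- rep(NA_integer_, nrow(res))
    col[mutual] <- fwd[mutual]
    res[[paste0(sp, "_bin")]] <- col
  }
  res[stats::complete.cases(res), , drop = FALSE]
}

#' CGI identity across species
#'
#' Projects `cgi_a` into the partner genome and scores identity against
#' `cgi_b`. The default definition is the Jaccard index on the target
#' genome, `|proj(a) int b| / |proj(a) un b|`; `"overlap_smaller"`
#' (intersection over the smaller interval) and `"reciprocal"`
#' (minimum of the two overlap fractions) are available for comparison.
#' Pairs with identity strictly above 0.5 are conventionally syntenic.
#'
#' @param cgi_a,cgi_b `GRanges` of equal length (pairs scored elementwise),
#'   `cgi_a` in the source genome, `cgi_b` in the target genome.
#' @param chains source->target `chain_set`.
#' @param mode identity definition (default `"jaccard"`).
#' @param min_match liftover threshold.
#' @return numeric identity in `[0, 1]` (0 when the projection fails).
#' @export
cgi_identity <- function(cgi_a, cgi_b, chains, mode = c("jaccard",
                         "overlap_smaller", "reciprocal"), min_match = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(cgi_a) == length(cgi_b))
  lo <- liftover(cgi_a, chains, min_match)
  idn <- numeric(length(cgi_a))
  ok <- which(lo$mapped &
                lo$chrom == as.character(seqnames(cgi_b)))
  if (!length(ok)) return(idn)
  i0 <- pmax(lo$start[ok], start(cgi_b)[ok])
  i1 <- pmin(lo$end[ok], end(cgi_b)[ok])
  inter <- pmax(0L, i1 - i0 + 1L)
  wa <- lo$end[ok] - lo$start[ok] + 1L
  wb <- width(cgi_b)[ok]
  idn[ok] <- switch(mode,
    jaccard = inter / (wa + wb - inter),
    overlap_smaller = inter / pmin(wa, wb),
    reciprocal = pmin(inter / wa, inter / wb))
  idn
}

#' Match syntenic CGIs between two species
#'
#' For each CGI of species A, finds the best-identity CGI of species B after
#' projection through `chains` and keeps pairs with identity strictly above
#' `threshold`.
#'
#' @param cgis_a,cgis_b per-species CGI `GRanges`.
#' @param chains A->B `chain_set`.
#' @param threshold syntenic identity cutoff (default 0.5, strict `>`).
#' @param mode identity definition, see [cgi_identity()].
#' @param min_match liftover threshold.
#' @return data.frame with `a` (index into `cgis_a`), `b` (index into
#'   `cgis_b`) and `identity`.
#' @export
match_syntenic_cgis <- function(cgis_a, cgis_b, chains, threshold = 0.5,
                                mode = "jaccard", min_match = 0.5) {
  proj <- .liftover_gr(cgis_a, chains, min_match)
  empty <- data.frame(a = integer(0), b = integer(0), identity = numeric(0))
  if (!length(proj)) return(empty)
  ov <- findOverlaps(proj, cgis_b, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  a <- mcols(proj)$src[queryHits(ov)]
  b <- subjectHits(ov)
  idn <- cgi_identity(cgis_a[a], cgis_b[b], chains, mode = mode,
                      min_match = min_match)
  dt <- data.table(a = a, b = b, identity = idn)
  setorder(dt, a, -identity, b)
  dt <- dt[!duplicated(dt$a)]
  as.data.frame(dt[dt$identity > threshold])
}

#' Classify intervals as genic or intergenic
#'
#' Genic means overlapping an annotated gene extended to TSS..TTS + 2 kb
#' (strand-aware tail extension).
#'
#' @param iv `GRanges` to classify.
#' @param genes gene models (`TranscriptSet` or stranded span `GRanges`).
#' @param tail_extension bp added past the TTS (default 2000).
#' @return character vector, "genic" or "intergenic".
#' @export
classify_genic <- function(iv, genes, tail_extension = 2000L) {
  spans <- if (is(genes, "GRangesList")) tx_spans(genes) else genes
  ext <- resize(spans, width = width(spans) + tail_extension, fix = "start")
  ifelse(overlapsAny(iv, ext, ignore.strand = TRUE), "genic", "intergenic")
}

#' Classify CGI genomic context
#'
#' * promoter — overlaps an annotated TSS +/- `tss_window`;
#' * intragenic — within a gene body and > 500 bp from every TSS;
#' * proximal — within a gene body, closer than 500 bp to a TSS but not a
#'   promoter hit (the dead zone between the two published rules, labeled
#'   rather than silently merged);
#' * genic/intergenic — otherwise, by gene-body overlap.
#'
#' @param iv `GRanges` of CGIs.
#' @param genes gene models (`TranscriptSet` or stranded span `GRanges`).
#' @param tss_window promoter half-window (default 500 bp; 100 bp is the
#'   stricter published alternative).
#' @param intragenic_min_tss_dist distance from a TSS beyond which an
#'   in-gene CGI counts as intragenic.
#' @return character vector of contexts.
#' @export
classify_cgi_context <- function(iv, genes, tss_window = 500L,
                                 intragenic_min_tss_dist = 500L) {
  spans <- if (is(genes, "GRangesList")) tx_spans(genes) else genes
  tss <- resize(spans, width = 1L, fix = "start")
  prom <- resize(tss, width = 2L * tss_window + 1L, fix = "center")
  trim(prom)
  is_prom <- overlapsAny(iv, prom, ignore.strand = TRUE)
  in_gene <- overlapsAny(iv, spans, ignore.strand = TRUE)
  d <- rep(Inf, length(iv))
  if (length(tss)) {
    nr <- distanceToNearest(iv, tss, ignore.strand = TRUE)
    d[queryHits(nr)] <- mcols(nr)$distance
  }
  out <- rep("intergenic", length(iv))
  out[in_gene] <- "proximal"
  out[in_gene & d > intragenic_min_tss_dist] <- "intragenic"
  out[is_prom] <- "promoter"
  out
}
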