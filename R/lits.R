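## LIONS-style classification of assembled transcripts by the relationship
## of their 5' ends to LTR repeats, LTR contribution ratios, gene chimerism
## calls, the active solo-LTR scan, and the hyper-domain rescue tier.

#' Classify transcript 5' ends against LTR repeats
#'
#' Operational reimplementation of the Up / UpEdge / EInside categories:
#' * **Up** — the strand-aware TSS lies inside an LTR-class repeat and
#'   exon 1 extends 3' beyond the repeat;
#' * **UpEdge** — the TSS lies outside but within `edge_window` bp of a
#'   repeat edge;
#' * **EInside** — a repeat is wholly contained in a non-first exon, or
#'   inside exon 1 without containing the TSS;
#' * **none** otherwise.
#' When several repeats qualify, the repeat containing (else nearest to)
#' the TSS wins. Only repeats with an LTR `repeat_class` (not "other")
#' are considered; ERV-internal segments share those classes and count.
#'
#' @param txs a `TranscriptSet`.
#' @param repeats repeat annotation `GRanges` (see [read_repeatmasker()]).
#' @param edge_window UpEdge boundary window in bp.
#' @return data.frame with `category` and `repeat_idx` (index into
#'   `repeats`, `NA` for category "none").
#' @export
classify_transcript_start <- function(txs, repeats, edge_window = 100L) {
  if (any(lengths(txs) == 0L)) .lm_stop("transcript with no exons")
  n <- length(txs)
  category <- rep("none", n)
  repeat_idx <- rep(NA_integer_, n)
  if (n == 0L) return(data.frame(category = character(0), repeat_idx = integer(0)))
  ltr <- which(mcols(repeats)$repeat_class != "other")
  reps <- repeats[ltr]
  tss <- tx_tss(txs)
  strand(tss) <- "*"
  spans <- tx_spans(txs)
  all_ex <- unlist(txs, use.names = FALSE)
  first_idx <- cumsum(lengths(txs)) - lengths(txs) + 1L
  exon1 <- all_ex[first_idx]
  plus <- as.character(strand(spans)) == "+"

  ## Up: TSS contained in repeat, exon 1 extends past its 3' edge
  ov <- findOverlaps(tss, reps, ignore.strand = TRUE)
  if (length(ov)) {
    q <- queryHits(ov); s <- subjectHits(ov)
    extends <- ifelse(plus[q], end(exon1)[q] > end(reps)[s],
                      start(exon1)[q] < start(reps)[s])
    cand <- data.table(q = q, s = s, up = extends)
    ## the containing repeat wins; prefer an Up-qualifying one
    cand <- cand[order(q, -up)]
    first <- cand[!duplicated(cand$q)]
    upq <- first$q[first$up]
    category[upq] <- "Up"
    repeat_idx[upq] <- ltr[first$s[first$up]]
    ## TSS inside a repeat that exon 1 never leaves: treated below for EInside
    inq <- first$q[!first$up]
    repeat_idx[inq] <- ltr[first$s[!first$up]]  # provisional anchor
  }

  ## UpEdge: TSS outside every repeat but within the edge window of one
  open <- which(category == "none" & is.na(repeat_idx))
  if (length(open) && length(reps)) {
    nr <- distanceToNearest(tss[open], reps, ignore.strand = TRUE)
    hit <- which(mcols(nr)$distance > 0L & mcols(nr)$distance <= edge_window)
    category[open[queryHits(nr)[hit]]] <- "UpEdge"
    repeat_idx[open[queryHits(nr)[hit]]] <- ltr[subjectHits(nr)[hit]]
  }

  ## EInside: repeat wholly inside a non-first exon, or inside exon 1
  ## without containing the TSS
  open <- which(!category %in% c("Up", "UpEdge"))
  if (length(open) && length(reps)) {
    ex <- unlist(txs[open], use.names = FALSE)
    tx_of <- rep(seq_along(open), lengths(txs[open]))
    rank <- unlist(lapply(lengths(txs[open]), seq_len))
    ovw <- findOverlaps(reps, ex, type = "within", ignore.strand = TRUE)
    if (length(ovw)) {
      r <- queryHits(ovw); e <- subjectHits(ovw)
      tss_in <- start(tss)[open[tx_of[e]]] >= start(reps)[r] &
        start(tss)[open[tx_of[e]]] <= end(reps)[r] &
        as.character(seqnames(tss))[open[tx_of[e]]] ==
          as.character(seqnames(reps))[r]
      ok <- (rank[e] > 1L) | (rank[e] == 1L & !tss_in)
      if (any(ok)) {
        hit <- data.table(q = tx_of[e][ok], s = r[ok])
        hit <- hit[!duplicated(hit$q)]
        category[open[hit$q]] <- "EInside"
        repeat_idx[open[hit$q]] <- ltr[hit$s]
      }
    }
  }
  repeat_idx[category == "none"] <- NA_integer_
  data.frame(category = category, repeat_idx = repeat_idx)
}

#' LTR contribution of a chimeric transcript
#'
#' Read coverage on exon 1 (the LTR) relative to the first annotated
#' canonical exon. Returns the raw coverage ratio and a `[0, 1]`-normalized
#' contribution `ratio / (1 + ratio)`; with canonical coverage 0 the share
#' is 1 with a degenerate-denominator flag, and with both coverages 0 the
#' value is undefined (flagged `NA`).
#'
#' @param exon1_cov mean per-base read coverage of the LIT's first exon.
#' @param canonical_cov mean coverage of the gene's first canonical exon.
#' @return data.frame with `ratio`, `contribution`, `flag`.
#' @export
ltr_contribution <- function(exon1_cov, canonical_cov) {
  .check_nonneg(exon1_cov); .check_nonneg(canonical_cov)
  n <- max(length(exon1_cov), length(canonical_cov))
  a <- rep_len(exon1_cov, n); b <- rep_len(canonical_cov, n)
  ratio <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, NA_real_))
  contribution <- ifelse(is.na(ratio), NA_real_,
                         ifelse(is.infinite(ratio), 1, ratio / (1 + ratio)))
  flag <- ifelse(is.na(ratio), "undefined",
                 ifelse(is.infinite(ratio), "zero_canonical", "ok"))
  data.frame(ratio = ratio, contribution = contribution, flag = flag)
}

#' Call LTR-initiated transcription units
#'
#' Keeps transcripts whose 5' ends classify as Up or UpEdge (the
#' high-specificity filter), then labels their relationship to annotated
#' genes: `sense-chimeric` when a non-first LIT exon shares >= 1 bp with an
#' exon of a same-strand gene *and* the LIT contributes more than
#' `min_share` of the gene's summed isoform FPKM; `antisense` when the LIT
#' overlaps a gene on the opposite strand; `intergenic` otherwise.
#'
#' @param transcripts assembled `TranscriptSet` (with `fpkm`).
#' @param repeats repeat annotation `GRanges`.
#' @param genes annotated gene models, a `TranscriptSet`.
#' @param min_share isoform-share threshold (default 0.10, strict `>`).
#' @param coverage optional named list: per transcript id, a numeric vector
#'   of mean per-exon read coverage (used for the contribution ratio).
#' @param edge_window UpEdge window, see [classify_transcript_start()].
#' @return data.frame of LIT calls (one row per accepted transcript).
#' @export
call_lits <- function(transcripts, repeats, genes, min_share = 0.10,
                      coverage = NULL, edge_window = 100L) {
  cls <- classify_transcript_start(transcripts, repeats, edge_window)
  keep <- which(cls$category %in% c("Up", "UpEdge"))
  empty <- data.frame(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), fpkm = numeric(0),
                      category = character(0), repeat_subfamily = character(0),
                      repeat_class = character(0), gene_id = character(0),
                      gene_overlap = character(0), isoform_share = numeric(0),
                      contribution = numeric(0), stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  lit_tx <- transcripts[keep]
  spans <- tx_spans(lit_tx)
  gene_spans <- tx_spans(genes)
  gene_fpkm_tot <- tapply(mcols(genes)$fpkm, mcols(genes)$gene_id, sum)

  ## sense: non-first LIT exon vs annotated exon, same strand
  gene_ex <- unlist(genes, use.names = FALSE)
  gene_ex_gene <- rep(mcols(genes)$gene_id, lengths(genes))
  lit_ex <- unlist(lit_tx, use.names = FALSE)
  lit_ex_tx <- rep(seq_along(lit_tx), lengths(lit_tx))
  lit_ex_rank <- unlist(lapply(lengths(lit_tx), seq_len))
  rest_ex <- lit_ex[lit_ex_rank > 1L]
  rest_tx <- lit_ex_tx[lit_ex_rank > 1L]
  sense_gene <- rep(NA_character_, length(lit_tx))
  if (length(rest_ex) && length(gene_ex)) {
    ovs <- findOverlaps(rest_ex, gene_ex)  # strand-aware
    if (length(ovs)) {
      hit <- data.table(tx = rest_tx[queryHits(ovs)],
                        gene = gene_ex_gene[subjectHits(ovs)])
      hit <- hit[!duplicated(hit$tx)]
      sense_gene[hit$tx] <- hit$gene
    }
  }
  lit_fpkm <- mcols(lit_tx)$fpkm
  gene_tot <- ifelse(is.na(sense_gene), NA_real_,
                     unname(gene_fpkm_tot[sense_gene]))
  isoform_share <- ifelse(is.na(sense_gene), NA_real_,
                          lit_fpkm / (gene_tot + lit_fpkm))
  isoform_share[!is.na(gene_tot) & gene_tot == 0 & lit_fpkm > 0] <- 1

  ## antisense: span overlap with an opposite-strand gene
  flipped <- spans
  strand(flipped) <- ifelse(as.character(strand(spans)) == "+", "-", "+")
  anti <- overlapsAny(flipped, gene_spans)
  anti_gene <- rep(NA_character_, length(lit_tx))
  ova <- findOverlaps(flipped, gene_spans)
  if (length(ova)) {
    hit <- data.table(tx = queryHits(ova),
                      gene = mcols(genes)$gene_id[subjectHits(ova)])
    hit <- hit[!duplicated(hit$tx)]
    anti_gene[hit$tx] <- hit$gene
  }

  sense_ok <- !is.na(sense_gene) & !is.na(isoform_share) &
    isoform_share > min_share
  gene_overlap <- ifelse(sense_ok, "sense-chimeric",
                         ifelse(anti, "antisense", "intergenic"))
  gene_id <- ifelse(sense_ok, sense_gene,
                    ifelse(anti, anti_gene, NA_character_))

  ## contribution ratio where exon coverage is available
  contribution <- rep(NA_real_, length(lit_tx))
  if (!is.null(coverage)) {
    canon_first_cov <- .first_canonical_exon_cov(genes, coverage)
    for (k in which(sense_ok)) {
      cov_t <- coverage[[mcols(lit_tx)$transcript_id[k]]]
      cov_g <- canon_first_cov[[sense_gene[k]]]
      if (!is.null(cov_t) && !is.null(cov_g)) {
        contribution[k] <- ltr_contribution(cov_t[1], cov_g)$contribution
      }
    }
  }
  ridx <- cls$repeat_idx[keep]
  data.frame(
    transcript_id = mcols(lit_tx)$transcript_id,
    chrom = as.character(seqnames(spans)),
    start = start(spans), end = end(spans),
    strand = as.character(strand(spans)),
    fpkm = lit_fpkm,
    category = cls$category[keep],
    repeat_subfamily = mcols(repeats)$subfamily[ridx],
    repeat_class = mcols(repeats)$repeat_class[ridx],
    gene_id = gene_id,
    gene_overlap = gene_overlap,
    isoform_share = isoform_share,
    contribution = contribution,
    stringsAsFactors = FALSE)
}

## mean coverage of the first canonical exon of each gene (highest-FPKM
## isoform representative)
.first_canonical_exon_cov <- function(genes, coverage) {
  out <- list()
  gid <- mcols(genes)$gene_id
  for (g in unique(gid)) {
    iso <- which(gid == g)
    best <- iso[which.max(mcols(genes)$fpkm[iso])]
    cov <- coverage[[mcols(genes)$transcript_id[best]]]
    if (!is.null(cov)) out[[g]] <- cov[1]
  }
  out
}

#' Scan for transcriptionally active LTRs
#'
#' Returns all annotated repeats with transcript levels strictly above
#' `min_fpkm` (default 1 FPKM), the totality-of-active-LTR estimate that
#' complements assembly-based LIT calling.
#'
#' @param repeats repeat annotation `GRanges`.
#' @param fpkm per-repeat expression over the repeat span.
#' @param min_fpkm activity threshold (strict `>`).
#' @return subset of `repeats` with an `fpkm` metadata column.
#' @export
active_ltr_scan <- function(repeats, fpkm, min_fpkm = 1) {
  stopifnot(length(fpkm) == length(repeats))
  keep <- !is.na(fpkm) & fpkm > min_fpkm
  out <- repeats[keep]
  mcols(out)$fpkm <- fpkm[keep]
  out
}

#' Class composition of a repeat set
#'
#' @param repeats `GRanges` with a `repeat_class` column.
#' @return named fractions summing to 1 (empty input gives an empty vector).
#' @export
ltr_class_composition <- function(repeats) {
  if (!length(repeats)) return(numeric(0))
  tab <- table(mcols(repeats)$repeat_class)
  setNames(as.numeric(tab) / length(repeats), names(tab))
}

#' Rescue LIT candidates from hypermethylated domain boundaries
#'
#' Secondary evidence tier: transcripts whose 5' end lies within `window`
#' bp of the 5' boundary (in transcript orientation) of a hypermethylated
#' domain and whose TSS overlaps an LTR repeat are flagged as
#' manual-inspection candidates. Transcripts already called Up/UpEdge are
#' never duplicated here.
#'
#' @param transcripts assembled `TranscriptSet`.
#' @param hyper_domains `GRanges` of domains with `meth_class` (only
#'   "hyper" rows are used).
#' @param repeats repeat annotation `GRanges`.
#' @param window boundary window in bp.
#' @param primary_calls optional data.frame from [call_lits()] whose
#'   transcript ids are excluded.
#' @return character vector of candidate transcript ids.
#' @export
rescue_lits_by_domain <- function(transcripts, hyper_domains, repeats,
                                  window = 1000L, primary_calls = NULL) {
  hyper <- hyper_domains[mcols(hyper_domains)$meth_class == "hyper"]
  if (!length(hyper) || !length(transcripts)) return(character(0))
  tss <- tx_tss(transcripts)
  plus <- as.character(strand(tss)) == "+"
  edge <- ifelse(plus, start(hyper)[nearest(tss, hyper, ignore.strand = TRUE)],
                 end(hyper)[nearest(tss, hyper, ignore.strand = TRUE)])
  inside <- overlapsAny(tss, hyper, ignore.strand = TRUE)
  near_edge <- !is.na(edge) & abs(start(tss) - edge) <= window & inside
  ltr <- repeats[mcols(repeats)$repeat_class != "other"]
  on_ltr <- overlapsAny(tss, ltr, ignore.strand = TRUE)
  ids <- mcols(transcripts)$transcript_id[near_edge & on_ltr]
  if (!is.null(primary_calls)) ids <- setdiff(ids, primary_calls$transcript_id)
  ids
}
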