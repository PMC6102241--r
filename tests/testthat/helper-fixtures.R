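## Shared fixtures, built in code. Heavier simulated cohorts are memoized
## per session so several test files can reuse one simulation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## a minimal MethTable on one chromosome
toy_meth <- function(pos, meth, total, chrom = "chr1", seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  if (!is.null(seqlen)) {
    seqlevels(gr) <- chrom
    seqlengths(gr) <- setNames(seqlen, chrom)
  }
  meth_table(gr, meth, total)
}

## a TranscriptSet from a compact exon description:
## list(id = list(strand, exon starts, exon ends))
toy_txs <- function(desc, chrom = "chr1", fpkm = NULL, gene_id = NULL) {
  rows <- lapply(names(desc), function(id) {
    d <- desc[[id]]
    GRanges(chrom, IRanges(d[[2]], d[[3]]), strand = d[[1]])
  })
  ex <- do.call(c, rows)
  n <- vapply(rows, length, 1L)
  transcript_set(ex, rep(names(desc), n),
                 rep_len(gene_id %||% NA_character_, length(ex)),
                 rep_len(fpkm %||% 1, length(ex)))
}

toy_repeats <- function(starts, ends, chrom = "chr1", strand = "+",
                        repeat_class = "LTR-MaLR", subfamily = "MTA") {
  gr <- GRanges(chrom, IRanges(starts, ends), strand = strand)
  mcols(gr) <- DataFrame(
    repeat_class = rep_len(repeat_class, length(gr)),
    subfamily = rep_len(subfamily, length(gr)),
    annotation_source = "fixture")
  gr
}

## a single-chain chain_set with the given absolute 1-based blocks
toy_chain <- function(blocks, s_chrom = "chr1", t_chrom = "chr1",
                      s_size = 1e6, t_size = 1e6) {
  bl <- as.data.frame(blocks)
  structure(list(list(
    score = 1000, s_chrom = s_chrom, s_size = s_size,
    s_start = bl$s_start[1] - 1, s_end = bl$s_start[nrow(bl)] + bl$len[nrow(bl)] - 1,
    t_chrom = t_chrom, t_size = t_size,
    t_start = bl$t_start[1] - 1, t_end = bl$t_start[nrow(bl)] + bl$len[nrow(bl)] - 1,
    chain_id = "1", blocks = bl)), class = "chain_set")
}

## memoized default three-species cohort (shared by several test files)
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    spec <- cohort_spec(seed = 42L)
    .fixture_env$cohort <- simulate_cohort(spec, tissues = c(
      "oocyte", "sperm", "pg_blastocyst", "blastocyst", "epiblast",
      "epiblast_tetko"))
  }
  .fixture_env$cohort
}

fixture_result <- function() {
  if (is.null(.fixture_env$result)) {
    .fixture_env$result <- run_cohort_analysis(fixture_cohort())
  }
  .fixture_env$result
}
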