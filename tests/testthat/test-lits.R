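test_that("transcript 5' classification follows the Up/UpEdge/EInside rules", {
  reps <- toy_repeats(starts = c(1000L, 8000L, 20000L),
                      ends = c(1500L, 8400L, 20400L))
  txs <- toy_txs(list(
    up = list("+", c(1250L, 4000L), c(3500L, 4500L)),       # TSS mid-repeat
    upedge = list("+", c(950L, 4000L), c(3500L, 4500L)),    # TSS 50 bp out
    einside = list("+", c(5000L, 7900L), c(5400L, 8600L)),  # repeat in exon 2
    none = list("+", c(30000L, 31000L), c(30400L, 31400L))))
  cls <- classify_transcript_start(txs, reps, edge_window = 100L)
  idx <- match(c("up", "upedge", "einside", "none"),
               mcols(txs)$transcript_id)
  expect_equal(cls$category[idx], c("Up", "UpEdge", "EInside", "none"))
  expect_equal(cls$repeat_idx[idx[1:3]], c(1L, 1L, 2L))
  expect_true(is.na(cls$repeat_idx[idx[4]]))

  ## minus-strand Up: TSS inside the repeat, exon 1 extends leftward past it
  txm <- toy_txs(list(m = list("-", c(18000L, 19000L), c(18400L, 20200L))))
  expect_equal(classify_transcript_start(txm, reps)$category, "Up")

  expect_error(classify_transcript_start(GRangesList(GRanges()), reps),
               "no exons")
})

test_that("classification is antisymmetric under coordinate mirroring", {
  L <- 50000L
  reps <- toy_repeats(starts = c(1000L, 8000L), ends = c(1500L, 8400L))
  txs <- toy_txs(list(
    a = list("+", c(1250L, 4000L), c(3500L, 4500L)),
    b = list("+", c(950L, 4000L), c(3500L, 4500L)),
    c = list("-", c(30000L, 31000L), c(30400L, 31400L))))
  mirror_gr <- function(gr) {
    out <- GRanges(seqnames(gr), IRanges(L + 1L - end(gr), L + 1L - start(gr)),
                   strand = ifelse(as.character(strand(gr)) == "+", "-", "+"))
    mcols(out) <- mcols(gr)
    out
  }
  reps_m <- mirror_gr(reps)
  ex <- unlist(txs, use.names = FALSE)
  txs_m <- transcript_set(mirror_gr(ex),
                          rep(mcols(txs)$transcript_id, lengths(txs)),
                          fpkm = 1)
  a <- classify_transcript_start(txs, reps)
  b <- classify_transcript_start(txs_m, reps_m)
  ord_a <- order(mcols(txs)$transcript_id)
  ord_b <- order(mcols(txs_m)$transcript_id)
  expect_equal(a$category[ord_a], b$category[ord_b])
})

test_that("LTR contribution is the stated coverage ratio with safe degenerate cases", {
  r <- ltr_contribution(10, 40)
  expect_equal(r$ratio, 0.25)
  expect_equal(r$contribution, 0.25 / 1.25)
  expect_equal(r$flag, "ok")
  r0 <- ltr_contribution(5, 0)
  expect_equal(r0$contribution, 1)
  expect_equal(r0$flag, "zero_canonical")
  rna <- ltr_contribution(0, 0)
  expect_true(is.na(rna$contribution))
  expect_equal(rna$flag, "undefined")
})

test_that("LIT calling applies the isoform-share rule and labels gene overlap", {
  reps <- toy_repeats(starts = 1000L, ends = 1500L)
  gene <- toy_txs(list(gA = list("+", c(6000L, 9000L, 12000L),
                                 c(6300L, 9300L, 12400L))),
                  fpkm = 45, gene_id = "gA")
  mk_lit <- function(fpkm) {
    toy_txs(list(lit1 = list("+", c(1200L, 9000L), c(2500L, 9300L))),
            fpkm = fpkm)
  }
  ## 45 * 0.08/0.92 puts the LIT just below a 10% share of all isoforms
  low <- call_lits(mk_lit(45 * 0.08 / 0.92), reps, gene, min_share = 0.10)
  expect_equal(low$gene_overlap, "intergenic")
  hi <- call_lits(mk_lit(20), reps, gene, min_share = 0.10)
  expect_equal(hi$gene_overlap, "sense-chimeric")
  expect_equal(hi$gene_id, "gA")
  expect_equal(hi$isoform_share, 20 / 65, tolerance = 1e-12)

  ## LIT as the only isoform: share 1 (degenerate denominator)
  gene0 <- toy_txs(list(gA = list("+", c(6000L, 9000L), c(6300L, 9300L))),
                   fpkm = 0, gene_id = "gA")
  only <- call_lits(mk_lit(5), reps, gene0, min_share = 0.10)
  expect_equal(only$isoform_share, 1)

  ## antisense: overlap with an opposite-strand gene
  anti_gene <- toy_txs(list(gB = list("-", c(1800L, 2600L), c(2200L, 3000L))),
                       fpkm = 10, gene_id = "gB")
  anti <- call_lits(mk_lit(5), reps, anti_gene, min_share = 0.10)
  expect_equal(anti$gene_overlap, "antisense")

  ## output is invariant to transcript input order
  both <- toy_txs(list(
    lit1 = list("+", c(1200L, 9000L), c(2500L, 9300L)),
    zzz = list("+", c(30000L), c(30500L))), fpkm = c(20, 20, 1))
  swapped <- both[c(2, 1)]
  c1 <- call_lits(both, reps, gene)
  c2 <- call_lits(swapped, reps, gene)
  expect_equal(c1[order(c1$transcript_id), ], c2[order(c2$transcript_id), ],
               ignore_attr = TRUE)
})

test_that("active LTR scan applies a strict >1 FPKM cutoff", {
  reps <- toy_repeats(starts = c(100L, 700L, 1300L), ends = c(400L, 1000L, 1600L),
                      repeat_class = c("LTR-MaLR", "LTR-ERVK", "LTR-MaLR"))
  act <- active_ltr_scan(reps, fpkm = c(1.0, 1.01, 0))
  expect_equal(length(act), 1L)             # exactly 1.0 excluded
  expect_equal(mcols(act)$fpkm, 1.01)
  expect_length(active_ltr_scan(reps, fpkm = c(0, 0, 0)), 0L)
  comp <- ltr_class_composition(reps)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
})

test_that("domain-boundary rescue flags candidates without duplicating calls", {
  reps <- toy_repeats(starts = 10000L, ends = 10400L)
  dom <- GRanges("chr1", IRanges(c(1L, 10001L), c(9000L, 30000L)),
                 meth_class = c("hypo", "hyper"))
  txs <- toy_txs(list(
    cand = list("+", c(10200L, 15000L), c(12000L, 15500L)),  # TSS near 5' edge, on LTR
    outside = list("+", c(40000L), c(41000L))))
  ids <- rescue_lits_by_domain(txs, dom, reps, window = 1000L)
  expect_equal(ids, "cand")
  ## a transcript already called Up/UpEdge is never duplicated
  primary <- data.frame(transcript_id = "cand")
  expect_length(rescue_lits_by_domain(txs, dom, reps, window = 1000L,
                                      primary_calls = primary), 0L)
})

test_that("no LITs are called when none are planted", {
  spec <- cohort_spec(species = "mouse", genome_length = 3e6, n_chrom = 1L,
                      n_genes = 80L, n_ancestral_ltrs = 30L,
                      n_branch_ltrs = c(mouse = 15L), p_active = 0,
                      seed = 19L)
  ann <- simulate_annotations(spec)
  tx <- simulate_transcriptome(ann)
  d <- tx$transcripts$mouse
  calls <- call_lits(d, ann$species$mouse$repeats,
                     d[!is.na(mcols(d)$gene_id)])
  expect_equal(nrow(tx$truth$lits), 0L)
  expect_equal(nrow(calls), 0L)
})
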