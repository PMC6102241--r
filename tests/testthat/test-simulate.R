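test_that("simulation is deterministic under a fixed seed", {
  spec <- cohort_spec(genome_length = 1e6, n_chrom = 1L, n_genes = 20L,
                      n_ancestral_ltrs = 10L,
                      n_branch_ltrs = c(pair = 4L, mouse = 6L, rat = 5L,
                                        human = 5L),
                      seed = 77L)
  a <- simulate_cohort(spec, tissues = "oocyte")
  b <- simulate_cohort(spec, tissues = "oocyte")
  expect_identical(a$truth$ltrs, b$truth$ltrs)
  expect_identical(a$truth$lits, b$truth$lits)
  expect_identical(mcols(a$meth$mouse$oocyte)$meth,
                   mcols(b$meth$mouse$oocyte)$meth)
  ## a different seed gives a different genome
  spec2 <- spec; spec2$seed <- 78L
  c2 <- simulate_annotations(spec2)
  expect_false(identical(a$annotations$truth$ltrs, c2$truth$ltrs))
})

test_that("zero private insertions give identical annotations and identity chains", {
  spec <- cohort_spec(genome_length = 1e6, n_chrom = 1L, n_genes = 20L,
                      n_ancestral_ltrs = 12L,
                      n_branch_ltrs = c(pair = 0L, mouse = 0L, rat = 0L,
                                        human = 0L),
                      seed = 5L)
  ann <- simulate_annotations(spec)
  gm <- tx_spans(ann$species$mouse$genes)
  gr <- tx_spans(ann$species$rat$genes)
  expect_equal(start(gm), start(gr))
  expect_equal(end(gm), end(gr))
  ch <- ann$chains$mouse$human
  expect_equal(length(ch), 1L)
  expect_equal(nrow(ch[[1]]$blocks), 1L)
  expect_equal(ch[[1]]$blocks$s_start, ch[[1]]$blocks$t_start)
})

test_that("every planted LIT has its 5' end anchored in the named LTR", {
  co <- fixture_cohort()
  lits <- co$truth$lits
  tr <- co$truth$ltrs
  for (r in seq_len(nrow(lits))) {
    row <- lits[r, ]
    k <- match(row$ltr_id, tr$ltr_id)
    ls <- tr[[paste0("start_", row$species)]][k]
    le <- tr[[paste0("end_", row$species)]][k]
    if (row$category_truth == "Up") {
      expect_true(row$tss >= ls && row$tss <= le)
    } else {
      expect_true(min(abs(row$tss - ls), abs(row$tss - le)) <= 100L)
    }
  }
  ## ...and corresponds to exactly one emitted transcript
  for (s in unique(lits$species)) {
    ids <- mcols(co$transcripts[[s]])$transcript_id
    expect_true(all(lits$transcript_id[lits$species == s] %in% ids))
    expect_false(any(duplicated(lits$transcript_id[lits$species == s])))
  }
})

test_that("oocyte methylation is bimodal with modes near the model means", {
  co <- fixture_cohort()
  m <- co$meth$mouse$oocyte
  deep <- mcols(m)$total >= 10
  f <- (mcols(m)$meth / mcols(m)$total)[deep]
  d <- density(f, from = 0, to = 1)
  lo_mode <- d$x[which.max(d$y[d$x < 0.4])]
  hi_mode <- d$x[d$x > 0.5][which.max(d$y[d$x > 0.5])]
  expect_lt(abs(lo_mode - 0.05), 0.1)
  expect_lt(abs(hi_mode - 0.85), 0.1)
})

test_that("zero depth drops everything downstream of the coverage filters", {
  spec <- cohort_spec(genome_length = 6e5, n_chrom = 1L, n_genes = 12L,
                      n_ancestral_ltrs = 6L,
                      n_branch_ltrs = c(pair = 2L, mouse = 2L, rat = 2L,
                                        human = 2L),
                      mean_depth = 0, seed = 9L)
  co <- simulate_cohort(spec, tissues = "oocyte")
  m <- co$meth$mouse$oocyte
  expect_true(all(mcols(m)$total == 0L))
  b <- score_bins(m, 1000L, min_cpgs = 5L, min_depth = 5L,
                  seqlens = co$annotations$species$mouse$seqlens)
  expect_false(any(mcols(b)$passes_filter))
})

test_that("retained CGIs exceed erased CGIs in blastocyst methylation", {
  co <- fixture_cohort()
  tr <- co$truth$cgis[co$truth$cgis$species == "mouse", ]
  cgis <- co$annotations$species$mouse$cgis
  pg <- region_methylation(cgis, co$meth$mouse$pg_blastocyst,
                           min_depth = 5L, min_cpgs = 6L)$mean_meth
  idx <- match(tr$cgi_id, mcols(cgis)$cgi_id)
  ret <- pg[idx[tr$methylated & tr$retained]]
  era <- pg[idx[tr$methylated & !tr$retained]]
  expect_gt(mean(ret, na.rm = TRUE), mean(era, na.rm = TRUE) + 0.3)
})

test_that("sperm is hypermethylated except CpG islands", {
  co <- fixture_cohort()
  sp <- co$meth$mouse$sperm
  cgis <- co$annotations$species$mouse$cgis
  in_cgi <- overlapsAny(sp, cgis, ignore.strand = TRUE)
  f <- mcols(sp)$meth / pmax(1L, mcols(sp)$total)
  expect_gt(mean(f[!in_cgi & mcols(sp)$total >= 5]), 0.85)
  expect_lt(mean(f[in_cgi & mcols(sp)$total >= 5]), 0.05)
})

test_that("orphan hyper territory overlaps no gene or LIT in any species", {
  co <- fixture_cohort()
  for (s in co$spec$species) {
    orph <- co$truth$orphans[[s]]
    if (!length(orph)) next
    genes <- tx_spans(co$annotations$species[[s]]$genes)
    expect_false(any(overlapsAny(orph, genes, ignore.strand = TRUE)))
    lits <- co$truth$lits[co$truth$lits$species == s, ]
    if (nrow(lits)) {
      lit_gr <- GRanges(lits$chrom, IRanges(lits$span_start, lits$span_end))
      expect_false(any(overlapsAny(orph, lit_gr, ignore.strand = TRUE)))
    }
  }
})
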