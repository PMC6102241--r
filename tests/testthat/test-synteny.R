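test_that("liftover translates colinear blocks exactly and honors min_match", {
  ## identity block
  ch <- toy_chain(data.frame(s_start = 1, t_start = 1, len = 10000))
  iv <- GRanges("chr1", IRanges(500, 999))
  lo <- liftover(iv, ch)
  expect_true(lo$mapped)
  expect_equal(c(lo$start, lo$end), c(500L, 999L))

  ## offset translation with length preserved inside one block
  ch2 <- toy_chain(data.frame(s_start = 1000, t_start = 5000, len = 2000))
  lo2 <- liftover(GRanges("chr1", IRanges(1200, 1399)), ch2)
  expect_equal(c(lo2$start, lo2$end), c(5200L, 5399L))
  expect_equal(lo2$end - lo2$start, 199L)

  ## interval spanning a 200 bp target-side insertion: covering span
  ch3 <- toy_chain(data.frame(s_start = c(1, 1001), t_start = c(1, 1201),
                              len = c(1000, 1000)))
  lo3 <- liftover(GRanges("chr1", IRanges(900, 1100)), ch3)
  expect_true(lo3$mapped)
  expect_equal(c(lo3$start, lo3$end), c(900L, 1300L))
  expect_equal(lo3$mapped_fraction, 1)

  ## entirely inside a chain gap (source-side insertion): none
  ch4 <- toy_chain(data.frame(s_start = c(1, 2001), t_start = c(1, 1001),
                              len = c(1000, 1000)))
  expect_false(liftover(GRanges("chr1", IRanges(1100, 1900)), ch4)$mapped)
  ## mostly in the gap: mapped fraction below 0.5 -> none
  expect_false(liftover(GRanges("chr1", IRanges(1100, 2199)), ch4)$mapped)
  lo5 <- liftover(GRanges("chr1", IRanges(1900, 2300)), ch4)
  expect_true(lo5$mapped)   # 300/401 bases mapped
})

test_that("liftover agrees with the per-base oracle on cohort chains", {
  spec <- cohort_spec(seed = 23L)
  ann <- simulate_annotations(spec)
  chains <- ann$chains$mouse$rat
  sl <- ann$species$mouse$seqlens
  set.seed(14)
  for (r in 1:60) {
    chr <- sample(names(sl), 1)
    w <- sample(c(10L, 200L, 1500L), 1)
    st <- sample.int(sl[[chr]] - w, 1)
    iv <- GRanges(chr, IRanges(st, st + w - 1L))
    mine <- liftover(iv, chains)
    want <- liftover_oracle(iv, chains)
    if (is.null(want)) {
      expect_false(mine$mapped)
    } else {
      expect_true(mine$mapped)
      expect_equal(mine$start, as.integer(want[["start"]]))
      expect_equal(mine$end, as.integer(want[["end"]]))
    }
  }
})

test_that("reciprocal-best bins pair positional twins on identity chains", {
  idA <- toy_chain(data.frame(s_start = 1, t_start = 1, len = 50000))
  bins <- tileGenome(c(chr1 = 50000L), tilewidth = 1000L,
                     cut.last.tile.in.chrom = TRUE)
  units <- reciprocal_best_bins(list(a = bins, b = bins),
                                chains_fwd = list(b = idA),
                                chains_rev = list(b = idA), hub = "a")
  expect_equal(nrow(units), 50L)
  expect_equal(units$a_bin, units$b_bin)

  ## pairing is a partial matching: no target bin appears twice
  expect_false(any(duplicated(units$b_bin)))
})

test_that("bins inside a species-private insertion have no syntenic partner", {
  spec <- cohort_spec(seed = 31L)
  ann <- simulate_annotations(spec)
  ## a mouse-private insertion occupies mouse coordinates absent from rat
  ins <- ann$truth$ltrs[ann$truth$ltrs$branch == "mouse", ][1, ]
  gap_chain <- ann$chains$mouse$rat
  iv <- GRanges(ins$chrom, IRanges(ins$start_mouse, ins$end_mouse))
  expect_false(liftover(iv, gap_chain)$mapped)
  ## the rat->mouse chain carries a gap exactly spanning that insertion
  blocks <- do.call(rbind, lapply(gap_chain, function(c_)
    if (c_$s_chrom == ins$chrom) c_$blocks))
  gap_edges <- blocks$s_start + blocks$len
  expect_true(any(gap_edges == ins$start_mouse &
                    c(blocks$s_start[-1], Inf) == ins$end_mouse + 1))
})

test_that("CGI identity is the projected Jaccard with a strict 0.5 cutoff", {
  id <- toy_chain(data.frame(s_start = 1, t_start = 1, len = 100000))
  a <- GRanges("chr1", IRanges(1000, 1099))
  ## perfectly conserved island
  expect_equal(cgi_identity(a, a, id), 1)
  ## 100 bp island overlapping a 100 bp island by 50 bp: 50/150, not syntenic
  b <- GRanges("chr1", IRanges(1050, 1149))
  expect_equal(cgi_identity(a, b, id), 50 / 150, tolerance = 1e-12)
  m <- match_syntenic_cgis(a, b, id)
  expect_equal(nrow(m), 0L)
  ## disjoint
  expect_equal(cgi_identity(a, GRanges("chr1", IRanges(5000, 5099)), id), 0)
  ## symmetric under direction swap on identity chains
  expect_equal(cgi_identity(a, b, id), cgi_identity(b, a, id))
  ## alternative identity definitions
  expect_equal(cgi_identity(a, b, id, mode = "overlap_smaller"), 0.5)
  expect_equal(cgi_identity(a, b, id, mode = "reciprocal"), 0.5)
})

test_that("CGI identity at exactly 0.5 is not syntenic (strict >)", {
  id <- toy_chain(data.frame(s_start = 1, t_start = 1, len = 100000))
  ## overlap 100 of union 200 -> identity exactly 0.5
  a <- GRanges("chr1", IRanges(1001, 1150))
  b <- GRanges("chr1", IRanges(1051, 1200))
  expect_equal(cgi_identity(a, b, id), 0.5, tolerance = 1e-12)
  expect_equal(nrow(match_syntenic_cgis(a, b, id, threshold = 0.5)), 0L)
})

test_that("genomic context classification follows the published windows", {
  genes <- toy_txs(list(g = list("+", c(10000L, 15000L, 19000L),
                                 c(10300L, 15400L, 20000L))),
                   fpkm = 5, gene_id = "g")
  ## CGI centered on the TSS
  expect_equal(classify_cgi_context(GRanges("chr1", IRanges(9700, 10300)),
                                    genes), "promoter")
  ## interval 1 kb past the TTS is genic (inside the +2 kb tail)
  expect_equal(classify_genic(GRanges("chr1", IRanges(20900, 21100)), genes),
               "genic")
  expect_equal(classify_genic(GRanges("chr1", IRanges(22500, 23000)), genes),
               "intergenic")
  ## in-gene but 300 bp from the TSS with a 100 bp promoter window:
  ## the dead zone between the promoter and intragenic rules
  expect_equal(classify_cgi_context(GRanges("chr1", IRanges(10280, 10400)),
                                    genes, tss_window = 100L), "proximal")
  ## deep in the gene body
  expect_equal(classify_cgi_context(GRanges("chr1", IRanges(15000, 15600)),
                                    genes), "intragenic")
  expect_equal(classify_cgi_context(GRanges("chr1", IRanges(40000, 40600)),
                                    genes), "intergenic")
})

test_that("lifting ancestral features through cohort chains matches placements", {
  co <- fixture_cohort()
  ann <- co$annotations
  ## every shared LTR's mouse placement must project exactly onto its rat
  ## placement (chain correctness against the generator's bookkeeping)
  tr <- ann$truth$ltrs
  shared <- tr[tr$present_mouse & tr$present_rat &
                 tr$branch %in% c("ancestral", "pair"), ]
  iv <- GRanges(shared$chrom, IRanges(shared$start_mouse, shared$end_mouse))
  lo <- liftover(iv, ann$chains$mouse$rat)
  expect_true(all(lo$mapped))
  expect_equal(lo$start, shared$start_rat)
  expect_equal(lo$end, shared$end_rat)
})
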