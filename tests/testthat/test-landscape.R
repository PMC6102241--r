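test_that("bin scores average per-CpG fractions under the coverage rule", {
  ## two covered CpGs at 100% and 0% methylation -> bin mean 0.5
  m <- toy_meth(pos = c(100, 300, 700, 900, 950),
                meth = c(10, 0, 3, 1, 0),
                total = c(10, 10, 10, 2, 0), seqlen = 2000L)
  b <- score_bins(m, bin_width = 1000L, min_cpgs = 3L, min_depth = 5L)
  expect_true(mcols(b)$passes_filter[1])
  expect_equal(mcols(b)$n_cpgs_pass[1], 3L)       # depth-2 and depth-0 drop
  expect_equal(mcols(b)$mean_meth[1], mean(c(1, 0, 0.3)))

  ## below min_cpgs the bin fails the filter and carries no mean
  b2 <- score_bins(m, bin_width = 1000L, min_cpgs = 5L, min_depth = 5L)
  expect_false(mcols(b2)$passes_filter[1])
  expect_true(is.na(mcols(b2)$mean_meth[1]))
})

test_that("methylation classes use strict inequalities at 30%/70%", {
  expect_equal(classify_meth(c(0.29, 0.30, 0.50, 0.70, 0.71)),
               c("hypo", "intermediate", "intermediate", "intermediate",
                 "hyper"))
  expect_error(classify_meth(1.2), "\\[0, 1\\]")
  ## class fractions normalize over passing territory
  dom <- GRanges("chr1", IRanges(c(1, 1001, 3001), c(1000, 3000, 3500)),
                 meth_class = c("hypo", "hyper", "intermediate"))
  fr <- genome_fraction_by_class(dom)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(fr[["hyper"]], 2000 / 3500)
})

test_that("PELT matches the exhaustive dynamic program and finds no spurious breaks", {
  ## constant signal: a single domain
  x <- rep(0.8, 100)
  expect_length(pelt_changepoints(x, penalty = 0.1), 0L)

  set.seed(11)
  for (r in 1:25) {
    n <- sample(8:30, 1)
    x <- cumsum(rnorm(n, 0, 0.2))
    if (runif(1) < 0.5) x <- x + rep(c(0, 0.8), each = ceiling(n / 2))[1:n]
    pen <- runif(1, 0.05, 1)
    got <- pelt_changepoints(x, penalty = pen, min_segment = 2L)
    want <- dp_changepoints_oracle(x, pen, min_segment = 2L)
    expect_identical(as.integer(got), as.integer(want$changepoints))
  }
})

test_that("segmentation recovers a planted step and labels domains", {
  set.seed(3)
  nb <- 100L
  x <- c(rep(0.1, 50), rep(0.9, 50)) + rnorm(nb, 0, 0.05)
  x <- pmin(1, pmax(0, x))
  bins <- GRanges("chr1", IRanges(seq(1L, by = 1000L, length.out = nb),
                                  width = 1000L),
                  mean_meth = x, n_cpgs_pass = 10L, passes_filter = TRUE)
  seqlengths(bins) <- c(chr1 = 200000L)
  dom <- segment_domains(bins, penalty = 2 * log(nb) * 0.05^2)
  expect_equal(length(dom), 2L)
  expect_equal(mcols(dom)$meth_class, c("hypo", "hyper"))
  expect_equal(end(dom)[1], 50000L, tolerance = 2000)

  ## appending non-passing bins at the chromosome end changes nothing
  pad <- GRanges("chr1", IRanges(seq(100001L, by = 1000L, length.out = 10L),
                                 width = 1000L),
                 mean_meth = NA_real_, n_cpgs_pass = 0L,
                 passes_filter = FALSE)
  seqlengths(pad) <- c(chr1 = 200000L)
  bins2 <- suppressWarnings(c(bins, pad))
  dom2 <- segment_domains(bins2, penalty = 2 * log(nb) * 0.05^2)
  expect_equal(start(dom2), start(dom))
  expect_equal(end(dom2), end(dom))
})

test_that("domain means reconstruct the global mean of passing bins", {
  set.seed(8)
  x <- pmin(1, pmax(0, c(rep(0.1, 40), rep(0.85, 30), rep(0.4, 30)) +
                      rnorm(100, 0, 0.04)))
  bins <- GRanges("chr1", IRanges(seq(1L, by = 1000L, length.out = 100L),
                                  width = 1000L),
                  mean_meth = x, n_cpgs_pass = 8L, passes_filter = TRUE)
  seqlengths(bins) <- c(chr1 = 100000L)
  dom <- segment_domains(bins)
  weighted <- sum(mcols(dom)$mean_meth * mcols(dom)$n_bins) /
    sum(mcols(dom)$n_bins)
  expect_equal(weighted, mean(x), tolerance = 1e-9)
})

test_that("region and gene-body methylation flag missing coverage as NA", {
  m <- toy_meth(pos = c(100, 200, 300, 400, 500),
                meth = c(9, 8, 9, 10, 8), total = rep(10, 5),
                seqlen = 10000L)
  r <- region_methylation(GRanges("chr1", IRanges(c(1, 5000),
                                                  c(1000, 6000))), m,
                          min_depth = 5L, min_cpgs = 5L)
  expect_equal(r$mean_meth[1], mean(c(0.9, 0.8, 0.9, 1.0, 0.8)))
  expect_true(is.na(r$mean_meth[2]))   # no covered CpG: undefined, not 0
  expect_equal(r$n_cpgs[2], 0L)
})

test_that("anchored profiles are strand-oriented", {
  set.seed(2)
  pos <- seq(100L, 39900L, by = 100L)
  grad <- seq(0, 1, length.out = length(pos))    # rising left to right
  m <- toy_meth(pos = pos, meth = round(grad * 1000),
                total = rep(1000L, length(pos)), seqlen = 50000L)
  plus <- GRanges("chr1", IRanges(20000, width = 1), strand = "+")
  minus <- GRanges("chr1", IRanges(20000, width = 1), strand = "-")
  pp <- profile_around(plus, m, flank = 10000L, n_bins = 20L)
  pm <- profile_around(minus, m, flank = 10000L, n_bins = 20L)
  expect_equal(as.numeric(pp), rev(as.numeric(pm)), tolerance = 1e-12)
  expect_true(all(diff(as.numeric(pp)) > 0))     # downstream is rightward

  ## anchor with no coverage in the flank: all-NA row
  far <- GRanges("chr1", IRanges(49000, width = 1), strand = "+")
  expect_true(all(is.na(profile_around(far, m, flank = 500L, n_bins = 4L))))
})
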