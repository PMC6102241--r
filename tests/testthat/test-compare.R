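test_that("Venn partitions tabulate hyper combinations and conserve totals", {
  meth <- rbind(
    matrix(rep(c(0.9, 0.1, 0.1), 3), 3, byrow = TRUE),   # A only x3
    matrix(rep(c(0.95, 0.9, 0.8), 2), 2, byrow = TRUE),  # all three x2
    c(0.2, 0.1, 0.3),                                    # hypo everywhere
    c(0.9, NA, 0.9))                                     # incomplete
  colnames(meth) <- c("A", "B", "C")
  p <- venn_partition(meth, 0.70)
  expect_equal(unname(p$counts[["A"]]), 3L)
  expect_equal(unname(p$counts[["A+B+C"]]), 2L)
  expect_equal(sum(p$counts), p$n_hyper_any)
  expect_equal(p$n_hyper_any + p$n_hypo_all + p$n_excluded, p$n_input)
  expect_equal(p$n_excluded, 1L)

  ## all-hypo input: empty partition, everything excluded-or-hypo
  hypo <- matrix(0.1, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  p0 <- venn_partition(hypo)
  expect_equal(sum(p0$counts), 0L)
  expect_equal(p0$n_hypo_all, 4L)

  ## counts equal an independent per-unit recount
  set.seed(21)
  rnd <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  p1 <- venn_partition(rnd, 0.70)
  oracle <- venn_recount_oracle(rnd, 0.70)
  expect_equal(p1$n_hyper_any, oracle$n_hyper_any)
  for (k in names(oracle$counts)) {
    expect_equal(unname(p1$counts[[k]]), unname(oracle$counts[[k]]))
  }
})

test_that("domain attribution weights by territory and sums to one", {
  dom <- GRanges("chr1", IRanges(c(1, 20001), width = c(10000, 30000)),
                 meth_class = "hyper")
  lit <- GRanges("chr1", IRanges(500, 2000))
  gene <- GRanges("chr1", IRanges(25000, 35000), strand = "+")
  at <- attribute_domains(dom, lit, gene)
  expect_equal(unname(at$fractions[["LIT only"]]), 0.25)
  expect_equal(unname(at$fractions[["gene only"]]), 0.75)
  expect_equal(sum(at$fractions), 1, tolerance = 1e-12)
  ## invariant to domain input order
  at2 <- attribute_domains(rev(dom), lit, gene)
  expect_equal(at$fractions, at2$fractions)
  expect_error(attribute_domains(GRanges(), lit, gene), "no hyper")
})

test_that("planted orphan territory appears as the 'neither' fraction", {
  res <- fixture_result()
  co <- fixture_cohort()
  target <- co$spec$orphan_hyper_frac
  for (s in res$species) {
    at <- res$per_species[[s]]$attribution
    expect_lt(abs(unname(at$fractions[["neither"]]) - target), 0.05)
  }
})

test_that("the expression Z-score reproduces the printed formula", {
  expect_equal(expression_zscore(0, 0), 0)
  expect_equal(expression_zscore(8, 0), 8 / (sqrt(8) + 0.01),
               tolerance = 1e-12)
  set.seed(4)
  a <- rexp(50, 1 / 10); b <- rexp(50, 1 / 10)
  expect_equal(expression_zscore(a, b), -expression_zscore(b, a),
               tolerance = 1e-12)
  expect_true(all(sign(expression_zscore(a, b)) == sign(a - b)))
  expect_error(expression_zscore(-1, 2), "non-negative")
})

test_that("strain differential requires concordant K36 above the quantile", {
  n <- 200
  set.seed(6)
  ma <- rep(0.05, n); mb <- rep(0.05, n)
  ka <- rnorm(n, 1, 0.05); kb <- rnorm(n, 1, 0.05)
  ## planted strain-A unit: Delta meth 0.45 with a strong concordant K36 gain
  ma[1] <- 0.50; kb[1] <- 1; ka[1] <- 5
  ## same methylation difference but opposite K36 sign: not called
  ma[2] <- 0.50; ka[2] <- 1; kb[2] <- 5
  ## difference below the 40% cutoff (exactly 0.40 is not strict >)
  ma[3] <- 0.45; mb[3] <- 0.05; ka[3] <- 5; kb[3] <- 1
  calls <- strain_differential(ma, mb, ka, kb)
  expect_equal(calls[1], "A")
  expect_equal(calls[2], "none")
  expect_equal(calls[3], "none")   # 0.45 - 0.05 = 0.40, not > 0.40
  expect_true(is.na(strain_differential(NA, 0.1, 1, 1)[1]))
})

test_that("profile correlations match the covariance-ratio definition", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("p", "q", "r")))
  cm <- correlate_profiles(x)
  expect_equal(diag(cm), c(p = 1, q = 1, r = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["p", "q"], pearson_oracle(x[, 1], x[, 2]),
               tolerance = 1e-12)
  ## anti-correlated centered vectors
  v <- rnorm(10); v <- v - mean(v)
  am <- correlate_profiles(cbind(a = v, b = -v))
  expect_equal(am["a", "b"], -1)
  ## too few complete units: undefined entry
  y <- cbind(a = c(1, 2, NA, NA), b = c(2, 1, NA, NA))
  expect_true(is.na(correlate_profiles(y)["a", "b"]))
})

test_that("meCGI classification labels sharing and LIT embedding", {
  cg <- function(s, e) GRanges("chr1", IRanges(s, e))
  meth <- cbind(mouse = c(0.9, 0.9, 0.1, NA),
                rat = c(0.1, 0.85, 0.1, 0.5))
  cgis <- list(mouse = cg(c(1000, 5000, 9000, 12000),
                          c(1600, 5600, 9600, 12600)),
               rat = cg(c(1000, 5000, 9000, 12000),
                        c(1600, 5600, 9600, 12600)))
  lits <- list(
    mouse = data.frame(chrom = "chr1", start = c(500, 4500),
                       end = c(3000, 7000),
                       repeat_subfamily = c("MTA", "MTC")),
    rat = data.frame(chrom = "chr1", start = 4500, end = 7000,
                     repeat_subfamily = "MTC"))
  out <- classify_mecgi(meth, cgis, lits)
  expect_equal(out$mecgi_label,
               c("mouse-specific", "shared", "unmethylated", NA))
  expect_equal(out$lit_embedded, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$lit_subfamily_class[1:2], c("MTA", "MT (non-MTA)"))
  expect_equal(out$embedded_rat, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("strain-mode cohorts recover planted polymorphic-LTR CGIs", {
  spec <- cohort_spec(species = c("b6", "cast"), strain_mode = TRUE,
                      genome_length = 3e6, n_chrom = 2L, n_genes = 80L,
                      n_ancestral_ltrs = 30L, p_chimeric = 0.7,
                      n_branch_ltrs = c(b6 = 30L, cast = 30L), seed = 2L)
  co <- simulate_cohort(spec, tissues = "oocyte")
  res <- run_cohort_analysis(co)
  sd <- res$strain_diff
  tr <- co$truth$cgis
  m_b6 <- tr[tr$species == "b6", ]
  m_ca <- tr[tr$species == "cast", ]
  idx <- match(sd$cgi_id, m_b6$cgi_id)
  truth_call <- ifelse(m_b6$methylated[idx] & !m_ca$methylated[idx], "A",
                ifelse(m_ca$methylated[idx] & !m_b6$methylated[idx], "B",
                       "none"))
  ok <- !is.na(sd$call)
  tp <- sum(sd$call[ok] != "none" & sd$call[ok] == truth_call[ok])
  fp <- sum(sd$call[ok] != "none" & sd$call[ok] != truth_call[ok])
  fn <- sum(truth_call[ok] != "none" & sd$call[ok] != truth_call[ok])
  expect_gte(tp / max(1, tp + fp), 0.9)
  expect_gte(tp / max(1, tp + fn), 0.9)
})
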