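## Headline comparative classifications: multi-species hypermethylation Venn
## partitions, hyper-domain attribution, meCGI/LIT embedding labels,
## cross-species expression Z-scores, strain-differential calling, and
## profile correlation.

#' Venn partition of syntenic units by hypermethylation
#'
#' Tabulates, over coverage-complete syntenic units, the presence/absence
#' combinations of hypermethylation (`mean_meth > hyper_threshold`, strict)
#' across species. Units hypermethylated in no species are excluded but
#' counted; units missing methylation in any species are excluded and
#' counted separately.
#'
#' @param meth matrix or data.frame of per-unit, per-species mean
#'   methylation (columns named by species).
#' @param hyper_threshold hypermethylation cutoff (default 0.70).
#' @return list with `counts` (named by species combination, e.g. `"mouse"`,
#'   `"mouse+rat"`), `n_hyper_any`, `n_hypo_all`, `n_excluded`, `n_input`.
#' @export
venn_partition <- function(meth, hyper_threshold = 0.70) {
  meth <- as.matrix(meth)
  species <- colnames(meth)
  stopifnot(!is.null(species))
  complete <- rowSums(is.na(meth)) == 0L
  hy <- meth[complete, , drop = FALSE] > hyper_threshold
  any_hyper <- rowSums(hy) > 0L
  combos <- apply(hy[any_hyper, , drop = FALSE], 1L,
                  function(z) paste(species[z], collapse = "+"))
  ## all non-empty combinations, in a stable order
  all_combos <- unlist(lapply(seq_along(species), function(k) {
    apply(utils::combn(species, k), 2L, paste, collapse = "+")
  }))
  counts <- setNames(integer(length(all_combos)), all_combos)
  tab <- table(combos)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       n_hyper_any = sum(any_hyper),
       n_hypo_all = sum(!any_hyper),
       n_excluded = sum(!complete),
       n_input = nrow(meth))
}

#' Attribute hypermethylated domains to LITs and genes
#'
#' Classifies each hypermethylated domain by any-overlap (>= 1 bp) with
#' called LIT spans and/or annotated genes (TSS..TTS + 2 kb), and reports
#' the bp-weighted fraction of hypermethylated territory per class
#' (normalized to the domain size).
#'
#' @param hyper_domains `GRanges` of hypermethylated domains.
#' @param lit_spans `GRanges` spans of called LITs.
#' @param genes gene models (`TranscriptSet` or span `GRanges`).
#' @param tail_extension genic tail past the TTS (default 2000 bp).
#' @return list with `class` (per-domain factor) and `fractions` (named
#'   fractions over `LIT only`, `gene only`, `LIT+gene`, `neither`,
#'   summing to 1).
#' @export
attribute_domains <- function(hyper_domains, lit_spans, genes,
                              tail_extension = 2000L) {
  if (!length(hyper_domains)) .lm_stop("no hyper territory to attribute")
  spans <- if (is(genes, "GRangesList")) tx_spans(genes) else genes
  ext <- resize(spans, width = width(spans) + tail_extension, fix = "start")
  in_lit <- overlapsAny(hyper_domains, lit_spans, ignore.strand = TRUE)
  in_gene <- overlapsAny(hyper_domains, ext, ignore.strand = TRUE)
  lev <- c("LIT only", "gene only", "LIT+gene", "neither")
  cls <- factor(ifelse(in_lit & in_gene, "LIT+gene",
               ifelse(in_lit, "LIT only",
               ifelse(in_gene, "gene only", "neither"))), levels = lev)
  w <- tapply(width(hyper_domains), cls, sum)
  w[is.na(w)] <- 0
  fractions <- as.numeric(w) / sum(width(hyper_domains))
  names(fractions) <- lev
  list(class = cls, fractions = fractions)
}

#' Cross-species expression Z-score
#'
#' `z = (a - b) / (sqrt(a + b) + 0.01)`, the variance-stabilized contrast
#' used for ortholog expression comparisons. Antisymmetric, zero iff the
#' two FPKM values are equal.
#'
#' @param fpkm_a,fpkm_b non-negative expression values (FPKM).
#' @return numeric z.
#' @export
expression_zscore <- function(fpkm_a, fpkm_b) {
  .check_nonneg(fpkm_a, "fpkm_a"); .check_nonneg(fpkm_b, "fpkm_b")
  (fpkm_a - fpkm_b) / (sqrt(fpkm_a + fpkm_b) + 0.01)
}

#' Classify syntenic CGIs by methylation sharing and LIT embedding
#'
#' A CGI is a meCGI in a species when its mean methylation there exceeds
#' `hyper_threshold` (methylation values must already satisfy the >5
#' covered-CpGs rule; uncovered entries are `NA` and make the CGI
#' unclassified). meCGIs are labeled `shared` (hyper in every species) or
#' `<species>-specific`; a CGI is "LIT-embedded" in a species when its
#' interval lies within the transcript span of a called LIT there, and the
#' embedding subfamily is classed as `MTA`, `MT (non-MTA)`, or
#' `other LTR`.
#'
#' @param meth per-unit x per-species methylation matrix (species columns).
#' @param cgis_by_species named list of per-species CGI `GRanges`, parallel
#'   rows to `meth`.
#' @param lits_by_species named list of per-species LIT call data.frames
#'   (from [call_lits()]).
#' @param hyper_threshold meCGI cutoff (default 0.70, strict).
#' @return data.frame with `mecgi_label`, per-species `embedded_*` flags,
#'   `lit_embedded` (any species), `lit_subfamily_class`.
#' @export
classify_mecgi <- function(meth, cgis_by_species, lits_by_species,
                           hyper_threshold = 0.70) {
  meth <- as.matrix(meth)
  species <- colnames(meth)
  n <- nrow(meth)
  hy <- meth > hyper_threshold
  label <- rep(NA_character_, n)
  complete <- rowSums(is.na(meth)) == 0L
  n_hyper <- rowSums(hy)
  label[complete & n_hyper == 0L] <- "unmethylated"
  label[complete & n_hyper == length(species)] <- "shared"
  for (sp in species) {
    only <- complete & hy[, sp] & n_hyper == 1L
    label[only] <- paste0(sp, "-specific")
  }
  label[complete & is.na(label)] <- "partial"
  emb <- matrix(FALSE, n, length(species), dimnames = list(NULL, species))
  subfam <- matrix(NA_character_, n, length(species))
  for (k in seq_along(species)) {
    sp <- species[k]
    calls <- lits_by_species[[sp]]
    if (is.null(calls) || !nrow(calls)) next
    lit_gr <- GRanges(calls$chrom, IRanges(calls$start, calls$end))
    ov <- findOverlaps(cgis_by_species[[sp]], lit_gr, type = "within",
                       ignore.strand = TRUE)
    if (length(ov)) {
      emb[queryHits(ov), k] <- TRUE
      first <- !duplicated(queryHits(ov))
      subfam[queryHits(ov)[first], k] <-
        calls$repeat_subfamily[subjectHits(ov)[first]]
    }
  }
  any_emb <- rowSums(emb) > 0L
  sub1 <- apply(subfam, 1L, function(z) {
    z <- z[!is.na(z)]; if (length(z)) z[1] else NA_character_
  })
  out <- data.frame(mecgi_label = label, lit_embedded = any_emb,
                    lit_subfamily_class = lit_subfamily_class(sub1),
                    stringsAsFactors = FALSE)
  for (k in seq_along(species)) {
    out[[paste0("embedded_", species[k])]] <- emb[, k]
  }
  out
}

#' Subfamily class of an initiating LTR
#'
#' Groups initiating subfamilies the way promoter-meCGI composition is
#' reported: the mouse-restricted `MTA`, other `MT (non-MTA)` MaLR
#' subfamilies (MTB/MTC/MTD/MTE), and `other LTR`.
#'
#' @param subfamily character vector of repeat subfamily names.
#' @return character vector of classes (`NA` stays `NA`).
#' @export
lit_subfamily_class <- function(subfamily) {
  out <- rep(NA_character_, length(subfamily))
  hit <- !is.na(subfamily)
  out[hit] <- "other LTR"
  out[hit & grepl("^MT[B-E]", subfamily)] <- "MT (non-MTA)"
  out[hit & grepl("^MTA", subfamily)] <- "MTA"
  out
}

#' Strain-differential methylation with H3K36me3 concordance
#'
#' A unit is strain-A specific when `meth_a - meth_b > d_meth` (default
#' 0.40, strict) *and* the H3K36me3 difference (depth-normalized coverage)
#' is positive in the same direction and exceeds the `k36_quantile` of the
#' genome-wide `|delta|` distribution; symmetrically for strain B.
#'
#' @param meth_a,meth_b per-unit methylation in the two strains.
#' @param k36_a,k36_b per-unit normalized H3K36me3 coverage.
#' @param d_meth methylation difference cutoff.
#' @param k36_quantile quantile of `|delta K36|` the concordant excess must
#'   exceed (default 0.75).
#' @return character vector per unit: `"A"`, `"B"` or `"none"` (`NA` where
#'   any input is missing).
#' @export
strain_differential <- function(meth_a, meth_b, k36_a, k36_b,
                                d_meth = 0.40, k36_quantile = 0.75) {
  dm <- meth_a - meth_b
  dk <- k36_a - k36_b
  thr <- quantile(abs(dk), k36_quantile, na.rm = TRUE, names = FALSE)
  out <- rep("none", length(dm))
  out[dm > d_meth & dk > 0 & abs(dk) > thr] <- "A"
  out[dm < -d_meth & dk < 0 & abs(dk) > thr] <- "B"
  out[is.na(dm) | is.na(dk)] <- NA_character_
  out
}

#' Pairwise Pearson correlation of profiles over shared units
#'
#' @param x numeric matrix, units in rows, samples in columns; only
#'   complete-case rows enter each pairwise correlation.
#' @param min_units minimum complete units for a defined entry (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlate_profiles <- function(x, min_units = 3L) {
  x <- as.matrix(x)
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  diag(out) <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    ok <- stats::complete.cases(x[, c(i, j)])
    if (sum(ok) >= min_units) {
      out[i, j] <- out[j, i] <- cor(x[ok, i], x[ok, j])
    }
  }
  out
}
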