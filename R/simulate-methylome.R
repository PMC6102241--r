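## Methylome stage of the cohort generator: transcription-coupled oocyte
## hypermethylation, an orphan hyper background with no underlying
## transcript, sperm/blastocyst/epiblast tissues with per-CGI retention,
## and an H3K36me3 coverage track.

#' Simulate per-species, per-tissue methylomes
#'
#' Oocyte per-CpG methylation follows a Beta model with mean `m_high`
#' inside transcribed territory (gene bodies and LIT bodies of units above
#' 1 FPKM, truncated at transcript boundaries) plus planted orphan hyper
#' domains, and `m_low` elsewhere; CGIs are methylated only when fully
#' embedded in a transcribed unit whose TSS lies outside the island. Read
#' counts are Binomial over an overdispersed (negative binomial) depth.
#' Sperm is near-uniformly high except CGIs (< 1%). Maternal blastocyst
#' signal is the attenuated oocyte signal with a per-meCGI retention draw;
#' the biparental blastocyst averages maternal and sperm levels; wild-type
#' epiblast erases TET-sensitive CGIs while the TET-null profile retains
#' them.
#'
#' @param ann output of [simulate_annotations()].
#' @param tx output of [simulate_transcriptome()].
#' @param tissues tissues to emit (subset of oocyte, sperm, pg_blastocyst,
#'   blastocyst, epiblast, epiblast_tetko).
#' @return list with `meth` (`meth[[species]][[tissue]]` MethTables),
#'   `truth` (per-species CGI ledger and orphan domains).
#' @export
simulate_methylomes <- function(ann, tx,
                                tissues = c("oocyte", "sperm",
                                            "pg_blastocyst", "blastocyst",
                                            "epiblast", "epiblast_tetko")) {
  spec <- ann$spec
  set.seed(.stage_seed(spec$seed, 3L))
  sp_names <- spec$species

  ## transcribed territory per species (units above 1 FPKM)
  territory <- lapply(sp_names, function(s) {
    txs <- tx$transcripts[[s]]
    reduce(tx_spans(txs)[mcols(txs)$fpkm > 1], ignore.strand = TRUE)
  })
  names(territory) <- sp_names

  orphans_anc <- .plant_orphans(ann, territory)
  orphans <- lapply(sp_names, function(s) {
    ins <- ann$insertions[[s]]
    gr <- orphans_anc
    if (length(gr)) {
      ns <- vapply(seq_along(gr), function(i) {
        a <- ins[chrom == as.character(seqnames(gr))[i]]
        as.numeric(.anc_to_species(start(gr)[i], a$anc_start - 1L, a$width))
      }, 1)
      ne <- vapply(seq_along(gr), function(i) {
        a <- ins[chrom == as.character(seqnames(gr))[i]]
        as.numeric(.anc_to_species(end(gr)[i], a$anc_start - 1L, a$width))
      }, 1)
      gr <- GRanges(seqnames(gr), IRanges(ns, ne))
    }
    gr
  })
  names(orphans) <- sp_names

  meth <- list(); cgi_truth <- list()
  for (s in sp_names) {
    seqlens <- ann$species[[s]]$seqlens
    cgis <- ann$species[[s]]$cgis
    txs <- tx$transcripts[[s]]
    spans <- tx_spans(txs)
    expressed <- mcols(txs)$fpkm > 1

    ## CGI methylation truth: island fully inside an expressed unit whose
    ## TSS is outside the island
    cgi_meth <- logical(length(cgis))
    embed_tx <- rep(NA_character_, length(cgis))
    ovw <- findOverlaps(cgis, spans[expressed], type = "within",
                        ignore.strand = TRUE)
    if (length(ovw)) {
      tss <- tx_tss(txs[expressed])
      tss_in <- start(tss)[subjectHits(ovw)] >= start(cgis)[queryHits(ovw)] &
        start(tss)[subjectHits(ovw)] <= end(cgis)[queryHits(ovw)]
      ok <- !tss_in
      hit <- data.table(q = queryHits(ovw)[ok], t = subjectHits(ovw)[ok])
      if (nrow(hit)) {
        ## prefer a LIT as the embedding unit when there is a choice
        ids <- mcols(txs[expressed])$transcript_id[hit$t]
        hit[, is_lit := ids %in% tx$truth$lits$transcript_id]
        setorder(hit, q, -is_lit)
        hit <- hit[!duplicated(hit$q)]
        cgi_meth[hit$q] <- TRUE
        embed_tx[hit$q] <- mcols(txs[expressed])$transcript_id[hit$t]
      }
    }
    lit_embedded <- !is.na(embed_tx) &
      embed_tx %in% tx$truth$lits$transcript_id
    retained <- cgi_meth & runif(length(cgis)) < spec$retention_prob
    tet_sensitive <- retained & runif(length(cgis)) < spec$p_tet_sensitive

    ## CpG positions: background spacing plus dense CGIs
    pos_list <- list()
    for (ch in names(seqlens)) {
      n_bg <- floor(seqlens[[ch]] / spec$cpg_spacing)
      bg <- sort(sample.int(seqlens[[ch]] - 2L, n_bg))
      cg_ch <- cgis[seqnames(cgis) == ch]
      dense <- unlist(lapply(seq_along(cg_ch), function(i) {
        seq(start(cg_ch)[i] + 3L, end(cg_ch)[i] - 3L,
            by = spec$cgi_cpg_spacing)
      }))
      pos_list[[ch]] <- sort(unique(c(bg, dense)))
    }
    sites <- GRanges(rep(names(pos_list), lengths(pos_list)),
                     IRanges(unlist(pos_list), width = 1L))
    seqlevels(sites) <- names(seqlens); seqlengths(sites) <- seqlens

    in_hyper <- overlapsAny(sites, territory[[s]], ignore.strand = TRUE) |
      overlapsAny(sites, orphans[[s]], ignore.strand = TRUE)
    cgi_of <- rep(NA_integer_, length(sites))
    ovc <- findOverlaps(sites, cgis, ignore.strand = TRUE)
    cgi_of[queryHits(ovc)] <- subjectHits(ovc)
    in_cgi <- !is.na(cgi_of)

    m_tissue <- .tissue_means(spec, in_hyper, in_cgi, cgi_of, cgi_meth,
                              retained, tet_sensitive)
    meth[[s]] <- list()
    for (tis in tissues) {
      m <- m_tissue[[tis]]
      a <- pmax(spec$beta_conc * m, 1e-3)
      b <- pmax(spec$beta_conc * (1 - m), 1e-3)
      p <- rbeta(length(m), a, b)
      depth <- rnbinom(length(m), mu = spec$mean_depth,
                       size = spec$depth_dispersion)
      mr <- rbinom(length(m), depth, p)
      meth[[s]][[tis]] <- meth_table(sites, mr, depth)
    }
    cgi_truth[[s]] <- data.table(
      cgi_id = mcols(cgis)$cgi_id, species = s,
      type = mcols(cgis)$type,
      methylated = cgi_meth, embed_tx = embed_tx,
      lit_embedded = lit_embedded,
      retained = retained, tet_sensitive = tet_sensitive,
      maternal_dmr = retained)
  }
  list(meth = meth,
       truth = list(cgis = rbindlist(cgi_truth), orphans = orphans,
                    orphans_ancestral = orphans_anc))
}

## per-tissue expected methylation per CpG
.tissue_means <- function(spec, in_hyper, in_cgi, cgi_of, cgi_meth,
                          retained, tet_sensitive) {
  n <- length(in_hyper)
  cgi_state <- function(meth_val, unmeth_val) {
    v <- numeric(n)
    idx <- which(in_cgi)
    v[idx] <- ifelse(cgi_meth[cgi_of[idx]], meth_val[cgi_of[idx]],
                     unmeth_val)
    v
  }
  oo <- ifelse(in_hyper, spec$m_high, spec$m_low)
  oo[in_cgi] <- cgi_state(rep(spec$m_high, length(cgi_meth)),
                          spec$m_low / 2)[in_cgi]
  sperm <- rep(spec$sperm_meth, n)
  sperm[in_cgi] <- spec$sperm_cgi_meth
  pg_cgi_level <- ifelse(retained, spec$retained_meth, spec$erased_meth)
  pg <- ifelse(in_hyper, spec$m_high * spec$blastocyst_attenuation,
               spec$m_low * 0.6)
  pg[in_cgi] <- cgi_state(pg_cgi_level, 0.02)[in_cgi]
  bl <- (pg + sperm) / 2
  epi_cgi_wt <- ifelse(retained & !tet_sensitive,
                       spec$epiblast_retained_meth, 0.03)
  epi <- rep(spec$epiblast_meth, n)
  epi[in_cgi] <- cgi_state(epi_cgi_wt, 0.03)[in_cgi]
  epi_cgi_ko <- ifelse(retained, spec$epiblast_retained_meth, 0.03)
  epk <- rep(spec$epiblast_meth, n)
  epk[in_cgi] <- cgi_state(epi_cgi_ko, 0.03)[in_cgi]
  list(oocyte = oo, sperm = sperm, pg_blastocyst = pg, blastocyst = bl,
       epiblast = epi, epiblast_tetko = epk)
}

## orphan hyper domains: ancestral intergenic intervals far from any gene
## or LTR-downstream territory, totalling orphan_frac of hyper territory
.plant_orphans <- function(ann, territory) {
  spec <- ann$spec
  f <- spec$orphan_hyper_frac
  if (f <= 0) return(GRanges())
  t_mean <- mean(vapply(territory, function(g) sum(width(g)), 1))
  target <- t_mean * f / (1 - f)
  anc <- ann$ancestral
  blocked <- list()
  for (ch in anc$chroms) {
    g <- anc$genes[chrom == ch]
    gene_iv <- if (nrow(g))
      as.data.table(g)[, list(s = min(exon_start), e = max(exon_end)),
                       by = "gene_id"] else NULL
    b <- IRanges()
    if (!is.null(gene_iv) && nrow(gene_iv)) {
      ## clear the genic TSS..TTS+2kb rule plus a margin on either side
      b <- c(b, IRanges(pmax(1L, gene_iv$s - 4000L), gene_iv$e + 6000L))
    }
    l <- anc$ltrs[chrom == ch]
    if (nrow(l)) {
      ## LITs run downstream of the element: pad the transcribed side by
      ## the maximal LIT span, the other side by a margin
      pad_down <- max(spec$lit_length) + 2000L
      pad_up <- 2000L
      plus <- l$strand == "+"
      b <- c(b,
             IRanges(pmax(1L, l$anc_start - ifelse(plus, pad_up, pad_down)),
                     l$anc_start + l$width +
                       ifelse(plus, pad_down, pad_up)))
    }
    blocked[[ch]] <- reduce(b)
  }
  out <- list(); placed <- 0
  tries <- 0L
  while (placed < target && tries < 3000L) {
    tries <- tries + 1L
    ch <- sample(anc$chroms, 1L)
    w <- sample(4000:9000, 1L)
    s <- sample.int(max(1L, anc$chrom_len[[ch]] - w - 1L), 1L)
    cand <- IRanges(s, s + w - 1L)
    if (!length(findOverlaps(cand, blocked[[ch]]))) {
      out[[length(out) + 1L]] <- GRanges(ch, cand)
      blocked[[ch]] <- c(blocked[[ch]], cand + 2000L)
      placed <- placed + w
    }
  }
  if (!length(out)) return(GRanges())
  sort(unlist(GRangesList(out)))
}

#' Simulate an H3K36me3 coverage track
#'
#' Difference-of-means signal over transcribed territory: background 1x,
#' plus a gain proportional to the transcribed fraction of each bin, with
#' log-normal noise. The mark is deposited co-transcriptionally and is
#' depleted at unit 5' ends (it accumulates downstream of the TSS), so the
#' gain territory excludes the first `tss_taper` bp of each transcribed
#' unit.
#'
#' @param ann output of [simulate_annotations()].
#' @param tx output of [simulate_transcriptome()].
#' @param bin_width track resolution in bp.
#' @param gain enrichment over transcribed units.
#' @param tss_taper 5' depletion length in bp.
#' @return named list of per-species `GRanges` bins with a `score` column.
#' @export
simulate_k36 <- function(ann, tx, bin_width = 500L, gain = 4,
                         tss_taper = 1000L) {
  spec <- ann$spec
  set.seed(.stage_seed(spec$seed, 4L))
  out <- list()
  for (s in spec$species) {
    txs <- tx$transcripts[[s]]
    spans <- tx_spans(txs)[mcols(txs)$fpkm > 1]
    keep <- width(spans) > tss_taper + 200L
    spans <- spans[keep]
    spans <- resize(spans, width = width(spans) - tss_taper, fix = "end")
    terr <- reduce(spans, ignore.strand = TRUE)
    bins <- tileGenome(ann$species[[s]]$seqlens, tilewidth = bin_width,
                       cut.last.tile.in.chrom = TRUE)
    cov <- rep(0, length(bins))
    ov <- findOverlaps(bins, terr, ignore.strand = TRUE)
    if (length(ov)) {
      w <- width(pintersect(bins[queryHits(ov)], terr[subjectHits(ov)]))
      frac <- tapply(w, queryHits(ov), sum) / bin_width
      cov[as.integer(names(frac))] <- frac
    }
    score <- (1 + gain * cov) * rlnorm(length(bins), 0, 0.2)
    mcols(bins)$score <- score
    out[[s]] <- bins
  }
  out
}

#' Simulate a full cohort
#'
#' Convenience wrapper chaining [simulate_annotations()],
#' [simulate_transcriptome()], [simulate_methylomes()] and
#' [simulate_k36()], merging the truth ledgers.
#'
#' @param spec a [cohort_spec()].
#' @param tissues tissues passed to [simulate_methylomes()].
#' @return list with `spec`, `annotations`, `transcripts`, `coverage`,
#'   `repeat_fpkm`, `meth`, `k36`, and `truth` (`ltrs`, `lits`, `cgis`,
#'   `orphans`).
#' @export
simulate_cohort <- function(spec, tissues = c("oocyte", "sperm",
                                              "pg_blastocyst", "blastocyst",
                                              "epiblast", "epiblast_tetko")) {
  ann <- simulate_annotations(spec)
  tx <- simulate_transcriptome(ann)
  me <- simulate_methylomes(ann, tx, tissues = tissues)
  k36 <- simulate_k36(ann, tx)
  list(spec = spec, annotations = ann, transcripts = tx$transcripts,
       coverage = tx$coverage, repeat_fpkm = tx$repeat_fpkm,
       meth = me$meth, k36 = k36,
       truth = list(ltrs = ann$truth$ltrs, lits = tx$truth$lits,
                    active = tx$truth$active, cgis = me$truth$cgis,
                    orphans = me$truth$orphans))
}
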