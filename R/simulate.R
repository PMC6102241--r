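## Synthetic multi-species cohort generator. Species genomes are derived
## from a common ancestral coordinate frame by lineage-specific LTR
## insertions (insertion-only indels), so pairwise chains are exact by
## construction; genomes are coordinate-only (intervals and counts, no
## nucleotide sequence). A ground-truth ledger records every planted LTR,
## LIT and expected CGI methylation consequence.

#' Specification of a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: a
#' mouse/rat/human-like triplet (rodents close, human distal), bimodal
#' oocyte methylomes (modes near 0.85 and 0.05) with transcription-coupled
#' hypermethylation, ~15% of hypermethylated territory unexplained by any
#' transcript, sperm hypermethylated except CGIs (<1%), and a 0.4 per-CGI
#' probability of blastocyst persistence.
#'
#' @param species species names, ordered so the first two are the close
#'   pair (for three species the topology is `((s1, s2), s3)`).
#' @param genome_length ancestral genome length in bp.
#' @param n_chrom chromosomes (ancestral length split evenly).
#' @param n_genes genes placed in the ancestral frame.
#' @param exons_per_gene,exon_width,intron_width gene geometry ranges (bp).
#' @param intergenic_gap range of gaps between genes (bp).
#' @param cgi_width CpG island width (bp); every gene gets a promoter CGI.
#' @param p_intragenic_cgi probability a gene also carries a mid-body CGI.
#' @param n_ancestral_ltrs LTRs present in all species (ancestral frame).
#' @param n_branch_ltrs named insertion counts per branch: `pair` (shared
#'   by the first two species) plus one entry per species (private).
#' @param ltr_width LTR width range (bp).
#' @param p_active probability an LTR copy is transcriptionally active in
#'   the oocyte of a species carrying it.
#' @param shared_activity draw activity once per LTR and share it across
#'   species (instead of independent per-species draws).
#' @param p_chimeric probability an active LTR near/inside a gene yields a
#'   sense-chimeric transcript.
#' @param p_upedge fraction of LITs whose TSS sits just outside the LTR
#'   edge (UpEdge geometry) rather than inside it (Up).
#' @param upstream_window how far upstream of a gene an LTR can recruit it
#'   into a chimera (bp).
#' @param p_suppress_canonical probability the canonical TSS is suppressed
#'   when an upstream chimeric LIT exists.
#' @param lit_length span range of intergenic/antisense LITs (bp).
#' @param p_gene_expressed probability a gene is expressed in oocytes
#'   (shared across species; per-species FPKM jitter is applied on top).
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM model for expressed units.
#' @param m_high,m_low,beta_conc Beta methylation model: means of the
#'   hyper/hypo modes and the concentration.
#' @param mean_depth,depth_dispersion negative-binomial CpG coverage model.
#' @param cpg_spacing,cgi_cpg_spacing mean CpG spacing outside/inside CGIs.
#' @param orphan_hyper_frac fraction of hypermethylated territory planted
#'   with no underlying transcript (the unexplained-domain background).
#' @param sperm_meth,sperm_cgi_meth sperm methylation genome-wide / at CGIs.
#' @param retention_prob per-meCGI probability of blastocyst persistence.
#' @param retained_meth,erased_meth,blastocyst_attenuation maternal
#'   blastocyst levels for retained/erased CGIs and non-CGI attenuation.
#' @param p_tet_sensitive probability a retained meCGI is TET-sensitive
#'   (erased in wild-type epiblast, retained in TET-null).
#' @param epiblast_meth,epiblast_retained_meth epiblast background and
#'   retained-CGI levels.
#' @param strain_mode model the cohort as strains of one species:
#'   polymorphic LTRs become presence/absence flags on a shared coordinate
#'   frame (no indels; identity chains).
#' @param seed RNG seed (integer).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(species = c("mouse", "rat", "human"),
                        genome_length = 2e6L, n_chrom = 2L,
                        n_genes = 60L,
                        exons_per_gene = c(3L, 6L),
                        exon_width = c(150L, 600L),
                        intron_width = c(800L, 3500L),
                        intergenic_gap = c(6000L, 16000L),
                        cgi_width = 600L, p_intragenic_cgi = 0.25,
                        n_ancestral_ltrs = 25L,
                        n_branch_ltrs = NULL,
                        ltr_width = c(300L, 600L),
                        p_active = 0.45, shared_activity = FALSE,
                        p_chimeric = 0.5, p_upedge = 0.12,
                        upstream_window = 12000L,
                        p_suppress_canonical = 0.3,
                        lit_length = c(4000L, 10000L),
                        p_gene_expressed = 0.75,
                        fpkm_meanlog = 2.2, fpkm_sdlog = 0.9,
                        m_high = 0.85, m_low = 0.05, beta_conc = 30,
                        mean_depth = 15, depth_dispersion = 8,
                        cpg_spacing = 150L, cgi_cpg_spacing = 25L,
                        orphan_hyper_frac = 0.15,
                        sperm_meth = 0.92, sperm_cgi_meth = 0.004,
                        retention_prob = 0.4,
                        retained_meth = 0.70, erased_meth = 0.08,
                        blastocyst_attenuation = 0.45,
                        p_tet_sensitive = 0.4,
                        epiblast_meth = 0.65, epiblast_retained_meth = 0.50,
                        strain_mode = FALSE,
                        seed = 1L) {
  if (is.null(n_branch_ltrs)) {
    n_branch_ltrs <- c(pair = if (length(species) >= 3L) 10L else 0L,
                       setNames(rep(14L, length(species)), species))
  }
  spec <- as.list(environment())
  for (p in c("p_active", "p_chimeric", "p_upedge", "p_suppress_canonical",
              "p_gene_expressed", "p_intragenic_cgi", "m_high", "m_low",
              "orphan_hyper_frac", "sperm_meth", "sperm_cgi_meth",
              "retention_prob", "retained_meth", "erased_meth",
              "blastocyst_attenuation", "p_tet_sensitive", "epiblast_meth",
              "epiblast_retained_meth")) {
    .check_fraction(spec[[p]], p)
  }
  if (genome_length < n_genes * (mean(exon_width) * mean(exons_per_gene) +
                                 mean(intron_width) * (mean(exons_per_gene) - 1))) {
    .lm_stop("genome_length too small for %d genes", n_genes)
  }
  structure(spec, class = "cohort_spec")
}

## subfamily sampling tables per branch; generic fallbacks keep arbitrary
## species/strain names working
.branch_subfamily_table <- function(branch, species) {
  known <- list(
    ancestral = c(MLT1A = 0.6, MLT1B = 0.4),
    pair = c(MTB = 0.3, MTC = 0.35, MTD = 0.35),
    mouse = c(MTA = 0.6, RLTR10 = 0.2, IAPLTR1 = 0.2),
    rat = c(RLTR31B2 = 0.6, IAPLTR1 = 0.4),
    human = c(THE1B = 0.4, LTR12C = 0.4, LTR7 = 0.2))
  if (branch %in% names(known)) return(known[[branch]])
  c(MTA = 0.5, MTC = 0.3, RLTR10 = 0.2)  # strain-style polymorphic MTs
}

.subfamily_family <- function(subfamily) {
  fam <- rep("LTR/ERVK", length(subfamily))
  fam[grepl("^(MT[A-E]|MLT|THE1)", subfamily)] <- "LTR/ERVL-MaLR"
  fam[grepl("^(LTR12|LTR7|HERV)", subfamily)] <- "LTR/ERV1"
  fam[grepl("^(MERVL|MT2)", subfamily)] <- "LTR/ERVL"
  fam
}

## coordinate mapping ancestral -> species given sorted insertion
## breakpoints A (0-based) and widths W
.anc_to_species <- function(x, A, W) {
  if (!length(A)) return(x)
  cw <- c(0, cumsum(W))
  x + cw[findInterval(x - 1L, A) + 1L]
}

## sample n non-overlapping positions of width w from a chromosome,
## avoiding `blocked` (IRanges); returns starts (may return fewer than n)
.place_intervals <- function(n, w, chrom_len, blocked, margin = 150L) {
  starts <- integer(0); widths <- integer(0)
  occupied <- blocked
  tries <- 0L
  while (length(starts) < n && tries < n * 60L) {
    tries <- tries + 1L
    wi <- if (length(w) > 1L) sample(w[1]:w[2], 1L) else w
    s <- sample.int(max(1L, chrom_len - wi - margin - 1L), 1L)
    cand <- IRanges(max(1L, s - margin), s + wi - 1L + margin)
    if (!length(findOverlaps(cand, occupied))) {
      starts <- c(starts, s); widths <- c(widths, wi)
      occupied <- c(occupied, IRanges(s, s + wi - 1L))
    }
  }
  attr(starts, "widths") <- widths
  starts
}

#' Simulate per-species annotations from a cohort specification
#'
#' Lays out genes (with promoter and optional intragenic CGIs), ancestral
#' LTRs and branch-specific LTR insertions in a common ancestral frame,
#' derives each species' coordinates, and emits pairwise chain alignments
#' that are exact by construction.
#'
#' @param spec a [cohort_spec()].
#' @return list with `species` (per-species `genes` TranscriptSet,
#'   `gene_spans`, `cgis`, `repeats`, `seqlens`), `chains` (nested
#'   `chains[[from]][[to]]`), `truth` (LTR ledger), and `spec`.
#' @export
simulate_annotations <- function(spec) {
  set.seed(.stage_seed(spec$seed, 1L))
  sp_names <- spec$species
  n_chrom <- spec$n_chrom
  chrom_len <- rep(floor(spec$genome_length / n_chrom), n_chrom)
  chroms <- paste0("chr", seq_len(n_chrom))

  ## --- ancestral gene layout -------------------------------------------
  genes <- list(); cgis <- list()
  per_chrom <- diff(floor(seq(0, spec$n_genes, length.out = n_chrom + 1L)))
  gid <- 0L
  for (ci in seq_len(n_chrom)) {
    cursor <- sample(2000:5000, 1L)
    for (g in seq_len(per_chrom[ci])) {
      cursor <- cursor + sample(spec$intergenic_gap[1]:spec$intergenic_gap[2], 1L)
      ne <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
      ew <- sample(spec$exon_width[1]:spec$exon_width[2], ne, replace = TRUE)
      iw <- if (ne > 1L) sample(spec$intron_width[1]:spec$intron_width[2],
                                ne - 1L, replace = TRUE) else integer(0)
      starts <- cursor + cumsum(c(0L, head(ew, -1L) + iw))
      ends <- starts + ew - 1L
      gend <- ends[ne]
      if (gend > chrom_len[ci] - 3000L) break
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      genes[[gid]] <- data.table(
        gene_id = sprintf("g%04d", gid), chrom = chroms[ci],
        exon_start = starts, exon_end = ends, strand = strand)
      tss <- if (strand == "+") cursor else gend
      half <- floor(spec$cgi_width / 2)
      cgis[[length(cgis) + 1L]] <- data.table(
        cgi_id = sprintf("cgi_p_%04d", gid), chrom = chroms[ci],
        start = tss - half, end = tss + half - 1L,
        type = "promoter", gene_id = sprintf("g%04d", gid))
      if (runif(1) < spec$p_intragenic_cgi && gend - cursor > 4L * spec$cgi_width) {
        mid <- cursor + floor((gend - cursor) / 2)
        cgis[[length(cgis) + 1L]] <- data.table(
          cgi_id = sprintf("cgi_i_%04d", gid), chrom = chroms[ci],
          start = mid - half, end = mid + half - 1L,
          type = "intragenic", gene_id = sprintf("g%04d", gid))
      }
      cursor <- gend
    }
  }
  if (gid < spec$n_genes * 0.8) {
    .lm_stop("feature placement overflow: only %d of %d genes fit", gid,
             spec$n_genes)
  }
  gene_dt <- rbindlist(genes)
  cgi_dt <- rbindlist(cgis)

  ## blocked territory for LTR placement: exons and CGIs (+ margin keeps
  ## canonical TSSs outside any UpEdge window)
  blocked <- lapply(chroms, function(ch) {
    b <- rbind(gene_dt[chrom == ch, list(s = exon_start, e = exon_end)],
               cgi_dt[chrom == ch, list(s = start, e = end)])
    IRanges(b$s, b$e)
  })
  names(blocked) <- chroms

  ## --- LTR placement ----------------------------------------------------
  branches <- c("ancestral",
                if (!spec$strain_mode && length(sp_names) >= 3L) "pair",
                sp_names)
  branch_n <- setNames(integer(length(branches)), branches)
  branch_n["ancestral"] <- spec$n_ancestral_ltrs
  for (br in setdiff(branches, "ancestral")) {
    branch_n[br] <- if (br %in% names(spec$n_branch_ltrs))
      spec$n_branch_ltrs[[br]] else 0L
  }
  ltr_rows <- list()
  lid <- 0L
  for (br in branches) {
    nb <- branch_n[[br]]
    if (!nb) next
    tab <- .branch_subfamily_table(br, sp_names)
    per_chrom_n <- diff(floor(seq(0, nb, length.out = n_chrom + 1L)))
    for (ci in seq_len(n_chrom)) {
      if (!per_chrom_n[ci]) next
      starts <- .place_intervals(per_chrom_n[ci], spec$ltr_width,
                                 chrom_len[ci], blocked[[chroms[ci]]])
      widths <- attr(starts, "widths")
      for (k in seq_along(starts)) {
        lid <- lid + 1L
        ltr_rows[[lid]] <- data.table(
          ltr_id = sprintf("ltr%04d", lid), branch = br,
          chrom = chroms[ci], anc_start = starts[k],
          width = widths[k],
          subfamily = sample(names(tab), 1L, prob = tab),
          strand = sample(c("+", "-"), 1L))
        blocked[[chroms[ci]]] <- c(blocked[[chroms[ci]]],
                                   IRanges(starts[k], starts[k] + widths[k] - 1L))
      }
    }
  }
  ltr_dt <- rbindlist(ltr_rows)
  ltr_dt[, family := .subfamily_family(subfamily)]
  ltr_dt[, repeat_class := .repeat_class_from_family(family)]

  ## which branches each species carries
  path_of <- function(s) {
    idx <- match(s, sp_names)
    c("ancestral", if ("pair" %in% branches && idx <= 2L) "pair", s)
  }

  ## --- per-species coordinates -----------------------------------------
  indels <- !spec$strain_mode
  species_out <- list()
  ins_by_species <- list()
  for (s in sp_names) {
    present <- ltr_dt$branch %in% path_of(s)
    if (indels) {
      ## ancestral LTRs are frame features; branch LTRs are insertions
      ins <- ltr_dt[present & branch != "ancestral"]
      setorder(ins, chrom, anc_start)
    } else {
      ins <- ltr_dt[0]
    }
    ins_by_species[[s]] <- ins
    map_pos <- function(x, ch) {
      a <- ins[chrom == ch]
      .anc_to_species(x, a$anc_start - 1L, a$width)
    }
    seqlens <- setNames(chrom_len, chroms)
    for (ch in chroms) {
      seqlens[ch] <- seqlens[ch] + sum(ins[chrom == ch]$width)
    }
    ## genes
    gs <- copy(gene_dt)
    gs[, exon_start := map_pos(exon_start, chrom[1]), by = chrom]
    gs[, exon_end := map_pos(exon_end, chrom[1]), by = chrom]
    ex <- GRanges(gs$chrom, IRanges(gs$exon_start, gs$exon_end),
                  strand = gs$strand)
    seqlevels(ex) <- chroms
    seqlengths(ex) <- seqlens
    genes_ts <- transcript_set(ex, paste0("tx_", gs$gene_id), gs$gene_id,
                               NA_real_)
    ## CGIs
    cg <- copy(cgi_dt)
    cg[, start := map_pos(start, chrom[1]), by = chrom]
    cg[, end := map_pos(end, chrom[1]), by = chrom]
    cgr <- GRanges(cg$chrom, IRanges(cg$start, cg$end), cgi_id = cg$cgi_id,
                   type = cg$type, gene_id = cg$gene_id)
    seqlevels(cgr) <- chroms; seqlengths(cgr) <- seqlens
    ## repeats: mapped frame LTRs + this species' insertions
    frame_ltrs <- ltr_dt[present & (branch == "ancestral" | !indels)]
    fr <- copy(frame_ltrs)
    fr[, start := map_pos(anc_start, chrom[1]), by = chrom]
    fr[, end := start + width - 1L]
    rows <- fr[, list(ltr_id, chrom, start, end, strand, subfamily, family,
                      repeat_class)]
    if (indels && nrow(ins)) {
      i2 <- copy(ins)
      setorder(i2, chrom, anc_start)
      i2[, start := {
        cw <- c(0, cumsum(width))
        anc_start + head(cw, -1L)
      }, by = chrom]
      i2[, end := start + width - 1L]
      rows <- rbind(rows, i2[, list(ltr_id, chrom, start, end, strand,
                                    subfamily, family, repeat_class)])
    }
    setorder(rows, chrom, start)
    rep_gr <- GRanges(rows$chrom, IRanges(rows$start, rows$end),
                      strand = rows$strand)
    mcols(rep_gr) <- DataFrame(repeat_class = rows$repeat_class,
                               subfamily = rows$subfamily,
                               family = rows$family,
                               annotation_source = "simulated",
                               ltr_id = rows$ltr_id)
    seqlevels(rep_gr) <- chroms; seqlengths(rep_gr) <- seqlens
    species_out[[s]] <- list(genes = genes_ts, cgis = cgr, repeats = rep_gr,
                             seqlens = seqlens)
  }

  ## --- truth ledger: per-species placement of every LTR -----------------
  truth_ltrs <- copy(ltr_dt)
  for (s in sp_names) {
    reps <- species_out[[s]]$repeats
    idx <- match(truth_ltrs$ltr_id, mcols(reps)$ltr_id)
    truth_ltrs[[paste0("present_", s)]] <- !is.na(idx)
    truth_ltrs[[paste0("start_", s)]] <- start(reps)[idx]
    truth_ltrs[[paste0("end_", s)]] <- end(reps)[idx]
  }

  ## --- chains -----------------------------------------------------------
  chains <- list()
  for (a in sp_names) {
    chains[[a]] <- list()
    for (b in setdiff(sp_names, a)) {
      chains[[a]][[b]] <- .build_chains(a, b, ins_by_species, chroms,
                                        chrom_len, species_out)
    }
  }
  list(species = species_out, chains = chains,
       truth = list(ltrs = truth_ltrs), spec = spec,
       insertions = ins_by_species,
       ancestral = list(genes = gene_dt, cgis = cgi_dt, ltrs = ltr_dt,
                        chroms = chroms, chrom_len = setNames(chrom_len,
                                                              chroms)))
}

## exact chain construction between two species sharing the ancestral frame
.build_chains <- function(a, b, ins_by_species, chroms, chrom_len,
                          species_out) {
  ins_a <- ins_by_species[[a]]; ins_b <- ins_by_species[[b]]
  out <- list()
  cid <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    ia <- ins_a[chrom == ch]; ib <- ins_b[chrom == ch]
    shared_ids <- intersect(ia$ltr_id, ib$ltr_id)
    ev <- unique(rbind(ia[, list(ltr_id, anc_start, width)],
                       ib[, list(ltr_id, anc_start, width)]))
    setorder(ev, anc_start, ltr_id)
    Aa <- ia$anc_start - 1L; Wa <- ia$width
    Ab <- ib$anc_start - 1L; Wb <- ib$width
    oa <- order(Aa); Aa <- Aa[oa]; Wa <- Wa[oa]
    ob <- order(Ab); Ab <- Ab[ob]; Wb <- Wb[ob]
    map_a <- function(x) .anc_to_species(x, Aa, Wa)
    map_b <- function(x) .anc_to_species(x, Ab, Wb)
    blocks <- list()
    p <- 0L  # 0-based ancestral pointer
    add_anc <- function(p, a_end) {
      len <- a_end - p
      if (len > 0L) list(s_start = map_a(p + 1L), t_start = map_b(p + 1L),
                         len = len) else NULL
    }
    for (k in seq_len(nrow(ev))) {
      e <- ev[k]
      bl <- add_anc(p, e$anc_start - 1L)
      if (!is.null(bl)) blocks[[length(blocks) + 1L]] <- bl
      if (e$ltr_id %in% shared_ids) {
        sa <- .ins_species_start(e$ltr_id, ia)
        sb <- .ins_species_start(e$ltr_id, ib)
        blocks[[length(blocks) + 1L]] <- list(s_start = sa, t_start = sb,
                                              len = e$width)
      }
      p <- e$anc_start - 1L
    }
    bl <- add_anc(p, chrom_len[ci])
    if (!is.null(bl)) blocks[[length(blocks) + 1L]] <- bl
    bdt <- rbindlist(blocks)
    ## merge blocks contiguous in both genomes
    if (nrow(bdt) > 1L) {
      grp <- cumsum(c(TRUE, !(bdt$s_start[-1L] ==
                                bdt$s_start[-nrow(bdt)] + bdt$len[-nrow(bdt)] &
                              bdt$t_start[-1L] ==
                                bdt$t_start[-nrow(bdt)] + bdt$len[-nrow(bdt)])))
      bdt <- bdt[, list(s_start = s_start[1L], t_start = t_start[1L],
                        len = sum(len)), by = grp][, grp := NULL]
    }
    cid <- cid + 1L
    out[[cid]] <- list(score = 1000 + sum(bdt$len), s_chrom = ch,
                       s_size = unname(species_out[[a]]$seqlens[ch]),
                       s_start = bdt$s_start[1L] - 1L,
                       s_end = bdt$s_start[nrow(bdt)] + bdt$len[nrow(bdt)] - 1L,
                       t_chrom = ch,
                       t_size = unname(species_out[[b]]$seqlens[ch]),
                       t_start = bdt$t_start[1L] - 1L,
                       t_end = bdt$t_start[nrow(bdt)] + bdt$len[nrow(bdt)] - 1L,
                       chain_id = as.character(cid),
                       blocks = as.data.frame(bdt))
  }
  structure(out, class = "chain_set")
}

## species-frame start of an insertion (insertions sorted by position)
.ins_species_start <- function(id, ins) {
  setorder(ins, anc_start)
  cw <- c(0L, cumsum(ins$width))
  k <- match(id, ins$ltr_id)
  ins$anc_start[k] + cw[k]
}
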