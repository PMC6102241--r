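## End-to-end orchestration: analysis parameter block, cohort file export /
## import (the generator emits exactly the formats the readers consume),
## the full comparative analysis, result writing, and a one-command demo.

#' Analysis parameters with published defaults
#'
#' Every threshold used by the pipeline, under one declarative block that
#' round-trips through JSON unchanged. Defaults are the published cutoffs:
#' 1 kb bins with >=5 CpGs at >=5x, hypo/hyper classes at <30%/>70%,
#' LIT isoform share >10%, CGI synteny identity >0.5, CGI methylation over
#' >5 covered CpGs, strain Delta-DNAme >40%, PG retention >45%, maternal
#' DMR rule sperm <1% with blastocyst >30%.
#'
#' @param ... overrides of any default.
#' @return named list of parameters (class `litmeth_params`).
#' @export
analysis_params <- function(...) {
  p <- list(
    bin_width = 1000L, min_cpgs = 5L, min_depth = 5L,
    lo = 0.30, hi = 0.70, hyper_threshold = 0.70,
    penalty = NULL, min_segment = 2L,
    edge_window = 100L, min_share = 0.10,
    min_match = 0.5, identity_threshold = 0.5, identity_mode = "jaccard",
    cgi_min_cpgs = 6L, cgi_min_depth = 5L,
    tss_window = 500L, tail_extension = 2000L,
    d_meth = 0.40, k36_quantile = 0.75,
    t_oo = 0.70, t_retain = 0.45, t_sperm = 0.01, t_blast = 0.30)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) .lm_stop("unknown parameter(s): %s", paste(bad, collapse = ", "))
  structure(modifyList(p, over), class = "litmeth_params")
}

#' Write a simulated cohort to disk as standard files
#'
#' Emits, per species: annotated gene models and assembled transcripts
#' (GTF with FPKM), repeats (BED6+ with class/family token), CGIs (BED),
#' per-tissue CpG reports (bedGraph-style), an H3K36me3 bedGraph, a
#' per-repeat FPKM table and per-exon coverage table; pairwise chain files;
#' the truth ledger as TSV + JSON; and a `manifest.json`.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  fp <- function(...) file.path(dir, paste0(...))
  for (s in spec$species) {
    ann <- cohort$annotations$species[[s]]
    write_gtf_transcripts(ann$genes, fp(s, "_genes.gtf"))
    write_gtf_transcripts(cohort$transcripts[[s]], fp(s, "_transcripts.gtf"))
    reps <- ann$repeats
    rep_dt <- data.table(
      chrom = as.character(seqnames(reps)), start = start(reps) - 1L,
      end = end(reps), name = mcols(reps)$ltr_id, score = 0L,
      strand = as.character(strand(reps)),
      family = paste0(sub("^LTR/", "", mcols(reps)$family), "/",
                      mcols(reps)$subfamily))
    fwrite(rep_dt, fp(s, "_repeats.bed"), sep = "\t", col.names = FALSE,
           quote = FALSE)
    write_bed(ann$cgis, fp(s, "_cgis.bed"), name = "cgi_id")
    for (tis in names(cohort$meth[[s]])) {
      write_cpg_report(cohort$meth[[s]][[tis]], fp(s, "_", tis, ".cpg.tsv"))
    }
    k36 <- cohort$k36[[s]]
    fwrite(data.table(chrom = as.character(seqnames(k36)),
                      start = start(k36) - 1L, end = end(k36),
                      score = round(mcols(k36)$score, 6)),
           fp(s, "_k36.bedgraph"), sep = "\t", col.names = FALSE,
           quote = FALSE)
    fwrite(data.table(ltr_id = mcols(reps)$ltr_id,
                      fpkm = round(cohort$repeat_fpkm[[s]], 6)),
           fp(s, "_repeat_fpkm.tsv"), sep = "\t", quote = FALSE)
    cov <- cohort$coverage[[s]]
    cov_dt <- rbindlist(lapply(names(cov), function(id) {
      data.table(transcript_id = id, exon_rank = seq_along(cov[[id]]),
                 coverage = round(cov[[id]], 6))
    }))
    fwrite(cov_dt, fp(s, "_exon_coverage.tsv"), sep = "\t", quote = FALSE)
    ## seqlens
    fwrite(data.table(chrom = names(ann$seqlens),
                      length = unname(ann$seqlens)),
           fp(s, "_chrom.sizes"), sep = "\t", col.names = FALSE,
           quote = FALSE)
  }
  for (a in spec$species) for (b in setdiff(spec$species, a)) {
    write_chain(cohort$annotations$chains[[a]][[b]],
                fp(a, "_to_", b, ".chain"))
  }
  write_tsv(cohort$truth$ltrs, fp("truth_ltrs.tsv"))
  write_tsv(cohort$truth$lits, fp("truth_lits.tsv"))
  write_tsv(cohort$truth$cgis, fp("truth_cgis.tsv"))
  jsonlite::write_json(
    list(species = spec$species, tissues = names(cohort$meth[[1]]),
         seed = spec$seed, strain_mode = spec$strain_mode),
    fp("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory back into analysis inputs
#'
#' Reconstructs the analysis-facing inputs (never the truth ledger) from a
#' directory written by [write_cohort()], through the same readers any
#' external dataset would use.
#'
#' @param dir cohort directory.
#' @return list with `species`, per-species inputs and `chains`.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) .lm_stop("missing manifest: %s", man_path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  fp <- function(...) {
    p <- file.path(dir, paste0(...))
    if (!file.exists(p)) .lm_stop("manifest entry missing on disk: %s", p)
    p
  }
  out <- list(species = man$species, tissues = man$tissues, data = list(),
              chains = list())
  for (s in man$species) {
    sl <- fread(fp(s, "_chrom.sizes"), header = FALSE)
    seqlens <- setNames(sl[[2]], sl[[1]])
    meth <- list()
    for (tis in man$tissues) {
      m <- read_cpg_report(fp(s, "_", tis, ".cpg.tsv"), merge_dyads = FALSE)
      seqlevels(m) <- names(seqlens); seqlengths(m) <- seqlens
      meth[[tis]] <- m
    }
    k36 <- fread(fp(s, "_k36.bedgraph"), header = FALSE)
    k36_gr <- GRanges(k36[[1]], IRanges(k36[[2]] + 1L, k36[[3]]),
                      score = k36[[4]])
    covd <- fread(fp(s, "_exon_coverage.tsv"))
    cov <- split(covd$coverage, covd$transcript_id)
    rf <- fread(fp(s, "_repeat_fpkm.tsv"))
    repeats <- read_repeatmasker(fp(s, "_repeats.bed"))
    out$data[[s]] <- list(
      genes = read_gtf_transcripts(fp(s, "_genes.gtf")),
      transcripts = read_gtf_transcripts(fp(s, "_transcripts.gtf")),
      repeats = repeats,
      repeat_fpkm = rf$fpkm,
      cgis = read_bed(fp(s, "_cgis.bed")),
      meth = meth, k36 = k36_gr, coverage = cov, seqlens = seqlens)
  }
  for (a in man$species) {
    out$chains[[a]] <- list()
    for (b in setdiff(man$species, a)) {
      out$chains[[a]][[b]] <- read_chain(fp(a, "_to_", b, ".chain"))
    }
  }
  out
}

## CGI identifiers regardless of provenance (simulated mcols vs BED name)
.cgi_ids <- function(gr) {
  id <- mcols(gr)$cgi_id
  if (is.null(id)) id <- mcols(gr)$name
  if (is.null(id)) id <- paste0("cgi_", seq_along(gr))
  id
}

## hoist an in-memory cohort into the same shape read_cohort() returns
.cohort_inputs <- function(cohort) {
  spec <- cohort$spec
  data <- lapply(spec$species, function(s) {
    genes <- cohort$annotations$species[[s]]$genes
    txs <- cohort$transcripts[[s]]
    ## annotated models with expression: canonical rows of the assembly
    can <- txs[!is.na(mcols(txs)$gene_id)]
    list(genes = can, transcripts = txs,
         repeats = cohort$annotations$species[[s]]$repeats,
         repeat_fpkm = cohort$repeat_fpkm[[s]],
         cgis = cohort$annotations$species[[s]]$cgis,
         meth = cohort$meth[[s]], k36 = cohort$k36[[s]],
         coverage = cohort$coverage[[s]],
         seqlens = cohort$annotations$species[[s]]$seqlens)
  })
  names(data) <- spec$species
  list(species = spec$species, tissues = names(cohort$meth[[1]]),
       data = data, chains = cohort$annotations$chains)
}

#' Run the full comparative analysis
#'
#' Executes every stage over a cohort's inputs: binned scoring and domain
#' segmentation of each oocyte methylome, LIT calling and the active-LTR
#' scan, hyper-domain attribution, reciprocal-best syntenic bins with
#' stratified Venn partitions, syntenic-CGI identity matching and meCGI
#' classification, cross-species expression Z-scores, persistence
#' classification (and strain-differential calling in strain mode).
#'
#' @param inputs output of [read_cohort()], or a cohort from
#'   [simulate_cohort()] (hoisted automatically).
#' @param params an [analysis_params()] block.
#' @return result bundle (list; see the README walkthrough).
#' @export
run_cohort_analysis <- function(inputs, params = analysis_params()) {
  if (!is.null(inputs$annotations)) inputs <- .cohort_inputs(inputs)
  sp <- inputs$species
  hub <- sp[1]
  res <- list(params = params, species = sp, hub = hub, per_species = list())

  ## --- per-species landscape + LIT calling -----------------------------
  for (s in sp) {
    d <- inputs$data[[s]]
    bins <- score_bins(d$meth$oocyte, params$bin_width, params$min_cpgs,
                       params$min_depth, seqlens = d$seqlens)
    domains <- segment_domains(bins, penalty = params$penalty,
                               min_segment = params$min_segment,
                               lo = params$lo, hi = params$hi)
    genes <- d$genes
    lits <- call_lits(d$transcripts, d$repeats, genes,
                      min_share = params$min_share, coverage = d$coverage,
                      edge_window = params$edge_window)
    hyper <- domains[mcols(domains)$meth_class == "hyper"]
    lit_spans <- if (nrow(lits)) GRanges(lits$chrom,
                                         IRanges(lits$start, lits$end))
                 else GRanges()
    attr_s <- if (length(hyper)) attribute_domains(hyper, lit_spans, genes,
                                                   params$tail_extension)
              else NULL
    res$per_species[[s]] <- list(
      bins = bins, domains = domains, hyper = hyper,
      fractions = genome_fraction_by_class(domains, params$lo, params$hi),
      lits = lits, lit_spans = lit_spans,
      active_ltrs = active_ltr_scan(d$repeats, d$repeat_fpkm),
      rescue = rescue_lits_by_domain(d$transcripts, domains, d$repeats,
                                     primary_calls = lits),
      attribution = attr_s)
  }

  ## --- syntenic bins + Venn partitions ---------------------------------
  bins_by_sp <- lapply(sp, function(s) {
    granges(res$per_species[[s]]$bins)
  })
  names(bins_by_sp) <- sp
  units <- NULL
  if (length(sp) >= 2L) {
    fwd <- lapply(setdiff(sp, hub), function(b) inputs$chains[[hub]][[b]])
    names(fwd) <- setdiff(sp, hub)
    rev <- lapply(setdiff(sp, hub), function(b) inputs$chains[[b]][[hub]])
    names(rev) <- setdiff(sp, hub)
    units <- reciprocal_best_bins(bins_by_sp, fwd, rev, hub = hub,
                                  min_match = params$min_match)
    meth_mat <- sapply(sp, function(s) {
      mcols(res$per_species[[s]]$bins)$mean_meth[units[[paste0(s, "_bin")]]]
    })
    if (!is.matrix(meth_mat)) meth_mat <- matrix(meth_mat, ncol = length(sp),
                                                 dimnames = list(NULL, sp))
    covered <- rowSums(is.na(meth_mat)) == 0L
    units <- units[covered, , drop = FALSE]
    meth_mat <- meth_mat[covered, , drop = FALSE]
    lit_any <- rep(FALSE, nrow(units))
    for (s in sp) {
      b <- bins_by_sp[[s]][units[[paste0(s, "_bin")]]]
      lit_any <- lit_any | overlapsAny(b, res$per_species[[s]]$lit_spans,
                                       ignore.strand = TRUE)
    }
    genic_hub <- classify_genic(bins_by_sp[[hub]][units[[paste0(hub, "_bin")]]],
                                inputs$data[[hub]]$genes,
                                params$tail_extension)
    res$syntenic_bins <- list(
      units = units, meth = meth_mat, lit_overlap = lit_any,
      genic = genic_hub,
      n_syntenic = nrow(units),
      venn_all = venn_partition(meth_mat, params$hyper_threshold),
      venn_lit = venn_partition(meth_mat[lit_any, , drop = FALSE],
                                params$hyper_threshold),
      venn_nonlit = venn_partition(meth_mat[!lit_any, , drop = FALSE],
                                   params$hyper_threshold),
      venn_genic = venn_partition(meth_mat[genic_hub == "genic", ,
                                           drop = FALSE],
                                  params$hyper_threshold),
      venn_intergenic = venn_partition(meth_mat[genic_hub == "intergenic", ,
                                                drop = FALSE],
                                       params$hyper_threshold))
    res$bin_correlation <- correlate_profiles(meth_mat)
  }

  ## --- syntenic CGIs + meCGI classification ----------------------------
  cgi_meth <- lapply(sp, function(s) {
    region_methylation(inputs$data[[s]]$cgis, inputs$data[[s]]$meth$oocyte,
                       min_depth = params$cgi_min_depth,
                       min_cpgs = params$cgi_min_cpgs)
  })
  names(cgi_meth) <- sp
  hub_cgis <- inputs$data[[hub]]$cgis
  keep <- rep(TRUE, length(hub_cgis))
  partner <- list()
  for (s in setdiff(sp, hub)) {
    m <- match_syntenic_cgis(hub_cgis, inputs$data[[s]]$cgis,
                             inputs$chains[[hub]][[s]],
                             threshold = params$identity_threshold,
                             mode = params$identity_mode,
                             min_match = params$min_match)
    map <- rep(NA_integer_, length(hub_cgis))
    map[m$a] <- m$b
    partner[[s]] <- map
    keep <- keep & !is.na(map)
  }
  syn_idx <- which(keep)
  cgis_by_species <- list()
  cgis_by_species[[hub]] <- hub_cgis[syn_idx]
  meth_cgi <- matrix(NA_real_, length(syn_idx), length(sp),
                     dimnames = list(NULL, sp))
  meth_cgi[, hub] <- cgi_meth[[hub]]$mean_meth[syn_idx]
  for (s in setdiff(sp, hub)) {
    idx <- partner[[s]][syn_idx]
    cgis_by_species[[s]] <- inputs$data[[s]]$cgis[idx]
    meth_cgi[, s] <- cgi_meth[[s]]$mean_meth[idx]
  }
  lits_by_species <- lapply(sp, function(s) res$per_species[[s]]$lits)
  names(lits_by_species) <- sp
  mecgi <- classify_mecgi(meth_cgi, cgis_by_species, lits_by_species,
                          params$hyper_threshold)
  mecgi$cgi_id <- .cgi_ids(hub_cgis)[syn_idx]
  mecgi$context <- classify_cgi_context(hub_cgis[syn_idx],
                                        inputs$data[[hub]]$genes,
                                        params$tss_window)
  res$mecgi <- list(table = mecgi, meth = meth_cgi, hub_index = syn_idx,
                    cgis_by_species = cgis_by_species)

  ## --- expression Z-scores over shared genes ---------------------------
  gene_fpkm <- lapply(sp, function(s) {
    g <- inputs$data[[s]]$genes
    tapply(mcols(g)$fpkm, mcols(g)$gene_id, sum)
  })
  names(gene_fpkm) <- sp
  shared_genes <- Reduce(intersect, lapply(gene_fpkm, names))
  res$zscores <- list()
  for (s in setdiff(sp, hub)) {
    res$zscores[[paste0(hub, "_vs_", s)]] <- data.frame(
      gene_id = shared_genes,
      fpkm_a = unname(gene_fpkm[[hub]][shared_genes]),
      fpkm_b = unname(gene_fpkm[[s]][shared_genes]),
      z = expression_zscore(unname(gene_fpkm[[hub]][shared_genes]),
                            unname(gene_fpkm[[s]][shared_genes])))
  }

  ## --- persistence (hub species tissues) -------------------------------
  tis <- names(inputs$data[[hub]]$meth)
  get_cgi_meth <- function(t) {
    if (!t %in% tis) return(NULL)
    region_methylation(hub_cgis[syn_idx], inputs$data[[hub]]$meth[[t]],
                       min_depth = params$cgi_min_depth,
                       min_cpgs = params$cgi_min_cpgs)$mean_meth
  }
  oo <- meth_cgi[, hub]
  pg <- get_cgi_meth("pg_blastocyst")
  if (!is.null(pg)) {
    pers <- classify_persistence(oo, pg, mode = "pg", t_oo = params$t_oo,
                                 t_retain = params$t_retain,
                                 epiblast_wt = get_cgi_meth("epiblast"),
                                 epiblast_tetko = get_cgi_meth("epiblast_tetko"))
    shared_emb <- rep(FALSE, nrow(mecgi))
    for (s in setdiff(sp, hub)) {
      col <- paste0("embedded_", s)
      hyp <- !is.na(meth_cgi[, s]) & meth_cgi[, s] > params$hyper_threshold
      shared_emb <- shared_emb | (mecgi[[col]] & hyp)
    }
    privacy <- ifelse(shared_emb, "shared", "private")
    res$persistence_pg <- list(
      calls = cbind(data.frame(cgi_id = mecgi$cgi_id), pers,
                    oocyte = oo, pg_blastocyst = pg),
      by_lit = persistence_by_lit(pers$fate, mecgi$lit_embedded, privacy))
  }
  sperm <- get_cgi_meth("sperm"); bl <- get_cgi_meth("blastocyst")
  if (!is.null(sperm) && !is.null(bl)) {
    persb <- classify_persistence(oo, bl, sperm, mode = "biparental",
                                  t_oo = params$t_oo,
                                  t_sperm = params$t_sperm,
                                  t_blast = params$t_blast)
    res$persistence_biparental <- list(
      calls = cbind(data.frame(cgi_id = mecgi$cgi_id), persb,
                    oocyte = oo, sperm = sperm, blastocyst = bl),
      by_lit = persistence_by_lit(persb$fate, mecgi$lit_embedded))
  }

  ## --- strain differential (two same-frame strains) --------------------
  if (length(sp) == 2L) {
    a <- sp[1]; b <- sp[2]
    k36_at <- function(s, gr) {
      k <- inputs$data[[s]]$k36
      ov <- findOverlaps(gr, k, ignore.strand = TRUE)
      out <- rep(NA_real_, length(gr))
      m <- tapply(mcols(k)$score[subjectHits(ov)], queryHits(ov), mean)
      out[as.integer(names(m))] <- m
      out
    }
    ## strains share coordinates: score both methylomes over hub CGIs
    cg <- inputs$data[[a]]$cgis
    ma <- region_methylation(cg, inputs$data[[a]]$meth$oocyte,
                             min_depth = 1L, min_cpgs = 4L)$mean_meth
    mb <- region_methylation(cg, inputs$data[[b]]$meth$oocyte,
                             min_depth = 1L, min_cpgs = 4L)$mean_meth
    res$strain_diff <- data.frame(
      cgi_id = .cgi_ids(cg),
      meth_a = ma, meth_b = mb,
      call = strain_differential(ma, mb, k36_at(a, cg), k36_at(b, cg),
                                 d_meth = params$d_meth,
                                 k36_quantile = params$k36_quantile))
  }

  .check_conservation(res)
  res
}

## conservation invariants asserted on every run
.check_conservation <- function(res) {
  sb <- res$syntenic_bins
  if (!is.null(sb)) {
    for (v in c("venn_all", "venn_lit", "venn_nonlit")) {
      p <- sb[[v]]
      stopifnot(sum(p$counts) == p$n_hyper_any,
                p$n_hyper_any + p$n_hypo_all + p$n_excluded == p$n_input)
    }
  }
  for (s in res$species) {
    at <- res$per_species[[s]]$attribution
    if (!is.null(at)) stopifnot(abs(sum(at$fractions) - 1) < 1e-9)
  }
  for (nm in c("persistence_pg", "persistence_biparental")) {
    p <- res[[nm]]
    if (!is.null(p)) stopifnot(sum(p$by_lit) == nrow(p$calls))
  }
  invisible(TRUE)
}

#' Write an analysis result bundle to disk
#'
#' Plain TSV/BED/JSON outputs so any stage can be inspected or re-run
#' standalone; a run manifest records parameters and input checksums.
#'
#' @param res result of [run_cohort_analysis()].
#' @param outdir output directory (created).
#' @param input_dir optional cohort directory, checksummed into the
#'   manifest.
#' @return `outdir`, invisibly.
#' @export
write_results <- function(res, outdir, input_dir = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, paste0(...))
  frac <- list()
  for (s in res$species) {
    ps <- res$per_species[[s]]
    write_bed(ps$domains, fp(s, "_domains.bed"), name = "meth_class",
              score = "mean_meth")
    write_tsv(ps$lits, fp(s, "_lits.tsv"))
    frac[[s]] <- data.table(species = s,
                            hypo = ps$fractions[["hypo"]],
                            intermediate = ps$fractions[["intermediate"]],
                            hyper = ps$fractions[["hyper"]])
    if (!is.null(ps$attribution)) {
      write_tsv(data.table(class = names(ps$attribution$fractions),
                           fraction = as.numeric(ps$attribution$fractions),
                           species = s),
                fp(s, "_attribution.tsv"))
    }
  }
  write_tsv(rbindlist(frac), fp("genome_fractions.tsv"))
  if (!is.null(res$syntenic_bins)) {
    sb <- res$syntenic_bins
    venn <- lapply(sb[c("venn_all", "venn_lit", "venn_nonlit",
                        "venn_genic", "venn_intergenic")], function(p) {
      list(counts = as.list(p$counts), n_hyper_any = p$n_hyper_any,
           n_hypo_all = p$n_hypo_all, n_excluded = p$n_excluded,
           n_input = p$n_input)
    })
    jsonlite::write_json(venn, fp("venn.json"), auto_unbox = TRUE,
                         digits = NA)
    ub <- as.data.table(sb$units)
    ub[, lit_overlap := sb$lit_overlap]
    ub[, genic := sb$genic]
    for (s in res$species) ub[[paste0("meth_", s)]] <- sb$meth[, s]
    write_tsv(ub, fp("syntenic_bins.tsv"))
  }
  if (!is.null(res$mecgi)) write_tsv(res$mecgi$table, fp("mecgi.tsv"))
  for (nm in names(res$zscores)) {
    write_tsv(res$zscores[[nm]], fp("zscores_", nm, ".tsv"))
  }
  if (!is.null(res$persistence_pg)) {
    write_tsv(res$persistence_pg$calls, fp("persistence_pg.tsv"))
    write_tsv(as.data.frame(res$persistence_pg$by_lit),
              fp("persistence_pg_by_lit.tsv"))
  }
  if (!is.null(res$persistence_biparental)) {
    write_tsv(res$persistence_biparental$calls,
              fp("persistence_biparental.tsv"))
  }
  if (!is.null(res$strain_diff)) {
    write_tsv(res$strain_diff, fp("strain_differential.tsv"))
  }
  manifest <- list(
    package = "litmeth",
    version = as.character(utils::packageVersion("litmeth")),
    parameters = res$params[!vapply(res$params, is.null, TRUE)],
    species = res$species, hub = res$hub)
  if (!is.null(input_dir)) {
    files <- sort(list.files(input_dir, full.names = TRUE))
    manifest$input_checksums <- as.list(setNames(unname(md5sum(files)),
                                                 basename(files)))
  }
  jsonlite::write_json(manifest, fp("run_manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}

#' One-command synthetic demo
#'
#' Simulates a three-species cohort, writes it to disk in standard formats,
#' reads it back through the package's own readers, runs the full analysis
#' and writes the result bundle. Deterministic given `seed`: rerunning into
#' a second directory yields byte-identical result tables.
#'
#' @param seed RNG seed.
#' @param outdir output directory (`inputs/` and `results/` inside).
#' @param spec optional [cohort_spec()] override (its seed is replaced).
#' @param params optional [analysis_params()].
#' @return the result bundle, invisibly (with `$outdir` set).
#' @export
litmeth_demo <- function(seed = 7L, outdir = tempfile("litmeth_demo_"),
                         spec = NULL, params = analysis_params()) {
  if (is.null(spec)) spec <- cohort_spec(seed = seed)
  else { spec$seed <- seed }
  cohort <- simulate_cohort(spec)
  input_dir <- file.path(outdir, "inputs")
  write_cohort(cohort, input_dir)
  inputs <- read_cohort(input_dir)
  res <- run_cohort_analysis(inputs, params)
  write_results(res, file.path(outdir, "results"), input_dir = input_dir)
  res$outdir <- outdir
  invisible(res)
}
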