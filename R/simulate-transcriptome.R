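## Transcriptome stage of the cohort generator: shared gene expression with
## per-species jitter, per-species LTR activity, and LIT construction
## (sense-chimeric, antisense, intergenic) with Up/UpEdge TSS geometry.

#' Simulate per-species oocyte transcriptomes
#'
#' Gene expression states and base FPKM are drawn once and shared across
#' species (genic programs are concordant); LTR activity is drawn per
#' species carrying the element unless `spec$shared_activity`. Every active
#' LTR emits one transcript initiating within (Up geometry) or at the edge
#' of (UpEdge) the element; near or inside a same-strand gene it may splice
#' into downstream genic exons (sense chimera, optionally suppressing the
#' canonical TSS), otherwise it runs as an antisense or intergenic unit.
#'
#' @param ann output of [simulate_annotations()].
#' @return list with per-species `transcripts` (TranscriptSet: canonical +
#'   LIT), `coverage` (per transcript, mean per-exon read coverage),
#'   `repeat_fpkm` (per repeat-annotation row), and a `truth` ledger of
#'   planted LITs and expected CGI consequences of transcription.
#' @export
simulate_transcriptome <- function(ann) {
  spec <- ann$spec
  set.seed(.stage_seed(spec$seed, 2L))
  sp_names <- spec$species
  truth_ltrs <- ann$truth$ltrs

  ## shared genic program
  gene_ids <- unique(mcols(ann$species[[1]]$genes)$gene_id)
  expressed <- runif(length(gene_ids)) < spec$p_gene_expressed
  base_fpkm <- ifelse(expressed,
                      1.5 + rlnorm(length(gene_ids), spec$fpkm_meanlog,
                                   spec$fpkm_sdlog),
                      runif(length(gene_ids), 0, 0.5))
  names(base_fpkm) <- gene_ids

  ## LTR activity
  shared_draw <- runif(nrow(truth_ltrs)) < spec$p_active
  active <- matrix(FALSE, nrow(truth_ltrs), length(sp_names),
                   dimnames = list(truth_ltrs$ltr_id, sp_names))
  for (s in sp_names) {
    present <- truth_ltrs[[paste0("present_", s)]]
    if (spec$shared_activity) {
      active[, s] <- present & shared_draw
    } else {
      active[, s] <- present & (runif(nrow(truth_ltrs)) < spec$p_active)
    }
  }

  ## per-element transcript geometry, drawn once per LTR so a shared
  ## element yields a concordant unit in every species carrying it
  n_l <- nrow(truth_ltrs)
  ltr_par <- data.table(
    upedge = runif(n_l) < spec$p_upedge,
    tss_frac = runif(n_l, 0.30, 0.50),
    edge_off = sample(10:80, n_l, replace = TRUE),
    chim = runif(n_l) < spec$p_chimeric,
    suppress = runif(n_l) < spec$p_suppress_canonical,
    span_len = sample(spec$lit_length[1]:spec$lit_length[2], n_l,
                      replace = TRUE),
    gap_len = sample(800:2000, n_l, replace = TRUE),
    fpkm = 1.5 + rlnorm(n_l, spec$fpkm_meanlog, spec$fpkm_sdlog))

  out <- list(transcripts = list(), coverage = list(), repeat_fpkm = list())
  lit_truth <- list()
  for (s in sp_names) {
    genes <- ann$species[[s]]$genes
    reps <- ann$species[[s]]$repeats
    seqlens <- ann$species[[s]]$seqlens
    gspans <- tx_spans(genes)
    gexons <- unlist(genes, use.names = FALSE)
    gex_tx <- rep(seq_along(genes), lengths(genes))
    fpkm_s <- base_fpkm[mcols(genes)$gene_id] * rlnorm(length(genes), 0, 0.1)

    lit_exons <- list(); lit_meta <- list()
    act <- which(active[, s])
    for (k in act) {
      row <- truth_ltrs[k]
      ls <- row[[paste0("start_", s)]]; le <- row[[paste0("end_", s)]]
      lstr <- row$strand; ch <- row$chrom
      w <- le - ls + 1L
      upedge <- ltr_par$upedge[k]
      if (lstr == "+") {
        tss <- if (upedge) ls - ltr_par$edge_off[k]
               else ls + max(1L, floor(ltr_par$tss_frac[k] * w))
        e1_end <- le + 300L
      } else {
        tss <- if (upedge) le + ltr_par$edge_off[k]
               else le - max(1L, floor(ltr_par$tss_frac[k] * w))
        e1_end <- ls - 300L  # 5'->3' on minus strand
      }
      if (tss < 1L || tss > seqlens[[ch]]) next
      ## candidate gene for a sense chimera
      gene_idx <- .chimera_target(ch, lstr, tss, e1_end, gspans, ls, le,
                                  spec$upstream_window)
      fpkm_lit <- ltr_par$fpkm[k] * rlnorm(1, 0, 0.05)
      made <- FALSE
      kind <- "intergenic"
      cgi_hit_gene <- NA_character_
      if (!is.na(gene_idx) && ltr_par$chim[k]) {
        gex <- gexons[gex_tx == gene_idx]
        if (lstr == "+") {
          gex <- gex[order(start(gex))]
          cand <- which(start(gex) > max(tss, e1_end) + 100L)
          cand <- cand[cand >= 2L]
          if (length(cand)) {
            e1 <- GRanges(ch, IRanges(tss, min(e1_end, start(gex)[cand[1]] - 50L)),
                          strand = "+")
            exs <- c(e1, gex[cand[1]:length(gex)])
            made <- TRUE
          }
        } else {
          gex <- gex[order(start(gex), decreasing = TRUE)]
          cand <- which(end(gex) < min(tss, e1_end) - 100L)
          cand <- cand[cand >= 2L]
          if (length(cand)) {
            e1 <- GRanges(ch, IRanges(max(e1_end, end(gex)[cand[1]] + 50L), tss),
                          strand = "-")
            exs <- c(e1, gex[cand[1]:length(gex)])
            made <- TRUE
          }
        }
        if (made) {
          kind <- "sense-chimeric"
          upstream_of_tss <- if (lstr == "+") tss < start(gspans)[gene_idx]
                             else tss > end(gspans)[gene_idx]
          if (upstream_of_tss) {
            cgi_hit_gene <- mcols(genes)$gene_id[gene_idx]
            if (ltr_par$suppress[k]) {
              fpkm_s[gene_idx] <- runif(1, 0, 0.1)
            }
          }
        }
      }
      if (!made) {
        span_len <- ltr_par$span_len[k]
        gap <- ltr_par$gap_len[k]
        if (lstr == "+") {
          end3 <- min(tss + span_len, seqlens[[ch]] - 10L)
          if (end3 - tss < 800L) next  # no room at the chromosome edge
          mid <- min(e1_end, end3 - 200L)
          ir <- IRanges(tss, mid)
          if (mid + gap < end3) ir <- c(ir, IRanges(mid + gap, end3))
          exs <- GRanges(ch, ir, strand = "+")
        } else {
          end3 <- max(tss - span_len, 10L)
          if (tss - end3 < 800L) next
          mid <- max(e1_end, end3 + 200L)
          ir <- IRanges(mid, tss)
          if (mid - gap > end3) ir <- c(IRanges(end3, mid - gap), ir)
          exs <- GRanges(ch, ir, strand = "-")
        }
        opp <- gspans[as.character(strand(gspans)) != lstr]
        kind <- if (length(findOverlaps(GRanges(ch, IRanges(min(start(exs)),
                                                            max(end(exs)))),
                                        opp, ignore.strand = TRUE)))
          "antisense" else "intergenic"
      }
      id <- sprintf("lit_%s_%s", s, row$ltr_id)
      lit_exons[[id]] <- exs
      lit_meta[[id]] <- data.table(
        transcript_id = id, species = s, ltr_id = row$ltr_id,
        subfamily = row$subfamily, branch = row$branch,
        category_truth = if (upedge) "UpEdge" else "Up",
        kind = kind, fpkm = fpkm_lit,
        tss = tss, span_start = min(start(exs)), span_end = max(end(exs)),
        chrom = ch, strand = lstr,
        cgi_target_gene = cgi_hit_gene)
    }

    ## assemble the species transcriptome: canonical + LIT
    can_ex <- unlist(genes, use.names = FALSE)
    can_id <- rep(mcols(genes)$transcript_id, lengths(genes))
    can_gene <- rep(mcols(genes)$gene_id, lengths(genes))
    can_fpkm <- rep(fpkm_s, lengths(genes))
    lit_ex <- if (length(lit_exons)) unlist(GRangesList(lit_exons),
                                            use.names = FALSE) else GRanges()
    lit_n <- vapply(lit_exons, length, 1L)
    meta <- if (length(lit_meta)) rbindlist(lit_meta) else NULL
    ex_all <- c(can_ex, lit_ex)
    id_all <- c(can_id, rep(names(lit_exons), lit_n))
    gene_all <- c(can_gene, rep(NA_character_, length(lit_ex)))
    fpkm_all <- c(can_fpkm, if (is.null(meta)) numeric(0) else
      rep(meta$fpkm, lit_n))
    seqlevels(ex_all) <- names(seqlens)
    seqlengths(ex_all) <- seqlens
    txs <- transcript_set(ex_all, id_all, gene_all, fpkm_all)

    ## per-exon mean read coverage, proportional to expression
    cov <- lapply(seq_along(txs), function(i) {
      f <- mcols(txs)$fpkm[i]
      pmax(0, f * 20 * rlnorm(lengths(txs)[i], 0, 0.05))
    })
    names(cov) <- mcols(txs)$transcript_id

    ## per-repeat expression for the active-LTR scan
    rf <- runif(length(reps), 0, 0.6)
    if (!is.null(meta) && nrow(meta)) {
      idx <- match(meta$ltr_id, mcols(reps)$ltr_id)
      rf[idx] <- meta$fpkm
    }
    out$transcripts[[s]] <- txs
    out$coverage[[s]] <- cov
    out$repeat_fpkm[[s]] <- rf
    if (!is.null(meta)) lit_truth[[s]] <- meta
  }
  lit_dt <- if (length(lit_truth)) rbindlist(lit_truth) else
    data.table(transcript_id = character(0), species = character(0))
  ## privacy of the driving element: shared when its branch reaches >1
  ## species of the cohort
  if (nrow(lit_dt)) {
    lit_dt[, privacy := ifelse(branch %in% c("ancestral", "pair"),
                               "shared", "private")]
  }
  out$truth <- list(lits = lit_dt, active = active,
                    gene_fpkm = base_fpkm, expressed = expressed)
  out
}

## nearest same-strand gene an LTR can splice into: the LTR lies inside the
## gene or within `window` bp upstream of its TSS
.chimera_target <- function(ch, lstr, tss, e1_end, gspans, ls, le, window) {
  same <- which(as.character(strand(gspans)) == lstr &
                  as.character(seqnames(gspans)) == ch)
  if (!length(same)) return(NA_integer_)
  gs <- gspans[same]
  if (lstr == "+") {
    inside <- ls >= start(gs) & le <= end(gs)
    upstream <- start(gs) - le
    ok <- inside | (upstream > 0L & upstream <= window)
    cand <- same[ok]
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(start(gspans)[cand] - tss))]
  } else {
    inside <- ls >= start(gs) & le <= end(gs)
    upstream <- ls - end(gs)
    ok <- inside | (upstream > 0L & upstream <= window)
    cand <- same[ok]
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(end(gspans)[cand] - tss))]
  }
}
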