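## I/O boundary: bedGraph-style CpG reports, RepeatMasker .out / BED repeats,
## GTF transcript models, UCSC chains, BED and TSV writers. Internally all
## coordinates live in GRanges (1-based, closed); 0-based half-open formats
## (BED, bedGraph, chain) are converted here and only here.

#' Read a bedGraph-style per-CpG methylation report
#'
#' Expects columns chrom, start, end, methylated count, unmethylated count
#' (dialect `"meth_unmeth"`, the default) or chrom, start, end, methylated
#' count, total count (dialect `"meth_total"`). Starts are 0-based half-open
#' unless `zero_based = FALSE`.
#'
#' With `merge_dyads = TRUE` (the default; symmetric CpG methylation is
#' assumed) calls at adjacent positions forming a CpG dyad are summed into a
#' single record anchored at the plus-strand cytosine.
#'
#' @param path path to the report.
#' @param merge_dyads merge plus/minus strand calls at a CpG dyad.
#' @param dialect count-column dialect, see Details.
#' @param zero_based are input starts 0-based half-open?
#' @param chrom_alias optional named character vector renaming chromosomes.
#' @return a `MethTable`: a sorted `GRanges` of width-1 CpG positions with
#'   metadata columns `meth` and `total`.
#' @export
read_cpg_report <- function(path, merge_dyads = TRUE,
                            dialect = c("meth_unmeth", "meth_total"),
                            zero_based = TRUE, chrom_alias = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .lm_stop("no such file: %s", path)
  if (file.size(path) == 0L) {
    return(meth_table(GRanges(), integer(0), integer(0)))
  }
  dt <- fread(path, header = FALSE, fill = TRUE, colClasses = "character",
              showProgress = FALSE)
  if (nrow(dt) == 0L) return(meth_table(GRanges(), integer(0), integer(0)))
  if (ncol(dt) < 5L) {
    .lm_stop("CpG report %s: expected >= 5 columns, found %d", path, ncol(dt))
  }
  num <- suppressWarnings(lapply(dt[, 2:5], as.numeric))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    .lm_stop("CpG report %s: malformed line %d", path, bad[1])
  }
  chrom <- normalize_chroms(dt[[1]], chrom_alias)
  start <- num[[1]] + if (zero_based) 1L else 0L
  m <- as.integer(num[[3]])
  tot <- if (dialect == "meth_total") as.integer(num[[4]]) else
    m + as.integer(num[[4]])
  if (any(m < 0L) || any(tot < 0L)) {
    .lm_stop("CpG report %s: negative counts", path)
  }
  if (any(m > tot)) {
    .lm_stop("CpG report %s: methylated count exceeds total at line %d",
             path, which(m > tot)[1])
  }
  gr <- GRanges(chrom, IRanges(start, width = 1L), meth = m, total = tot)
  gr <- sort(sortSeqlevels(gr))
  if (merge_dyads) gr <- .merge_dyads(gr)
  gr
}

## Sum records at adjacent positions (pos, pos + 1) into one dyad record.
## Greedy left-to-right pairing; idempotent because merged records sit at
## least 2 bp apart.
.merge_dyads <- function(gr) {
  if (length(gr) < 2L) return(gr)
  same_chrom <- as.character(seqnames(gr))[-length(gr)] ==
    as.character(seqnames(gr))[-1L]
  adjacent <- same_chrom & diff(start(gr)) == 1L
  keep <- rep(TRUE, length(gr))
  i <- 1L
  while (i < length(gr)) {
    if (adjacent[i] && keep[i]) {
      mcols(gr)$meth[i] <- mcols(gr)$meth[i] + mcols(gr)$meth[i + 1L]
      mcols(gr)$total[i] <- mcols(gr)$total[i] + mcols(gr)$total[i + 1L]
      keep[i + 1L] <- FALSE
      i <- i + 2L
    } else i <- i + 1L
  }
  gr[keep]
}

#' Construct a MethTable from components
#'
#' @param sites `GRanges` of CpG positions.
#' @param meth,total non-negative integer read counts, `meth <= total`.
#' @return sorted `GRanges` with `meth` and `total` metadata columns.
#' @export
meth_table <- function(sites, meth, total) {
  meth <- as.integer(meth); total <- as.integer(total)
  .check_nonneg(meth); .check_nonneg(total)
  if (any(meth > total)) .lm_stop("meth count exceeds total")
  mcols(sites)$meth <- meth
  mcols(sites)$total <- total
  sort(sortSeqlevels(sites))
}

## class/family token -> coarse LTR class used throughout.
.repeat_class_from_family <- function(family) {
  cls <- rep("other", length(family))
  cls[grepl("MaLR", family)] <- "LTR-MaLR"
  cls[grepl("ERV1", family) & cls == "other"] <- "LTR-ERV1"
  cls[grepl("ERVK", family) & cls == "other"] <- "LTR-ERVK"
  cls[grepl("ERVL", family) & cls == "other"] <- "LTR-ERVL"
  cls
}

## repeat name -> subfamily (strip species/internal suffixes).
.repeat_subfamily <- function(name) {
  sub("(_Mm|_Rn|_Hs|-int)$", "", name)
}

#' Read a repeat annotation (RepeatMasker .out or BED6+)
#'
#' RepeatMasker `.out` files (fixed-column, 1-based inclusive, with the
#' standard two header lines) and BED-style files (0-based half-open) are
#' both accepted; the format is sniffed from the first data line. The
#' "class/family" token is parsed into a coarse `repeat_class`
#' (LTR-MaLR, LTR-ERV1, LTR-ERVK, LTR-ERVL, other) and a `subfamily`.
#'
#' @param path input file.
#' @param chrom_alias optional chromosome renaming map.
#' @return `GRanges` with metadata columns `repeat_class`, `subfamily`,
#'   `annotation_source`.
#' @export
read_repeatmasker <- function(path, chrom_alias = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(GRanges(repeat_class = character(0), subfamily = character(0),
                   annotation_source = character(0)))
  }
  is_out <- grepl("^\\s*(SW|score)", lines[1]) ||
    grepl("^\\s*\\d+\\s+[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s+\\S+\\s+\\d+\\s+\\d+",
          lines[1])
  if (is_out) {
    body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    fields <- strsplit(trimws(body), "\\s+")
    n_ok <- vapply(fields, length, 1L) >= 11L
    if (!all(n_ok)) .lm_stop("repeat file %s: unrecognized .out line", path)
    chrom <- normalize_chroms(vapply(fields, `[[`, "", 5L), chrom_alias)
    qstart <- as.integer(vapply(fields, `[[`, "", 6L))
    qend <- as.integer(vapply(fields, `[[`, "", 7L))
    strand <- vapply(fields, `[[`, "", 9L)
    strand <- ifelse(strand == "C", "-", "+")
    name <- vapply(fields, `[[`, "", 10L)
    family <- vapply(fields, `[[`, "", 11L)
    gr <- GRanges(chrom, IRanges(qstart, qend), strand = strand)
    mcols(gr)$repeat_class <- .repeat_class_from_family(family)
    mcols(gr)$subfamily <- .repeat_subfamily(name)
    mcols(gr)$annotation_source <- "repeatmasker_out"
    return(sort(sortSeqlevels(gr), ignore.strand = TRUE))
  }
  ## BED6+ with a class/family token in column 7 (or combined in column 4)
  dt <- fread(path, header = FALSE, fill = TRUE, showProgress = FALSE)
  if (ncol(dt) < 4L) .lm_stop("repeat file %s: unknown format", path)
  chrom <- normalize_chroms(as.character(dt[[1]]), chrom_alias)
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  token <- if (ncol(dt) >= 7L) as.character(dt[[7]]) else as.character(dt[[4]])
  parts <- strsplit(token, "/", fixed = TRUE)
  first <- vapply(parts, `[[`, "", 1L)
  last <- vapply(parts, function(p) p[[length(p)]], "")
  combined <- grepl("ERV|MaLR", first)  # e.g. "ERVL-MaLR/MTA_Mm"
  family <- ifelse(combined, first, token)
  name <- ifelse(combined, last, as.character(dt[[4]]))
  gr <- GRanges(chrom, IRanges(as.integer(dt[[2]]) + 1L, as.integer(dt[[3]])),
                strand = strand)
  mcols(gr)$repeat_class <- .repeat_class_from_family(family)
  mcols(gr)$subfamily <- .repeat_subfamily(name)
  mcols(gr)$annotation_source <- "bed"
  sort(sortSeqlevels(gr), ignore.strand = TRUE)
}

#' Read transcript models from a GTF file
#'
#' Exon records are grouped by `transcript_id` and ordered 5' to 3'
#' (descending coordinates on the minus strand). An `FPKM` attribute, when
#' present (Cufflinks-style assemblies), is carried into `mcols()$fpkm`.
#'
#' @param path GTF file (1-based inclusive; converted on read).
#' @param chrom_alias optional chromosome renaming map.
#' @return a `TranscriptSet`: a `GRangesList` of exons, one element per
#'   transcript, with metadata columns `transcript_id`, `gene_id`, `fpkm`.
#' @export
read_gtf_transcripts <- function(path, chrom_alias = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "exon"]
  if (!is.null(chrom_alias)) {
    seqlevels(gr) <- normalize_chroms(seqlevels(gr), chrom_alias)
  }
  fpkm <- if ("FPKM" %in% names(mcols(gr))) {
    suppressWarnings(as.numeric(mcols(gr)$FPKM))
  } else rep(NA_real_, length(gr))
  ids <- mcols(gr)$transcript_id
  gene <- if ("gene_id" %in% names(mcols(gr))) mcols(gr)$gene_id else
    rep(NA_character_, length(gr))
  exons <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
  transcript_set(exons, ids, gene, fpkm)
}

#' Assemble a TranscriptSet from exon records
#'
#' @param exons `GRanges` of exons (any order).
#' @param transcript_id,gene_id per-exon identifiers.
#' @param fpkm per-exon expression value (constant within a transcript).
#' @return `GRangesList` keyed by transcript with 5'->3' ordered exons and
#'   `transcript_id`, `gene_id`, `fpkm` metadata.
#' @export
transcript_set <- function(exons, transcript_id, gene_id = NA, fpkm = NA) {
  if (length(exons) == 0L) {
    out <- GRangesList()
    mcols(out) <- DataFrame(transcript_id = character(0),
                            gene_id = character(0), fpkm = numeric(0))
    return(out)
  }
  gene_id <- rep_len(as.character(gene_id), length(exons))
  fpkm <- rep_len(as.numeric(fpkm), length(exons))
  ord <- order(transcript_id, start(exons))
  exons <- exons[ord]
  transcript_id <- transcript_id[ord]
  gene_id <- gene_id[ord]; fpkm <- fpkm[ord]
  grl <- split(exons, factor(transcript_id, levels = unique(transcript_id)))
  ## 5'->3' order within each transcript
  neg <- vapply(grl, function(g) as.character(strand(g))[1] == "-", TRUE)
  grl[neg] <- endoapply(grl[neg], rev)
  firsts <- cumsum(c(1L, head(lengths(grl), -1L)))
  idx <- match(names(grl), transcript_id)
  mcols(grl) <- DataFrame(transcript_id = names(grl),
                          gene_id = gene_id[idx], fpkm = fpkm[idx])
  grl
}

#' Transcript spans and 5' ends
#'
#' `tx_spans()` returns one stranded range per transcript (TSS..TTS);
#' `tx_tss()` the width-1 5' anchor of each span.
#'
#' @param txs a `TranscriptSet`.
#' @return `GRanges`, parallel to `txs`, carrying its metadata.
#' @export
tx_spans <- function(txs) {
  if (length(txs) == 0L) return(GRanges())
  sp <- unlist(range(txs), use.names = FALSE)
  mcols(sp) <- mcols(txs)
  sp
}

#' @rdname tx_spans
#' @export
tx_tss <- function(txs) {
  sp <- tx_spans(txs)
  resize(sp, width = 1L, fix = "start")
}

#' Write transcript models to GTF
#'
#' @param txs a `TranscriptSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf_transcripts <- function(txs, path) {
  if (length(txs) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  ex <- unlist(txs, use.names = FALSE)
  n <- lengths(txs)
  tid <- rep(mcols(txs)$transcript_id, n)
  gid <- rep(mcols(txs)$gene_id, n)
  fpkm <- rep(mcols(txs)$fpkm, n)
  gid[is.na(gid)] <- tid[is.na(gid)]
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; FPKM "%.6f";',
                      gid, tid, ifelse(is.na(fpkm), 0, fpkm))
  lines <- sprintf("%s\tlitmeth\texon\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(seqnames(ex)), start(ex), end(ex),
                   as.character(strand(ex)), attr_str)
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Parses the UCSC chain grammar into a list of chain records. By the UCSC
#' liftover convention the *target* coordinates of the header are the source
#' assembly of the projection and the *query* coordinates the destination.
#' Blocks are validated against the header spans; an overflowing block is a
#' format error. Reverse-strand chains are rejected (colinear blocks only).
#'
#' @param path chain file.
#' @param chrom_alias optional chromosome renaming map.
#' @return an object of class `chain_set`: a list of chains, each a list
#'   with `chain_id`, `score`, `s_chrom`, `s_size`, `t_chrom`, `t_size`,
#'   and a `blocks` data.frame with 1-based `s_start`, `t_start`, `len`.
#' @export
read_chain <- function(path, chrom_alias = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 13L) {
      .lm_stop("chain file %s: expected chain header at line %d", path, i)
    }
    if (f[5] != "+" || f[10] != "+") {
      .lm_stop("chain file %s: reverse-strand chain rejected (line %d)", path, i)
    }
    hdr <- list(score = as.numeric(f[2]),
                s_chrom = normalize_chroms(f[3], chrom_alias),
                s_size = as.numeric(f[4]),
                s_start = as.numeric(f[6]), s_end = as.numeric(f[7]),
                t_chrom = normalize_chroms(f[8], chrom_alias),
                t_size = as.numeric(f[9]),
                t_start = as.numeric(f[11]), t_end = as.numeric(f[12]),
                chain_id = f[13])
    i <- i + 1L
    s_pos <- hdr$s_start; t_pos <- hdr$t_start
    blocks <- list()
    repeat {
      if (i > length(lines) || !nzchar(lines[i])) break
      b <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      blocks[[length(blocks) + 1L]] <-
        c(s_start = s_pos + 1, t_start = t_pos + 1, len = b[1])
      s_pos <- s_pos + b[1]; t_pos <- t_pos + b[1]
      i <- i + 1L
      if (length(b) == 1L) break
      s_pos <- s_pos + b[2]; t_pos <- t_pos + b[3]
    }
    bl <- as.data.frame(do.call(rbind, blocks))
    if (s_pos != hdr$s_end || t_pos != hdr$t_end) {
      .lm_stop("chain file %s: chain %s blocks overflow header span",
               path, hdr$chain_id)
    }
    chains[[length(chains) + 1L]] <- c(hdr, list(blocks = bl))
  }
  structure(chains, class = "chain_set")
}

#' Write a chain_set to a UCSC chain file
#'
#' @param chains a `chain_set` (see [read_chain()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    bl <- ch$blocks
    hdr <- sprintf("chain %d %s %d + %d %d %s %d + %d %d %s",
                   as.integer(ch$score), ch$s_chrom, as.integer(ch$s_size),
                   as.integer(bl$s_start[1] - 1),
                   as.integer(bl$s_start[nrow(bl)] + bl$len[nrow(bl)] - 1),
                   ch$t_chrom, as.integer(ch$t_size),
                   as.integer(bl$t_start[1] - 1),
                   as.integer(bl$t_start[nrow(bl)] + bl$len[nrow(bl)] - 1),
                   ch$chain_id)
    body <- character(nrow(bl))
    for (k in seq_len(nrow(bl))) {
      if (k < nrow(bl)) {
        dt <- bl$s_start[k + 1] - (bl$s_start[k] + bl$len[k])
        dq <- bl$t_start[k + 1] - (bl$t_start[k] + bl$len[k])
        body[k] <- sprintf("%d %d %d", as.integer(bl$len[k]),
                           as.integer(dt), as.integer(dq))
      } else body[k] <- sprintf("%d", as.integer(bl$len[k]))
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' Writes BED6 when `name`/`score` columns are available (methylation means
#' are scaled to the 0-1000 BED score range), BED3 otherwise.
#'
#' @param gr `GRanges` to write.
#' @param path output file.
#' @param name,score optional metadata column names to use.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name = NULL, score = NULL) {
  dt <- data.table(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(name) || !is.null(score)) {
    nm <- if (!is.null(name)) as.character(mcols(gr)[[name]]) else "."
    sc <- if (!is.null(score)) {
      v <- mcols(gr)[[score]]
      if (is.numeric(v) && all(v >= 0 & v <= 1, na.rm = TRUE)) round(v * 1000) else v
    } else 0
    dt[, c("name", "score", "strand") :=
         list(nm, sc, as.character(strand(gr)))]
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED3/BED6 file.
#' @param chrom_alias optional chromosome renaming map.
#' @return `GRanges` (with `name`/`score` metadata when present).
#' @export
read_bed <- function(path, chrom_alias = NULL) {
  dt <- fread(path, header = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L) return(GRanges())
  gr <- GRanges(normalize_chroms(as.character(dt[[1]]), chrom_alias),
                IRanges(as.integer(dt[[2]]) + 1L, as.integer(dt[[3]])))
  if (ncol(dt) >= 6L) {
    s <- as.character(dt[[6]]); s[!s %in% c("+", "-")] <- "*"
    strand(gr) <- s
  }
  if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) mcols(gr)$score <- dt[[5]]
  sort(sortSeqlevels(gr), ignore.strand = TRUE)
}

#' Write a data frame as a TSV result table
#'
#' @param x data.frame / data.table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a MethTable as a CpG report
#'
#' Inverse of [read_cpg_report()]; emits 0-based bedGraph-style columns
#' chrom, start, end, methylated count, unmethylated count.
#'
#' @param meth a `MethTable`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cpg_report <- function(meth, path) {
  dt <- data.table(chrom = as.character(seqnames(meth)),
                   start = start(meth) - 1L, end = end(meth),
                   meth = mcols(meth)$meth,
                   unmeth = mcols(meth)$total - mcols(meth)$meth)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
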