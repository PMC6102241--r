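## Internal helpers shared across modules.

.lm_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_fraction <- function(x, name = deparse(substitute(x))) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    .lm_stop("%s must lie in [0, 1]; got %s", name,
             format(x[bad][1], digits = 6))
  }
  invisible(x)
}

.check_nonneg <- function(x, name = deparse(substitute(x))) {
  bad <- !is.na(x) & x < 0
  if (any(bad)) .lm_stop("%s must be non-negative", name)
  invisible(x)
}

#' Normalize chromosome names through an alias map
#'
#' Inputs from different providers disagree on chromosome naming
#' ("chr1" vs "1"). All readers funnel names through this map; downstream
#' joins between inputs with disjoint chromosome sets raise an error rather
#' than silently returning empty overlaps.
#'
#' @param x character vector of chromosome names.
#' @param alias named character vector mapping input names to canonical
#'   names, or `NULL` for no renaming.
#' @return character vector of canonical names.
#' @export
normalize_chroms <- function(x, alias = NULL) {
  x <- as.character(x)
  if (is.null(alias)) return(x)
  hit <- x %in% names(alias)
  x[hit] <- unname(alias[x[hit]])
  x
}

## Error, not an empty join, when two inputs share no chromosome names.
.check_shared_chroms <- function(a, b, what = "inputs") {
  ca <- as.character(unique(seqnames(a)))
  cb <- as.character(unique(seqnames(b)))
  if (length(ca) && length(cb) && !length(intersect(ca, cb))) {
    .lm_stop(
      "no shared chromosome names between %s (%s vs %s); check naming/alias map",
      what, paste(head(ca, 3), collapse = ","), paste(head(cb, 3), collapse = ","))
  }
  invisible(TRUE)
}

## Deterministic derived seeds for simulation stages (kept below 2^31).
.stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage
}

## Per-CpG fractional methylation of a MethTable.
.meth_frac <- function(meth) {
  f <- mcols(meth)$meth / mcols(meth)$total
  f[mcols(meth)$total == 0L] <- NA_real_
  f
}
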