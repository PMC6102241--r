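## Post-fertilization fate of oocyte-methylated CGIs. Two named rule
## presets encode two maternal-origin inferences: "pg" reads maternal-only
## material (parthenogenetic blastocysts / maternal-allele ICM) directly;
## "biparental" infers maternal origin in biparental tissue from a
## hypomethylated sperm track.

#' Classify post-fertilization persistence of oocyte methylation
#'
#' Requires oocyte methylation above `t_oo` (CGIs below it are
#' "not_oocyte_methylated"; missing oocyte values are "unclassifiable").
#'
#' * mode `"pg"` — **retained** iff PG-blastocyst (or maternal-allele)
#'   methylation is strictly above `t_retain` (default 0.45); otherwise
#'   **erased**.
#' * mode `"biparental"` — **maternal_dmr_candidate** iff sperm methylation
#'   is strictly below `t_sperm` (default 0.01) *and* biparental
#'   blastocyst/placenta methylation strictly above `t_blast` (default
#'   0.30); otherwise **erased**.
#'
#' When wild-type and TET-null epiblast profiles are both supplied, a
#' `tet_sensitive` annotation is set where the TET-null value exceeds the
#' wild type by more than `tet_margin`.
#'
#' @param oocyte,blast,sperm per-CGI methylation fractions; `blast` is the
#'   PG blastocyst (pg mode) or biparental blastocyst/placenta
#'   (biparental mode) track.
#' @param mode `"pg"` or `"biparental"`.
#' @param t_oo,t_retain,t_sperm,t_blast thresholds (defaults 0.70, 0.45,
#'   0.01, 0.30).
#' @param epiblast_wt,epiblast_tetko optional epiblast profiles for the
#'   TET-sensitivity annotation.
#' @param tet_margin TET-null minus wild-type excess (default 0.2).
#' @return data.frame with `fate` and logical `tet_sensitive` (`NA` when
#'   no epiblast profiles were supplied).
#' @export
classify_persistence <- function(oocyte, blast, sperm = NULL,
                                 mode = c("pg", "biparental"),
                                 t_oo = 0.70, t_retain = 0.45,
                                 t_sperm = 0.01, t_blast = 0.30,
                                 epiblast_wt = NULL, epiblast_tetko = NULL,
                                 tet_margin = 0.2) {
  mode <- match.arg(mode)
  n <- length(oocyte)
  fate <- rep(NA_character_, n)
  fate[is.na(oocyte)] <- "unclassifiable"
  meok <- !is.na(oocyte) & oocyte > t_oo
  fate[!is.na(oocyte) & !meok] <- "not_oocyte_methylated"
  if (mode == "pg") {
    fate[meok & !is.na(blast) & blast > t_retain] <- "retained"
    fate[meok & !is.na(blast) & blast <= t_retain] <- "erased"
    fate[meok & is.na(blast)] <- "unclassifiable"
  } else {
    if (is.null(sperm)) .lm_stop("biparental mode requires a sperm track")
    dmr <- meok & !is.na(sperm) & !is.na(blast) &
      sperm < t_sperm & blast > t_blast
    fate[meok & !is.na(sperm) & !is.na(blast)] <- "erased"
    fate[dmr] <- "maternal_dmr_candidate"
    fate[meok & (is.na(sperm) | is.na(blast))] <- "unclassifiable"
  }
  tet <- rep(NA, n)
  if (!is.null(epiblast_wt) && !is.null(epiblast_tetko)) {
    tet <- !is.na(epiblast_wt) & !is.na(epiblast_tetko) &
      (epiblast_tetko - epiblast_wt) > tet_margin
  }
  data.frame(fate = fate, tet_sensitive = tet)
}

#' Cross-tabulate persistence fate by LIT embedding and privacy
#'
#' @param fates character vector of fates from [classify_persistence()].
#' @param lit_embedded logical: is the CGI embedded within a called LIT.
#' @param privacy optional character ("shared" / "private" labels) for
#'   LIT-embedded CGIs; non-embedded CGIs are tabulated as "non-LIT".
#' @return a `table` (fate x category) whose total equals the number of
#'   calls.
#' @export
persistence_by_lit <- function(fates, lit_embedded, privacy = NULL) {
  stopifnot(length(fates) == length(lit_embedded))
  cat <- ifelse(lit_embedded,
                if (is.null(privacy)) "LIT" else paste0("LIT-", privacy),
                "non-LIT")
  cat[is.na(cat)] <- "non-LIT"
  table(fate = fates, category = cat, useNA = "no")
}
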