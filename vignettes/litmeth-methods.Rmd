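---
title: "Methods: LTR-initiated transcription and the oocyte methylome"
author: "litmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LTR-initiated transcription and the oocyte methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

De novo DNA methylation (DNAme) in growing oocytes is deposited over
transcribed territory: gene bodies accumulate H3K36me3 co-transcriptionally,
and that mark guides the de novo methyltransferase machinery. A sizable
fraction of oocyte transcripts, however, do not start at canonical gene
promoters but inside long terminal repeats (LTRs) of endogenous
retroviruses. Because LTR insertions are young and lineage-specific —
thousands of elements present in one rodent are absent from the orthologous
position in another, and the rodent MT family of MaLR elements has no
primate counterpart — LTR-initiated transcription units (LITs) are a
mechanism by which the *same* methylation machinery produces *different*
methylomes in different species, strains, and ultimately alleles. When such
a unit runs across a CpG island (CGI) promoter, the island can be
methylated in the oocyte and, at a subset of loci, that maternal methylation
survives post-fertilization reprogramming.

`litmeth` implements the comparative pipeline needed to test and quantify
this mechanism end-to-end: methylome segmentation, LIT calling from
assembled transcripts, cross-species projection through chain alignments,
CGI methylation attribution, persistence classification — plus a synthetic
multi-species cohort generator with a complete ground-truth ledger, so
every stage can be validated by recovery rather than by eye.

# Methylome landscape

**Bin scores.** `score_bins()` averages per-CpG fractional methylation
(unweighted across CpGs) in fixed-width bins, with the coverage rule of at
least `min_cpgs` CpGs each covered by at least `min_depth` reads. The
published phrasing of these filters (">4 CpGs with >5x") is ambiguous by
one unit; we read it as >=5 CpGs at >=5 reads and expose both knobs
(`min_cpgs = 4, min_depth = 1` reproduces the low-resolution rule used for
sparse strain libraries). Bins failing the rule are flagged and excluded
from every downstream denominator — a mean of 0 and "no data" are
deliberately distinct throughout the package.

**Segmentation.** `segment_domains()` partitions the ordered series of
passing bins per chromosome into segments of constant mean by exact
penalized least squares, solved with PELT-style pruning
(`pelt_changepoints()`). The solver is exact: the test suite checks it
against an unpruned O(n^2) dynamic program on hundreds of instances. The
default penalty is MBIC-like, `2 log(n) sigma^2`, with `sigma` estimated
robustly from the median absolute deviation of first differences —
published applications of changepoint segmentation to methylomes name the
method but not its penalty, so the default is stated here and recorded in
the run manifest. Non-passing bins are bridged: the observation series
skips them but domain spans retain the genomic gaps. Segments are labeled
hypo (<30%), intermediate, or hyper (>70%); all class cutoffs in the
package are strict inequalities, and behavior *at* each boundary is pinned
by tests.

# LIT calling

`classify_transcript_start()` reimplements the Up / UpEdge / EInside
5'-overlap categories operationally, because the upstream tool that coined
them does not print its exact thresholds:

* **Up** — the strand-aware TSS lies inside an LTR-class repeat and exon 1
  extends 3' beyond the repeat;
* **UpEdge** — the TSS lies outside the repeat but within a boundary
  window (default 100 bp, configurable);
* **EInside** — the repeat is contained in a non-first exon (or in exon 1
  without containing the TSS); kept out of the high-specificity call set,
  as in the published filter that accepts only Up and UpEdge.

ERV-internal RepeatMasker entries share the LTR classes and count as
initiating elements. `call_lits()` then labels gene relationships:
sense-chimeric requires a non-first exon sharing >=1 bp with a same-strand
annotated exon *and* an isoform share strictly above 10% of the gene's
summed isoform FPKM; antisense is any opposite-strand gene overlap;
everything else is intergenic. The LTR contribution ratio uses mean
per-base exon coverage (mean, not total, for length independence) with
`ratio/(1 + ratio)` normalization and explicit flags for zero-coverage
denominators. `active_ltr_scan()` complements assembly-based calling with
the strict >1 FPKM census of transcribed repeats, and
`rescue_lits_by_domain()` implements the secondary evidence tier — 5' ends
at hypermethylated-domain boundaries over an LTR — kept disjoint from
primary calls.

# Synteny

`liftover()` projects intervals through UCSC chain files base-wise and
returns the minimal covering target interval, with two guardrails: a
minimum mapped fraction (default 0.5) and rejection of projections that
straddle target chromosomes. Its contract is defined by a brute-force
per-base oracle, and the acceptance suite holds the two equal across a
thousand random intervals on chains containing insertions.

`reciprocal_best_bins()` pairs fixed-width bins by mutual best overlap
after projection, anchored on a hub species (mouse-centered chain sets are
the published practice; the hub is configurable). `cgi_identity()` scores
syntenic CGI candidates; "identity" is not formally defined in the source
analyses, so the default is the Jaccard index of the projected island
against the partner island (symmetric, bounded, and meaningful at the 0.5
cutoff), with overlap-of-smaller and reciprocal-overlap variants available
and the choice recorded in output. Identity strictly above 0.5 is
syntenic.

CGI context uses the published windows: promoter = TSS +/- 500 bp (the
stricter +/-100 bp rule is a parameter), intragenic = inside a gene body
and >500 bp from every TSS, genic = overlap with TSS..TTS + 2 kb. The
300-500 bp band between the promoter and intragenic rules belongs to
neither; it is labeled `proximal` rather than silently merged.

# Comparative classifications

`venn_partition()` tabulates presence/absence of hypermethylation
(>70%, strict) across species over coverage-complete syntenic units,
conserving totals (categories + hypo-everywhere + excluded = input).
`attribute_domains()` classifies hypermethylated domains by any-overlap
with LIT spans and genes and reports bp-weighted territory fractions
("normalized to the domain size"). LIT stratification of Venn units counts
overlap with a called LIT in *any* species; the alternative
(overlap required in the hypermethylated species) is a documented open
reading, and any-species is the default. The cross-species expression
contrast is exactly the printed statistic
`z = (FPKM_A - FPKM_B) / (sqrt(FPKM_A + FPKM_B) + 0.01)`.

Strain-differential calling requires Delta DNAme strictly above 40%
together with an H3K36me3 difference that is sign-concordant and exceeds
the 75th percentile of the genome-wide |Delta| distribution — the
enrichment threshold is not printed in the source analyses, so
sign-concordance plus a quantile magnitude filter is this package's
explicit design choice, reported in output headers.

# Persistence

Two rule presets encode two different maternal-origin inferences and are
deliberately not merged. `"pg"` mode reads maternal-only material
(parthenogenetic blastocysts, maternal-allele ICM): oocyte methylation
>70% and blastocyst methylation strictly >45% is `retained`.
`"biparental"` mode infers maternal origin in biparental tissue: sperm
<1% and blastocyst/placenta >30% yields `maternal_dmr_candidate`. A
TET-sensitivity annotation is computed only when wild-type and TET-null
epiblast profiles are both supplied (otherwise left blank, since the
published flag derives from an external knockout dataset).

# The synthetic cohort generator

The generator defines the study conditions; it is not a tuning surface.
Species genomes are *coordinate-only* — every downstream stage consumes
intervals and counts, so no nucleotide sequence is simulated — and are
derived from one ancestral frame by insertion-only LTR indels along a
((species1, species2), species3) topology, which makes every pairwise
chain exact by construction (chain correctness is itself tested by lifting
ancestral features and comparing against the generator's bookkeeping).
Key defaults and their grounds:

* Beta methylation model with modes 0.85 / 0.05 and concentration 30 —
  reproduces the bimodal oocyte methylome; bimodality is asserted by a
  kernel-density test.
* Negative-binomial CpG depth, mean 15, dispersion 8 — WGBS-like
  overdispersed coverage.
* 15% of hypermethylated territory is planted as "orphan" domains
  overlapping neither genes nor LITs in any species, mirroring the
  reported 15-18% of unexplained hypermethylated domains; recovery of this
  fraction by `attribute_domains()` is a standing test.
* Sperm is near-uniformly high (0.92) with CGIs <1%; maternal blastocyst
  methylation keeps a per-meCGI retention draw at probability 0.4
  (retained islands at 0.70, erased at 0.08) and non-CGI attenuation 0.45;
  the biparental blastocyst averages maternal and sperm levels; wild-type
  epiblast erases TET-sensitive islands while the TET-null profile keeps
  them.
* A CGI is methylated in the generator's truth exactly when it lies wholly
  inside a transcribed unit whose TSS falls outside the island — canonical
  promoters of active genes therefore stay unmethylated while islands
  swept by an upstream-initiating LIT gain methylation, the mechanism
  under study.
* Transcript geometry (TSS placement inside the LTR, chimeric splicing
  dice, span, expression) is drawn once per element, so an element shared
  by two species emits concordant units in both; activity is drawn per
  species unless `shared_activity` is set. This is what makes the
  all-shared control cohort genuinely exchangeable between the
  LIT-overlapping and non-LIT strata.
* The H3K36me3 track gains coverage over transcribed units *excluding
  their first kilobase*: the mark is deposited co-transcriptionally and
  accumulates downstream of the TSS. This matters for strain comparisons
  at promoter CGIs, where the competing state is canonical initiation at
  the island itself.
* Hypermethylation is truncated at transcript boundaries (no 3' spreading
  taper by default): no quantitative spreading model is available to
  emulate, so the taper defaults to zero.
* Strain mode models polymorphic LTRs as presence/absence flags on a
  shared coordinate frame — the reads-mapped-to-reference view of strain
  data — while species mode exercises the full indel/chain machinery.

What the generator does *not* emulate: sequence-level divergence,
read-level errors and mapping bias, partial bisulfite conversion,
transcript-assembly fragmentation, inverted or duplicated chain blocks,
and H3K4me3. Passing recovery tests on these cohorts therefore
demonstrates the correctness of the pipeline's logic under its stated
model, not robustness to the full noise structure of real libraries.

# Problem sizes and determinism

Validation runs use desk-scale cohorts chosen to exercise every code path:
the default three-species cohort spans 2 Mb over 2 chromosomes with 60
genes and ~70 LTR elements (~15,000 CpGs per species per tissue); the LIT
recovery cohort plants 120 LITs among 1,000 transcripts on a 19 Mb
genome; stratum comparisons aggregate 20 seeded 1 Mb cohorts per
scenario. All simulation stages draw from seeds derived deterministically
from the cohort seed, and the demo (`litmeth_demo()`) writes the cohort to
disk, reads it back through the package's own parsers, analyzes it and
writes plain-text results that are byte-identical across reruns with the
same seed.

# Known limitations

* Only colinear (plus-strand) chains are supported; inversions and
  duplications are rejected at parse time.
* Three-species synteny is hub-anchored; a unit syntenic between the two
  non-hub species but unmappable in the hub is not recovered.
* The contribution ratio needs per-exon coverage input; when only FPKM is
  available the isoform share is reported alone.
* `partial` meCGI labels (hyper in two of three species) are reported but
  not further subdivided.
* FPKM is consumed, never computed, from expression inputs; quantitation
  pipelines are out of scope.
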