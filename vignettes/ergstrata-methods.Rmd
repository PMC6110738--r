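---
title: "Stratified multi-omics comparison of fusion-defined prostate cancer subtypes"
author: "ergstrata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified multi-omics comparison of fusion-defined prostate cancer subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergstrata)
```

## Scope and model

The *TMPRSS2:ERG* gene fusion places the ERG transcription factor under an
androgen-responsive promoter and defines the dominant molecular subtype of
prostate cancer in men of European ancestry; its frequency is markedly lower
in men of African and Asian ancestry, so the fusion-**negative** tumors are
the relevant reference class for those populations. `ergstrata` implements
the complete comparative workflow around that stratification:

1. **Group assignment.** A sample is ERG-positive when an ERG 3'-fusion is
   reported by *either* of two evidence sources (e.g. a consortium call set
   and a fusion database). Samples supported by only one source are flagged
   and can be checked by expression: a Welch *t*-test of the target gene's
   log2-CPM against confirmed negatives (z-score fallback for a single
   sample, since a two-sample *t* needs two observations per side).
2. **Clinical association.** One 2×2 test per clinical category (category
   vs. all other samples, per group). Samples with unknown values stay in
   the complement, so the denominators are always the full group sizes —
   this convention is what reproduces the published reference statistics.
3. **Alteration frequency comparison** for fusions (Fisher, recurrence ≥ 3
   samples), nonsilent mutations, binned copy number, tumor
   suppressor/oncogene classification, a representative-gene signature with
   sample coverage, differential expression and promoter hypermethylation,
   and pathway-level burden.

## The 2×2 test chooser

Every frequency contrast runs through one kernel, `assocTest()`. The test
is chosen from the *theoretical* (expected) cell counts of the 2×2 table:
if any expected count falls below `expected_count_min` (default 5), a
two-sided Fisher exact test is used — defined as the sum of hypergeometric
probabilities of tables no more probable than the observed one, with a
1e-7 relative slack against floating-point ties — otherwise a Yates
continuity-corrected chi-squared with 1 df whose correction term clamps at
zero. Both branches are implemented in the package because the exact
tie-handling convention is part of the contract; unit tests cross-check
them against `fisher.test()`/`chisq.test()` and against a brute-force
enumeration oracle on every table with total ≤ 40.

The chooser cutoff of 5 is validated by the reference clinical table
(`table1Cohort()`, reconstructed from published marginal counts): the one
sparse stage category (10 carriers) lands in the Fisher branch and
reproduces the published p = 0.747, while all dense rows reproduce the
published Yates chi-squared values to three significant figures.

```{r table1}
tab <- clinicalTable(table1Cohort())
tab[tab$variable == "stage", c("category", "n_pos", "n_neg", "test_used", "p")]
```

## Copy-number binning

Segments arrive in the SEG dialect (1-based inclusive) and are converted
to 0-based half-open internally, so lengths are simple differences. The
value column is auto-detected per file: if every sample's values lie
exactly in {-2, -1, 0, 1, 2} they are discrete calls (amp ≥ 1, del ≤ -1);
otherwise they are log2 ratios thresholded at ±0.3 (the GISTIC
convention; the cutoffs are configurable). A file mixing the two dialects
across samples is rejected.

The genome is divided into consecutive 10 kb bins; each (bin, sample) is
assigned the status carried by the strict majority of its bases — a status
wins only when it covers **more than** 5 kb, so a 5 kb/5 kb tie is
neutral, and uncovered bases count as neutral. A chromosome whose length
is not a multiple of the bin width ends in a short bin that can only be
neutral under the strict rule; the toy genomes used throughout are
bin-aligned. The implementation (interval overlap arithmetic on
`GRanges`) is property-tested against a literal per-base counting oracle
on random 1 Mb layouts.

Cytoband and arm frequencies are medians over member-bin frequencies. For
the group comparison a per-sample rule is needed that the frequency
definition alone does not give: a sample counts as altered in a region
when more than half of the region's bins carry the status — chosen for
symmetry with the per-bin majority rule, and configurable
(`region_sample_frac`). A region is flagged when the chooser test gives
p < 0.01 **and** the larger group frequency exceeds 30%.

## Gene-level calls and the signature

A gene is amp/del when a discretized segment of that status overlaps at
least half of the gene body (`gene_overlap_frac`); mutations count only
when nonsilent; fusions credit both partners. Tumor suppressors are
scored by deletion and oncogenes by amplification; genes above 20% in
both groups are *common*, and genes with chooser p < 0.001 and an
absolute difference above 10 points are *group-specific* (specific wins
when both rules fire).

Signature selection for the ERG-negative group takes candidates above the
recurrence floors (SCNA > 15%, mutation > 10% in the negative group),
flags priority (higher-in-negative at p < 0.05, druggability from a
user-supplied list, positive copy/expression correlation at p < 0.05),
clusters the candidates' binary alteration vectors by average-linkage on
the 1 − *r* distance, and cuts the tree at correlation 0.5. Neither the
linkage nor the cut height is dictated by the statistical model — average
linkage with a 0.5 correlation cut is a standard default, both are
configurable, and the behavior that matters (one representative per
planted redundancy cluster, coverage within 5 points of the planted
union) is what the test suite checks. Within a cluster the representative
is chosen by priority-flag count, then negative-group frequency, then
symbol — all tie-breaks total, so the output is deterministic. Coverage
is the fraction of samples carrying at least one alteration among the
representatives; a frozen representative list can be applied to a second
cohort's matrix for cross-cohort coverage.

## Expression and methylation

Counts are normalized to log2-CPM (rank-preserving per sample).
Differential expression is a per-gene Welch *t* on log2-CPM with the
linear fold-change of group mean CPMs; a gene is called at p < 0.05 and
|FC| > 2. This is a deliberately transparent stand-in for published
count-model pipelines: the contract tested here is planted-signal
recovery (fold-4 genes recovered with power ≥ 0.9, type-I near nominal),
not coefficient equality with any particular package. Group overlap of DE
calls is direction-aware — a gene up in one contrast and down in the
other is not "common".

The promoter hypermethylation cascade applies five nested filters in
order, recording survivors at each stage: (1) drop X/Y/mitochondrial
probes and probes with > 20% missing betas; (2) keep |Δβ| > 0.2 with
Welch p < 0.01; (3) keep promoter classes (TSS200, TSS1500, 5'UTR,
1stExon); (4) keep probes whose beta correlates negatively with their
gene's expression (p < 0.05 — no threshold is dictated for "negatively
correlated", so r < 0 at the conventional level, configurable); (5) keep
probes whose gene is expressed significantly lower in tumors (one-sided,
p < 0.05, again a documented choice). The nesting invariant is asserted
on every run. The between-group variant replaces the stage-2 contrast
with the signed tumor-group contrast, once per direction, keeping stages
4–5 against tumor expression; sites and distinct genes are reported per
direction.

## The synthetic cohort generator

`simConfig()`/`simulateCohort()` generate every input layer under one
seed. Defaults are the study conditions the pipeline targets: two tumor
groups of about 200 and 300 samples plus ~50 normals; per-gene event
frequencies in the 4–35% range with the subtype-defining fusion planted
in every positive sample (5' partner 94.1% TMPRSS2, otherwise SLC45A3,
dual-source evidence at 85% per source); clinical category proportions
mirroring the published cohort; exponential recurrence times (baseline
hazard 0.004/month, censoring at 120 months, hazard ratio 1 between
groups by default — matching the published null survival contrast).
Copy-number events are whole-gene segments at log2 ±0.8 with a 50 kb
flank over a neutral background on a miniature bin-aligned genome (4 × 3
Mb). Expression is negative-binomial (dispersion 0.1) with a log2 shift
per copy gain/loss (default 1) and fold-change effects for planted DE
genes; only genes that need coordinates are placed on the toy genome,
while a 200-gene expression background keeps CPM normalization stable
against compositional distortion. Methylation betas are
beta-distributed (baseline mean 0.2, hypermethylated 0.7, concentration
10); cis-flagged probes are coupled to expression on the logit scale to
a target correlation of about −0.6.

What the generator does **not** emulate: real segment-length and LD
structure, marginal TCGA distributions, batch effects, subclonality, or
purity. Passing recovery tests therefore demonstrates the pipeline's
statistical behavior under its own assumptions, not performance on real
cohorts; real TCGA-format exports are accepted unchanged by the readers
for users who obtain them.

## Numerical conventions and edge cases

* Coordinates are 0-based half-open everywhere in memory; SEG (1-based
  inclusive) and BED (half-open) convert on read/write and round-trip
  exactly.
* Degenerate 2×2 tables (an empty margin) raise an error; the clinical
  table surfaces that per row rather than aborting.
* Welch with both groups constant returns p = 1 at equal means and p = 0
  otherwise; constant vectors are an error for Pearson correlation.
* Candidates altered in no (or every) negative sample cannot be
  correlated and are excluded from clustering with a warning.
* All reported frequencies are count/group-size and the written tables
  reproduce them exactly on re-read.

## Problem sizes used in the checks

The packaged suites run at deliberately small scale chosen to make the
checks exact or tight: exhaustive Fisher enumeration on all 2×2 tables
with total ≤ 40; 100 random 1 Mb layouts against the per-base binning
oracle; 1,000 random matrices against the coverage oracle; a constructed
105-probe cascade fixture (5 pass-all probes, 100 single-failure decoys);
and 100-seed recovery studies at 200/300 samples with planted frequency
differences of 0.25, fold-4 expression effects and a 70% shared-DE
structure.
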