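---
title: "Calling and analysing clonal hematopoiesis burden: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analysing clonal hematopoiesis burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CHIPburden)
```

## What this package models

Clonal hematopoiesis of indeterminate potential (CHIP) is the presence of
somatic blood clones at a variant allele frequency (VAF) of at least 2% in
people without hematologic disease. Detecting CHIP from bulk blood
sequencing is mostly a filtering problem: after somatic calling and
annotation, the evidence for each candidate variant — read depths, strand
support, population frequency, local sequence context — has to be weighed
against the characteristic failure modes of high-depth panel data
(sequencing artifacts near homopolymers, germline leakage, recurrent panel
noise). CHIPburden implements that filtering layer, the burden and
prevalence statistics built on top of it, an exclusive-detection power
model for variant-level group comparisons, and the Wilcoxon-AUC preranked
gene set enrichment stage used to connect CHIP burden to single-cell
transcriptomes. A synthetic-data generator stands in for patient data,
which are typically not shareable.

## The filter cascade

`applyFilterCascade()` evaluates seven criteria for every candidate
variant, without short-circuiting, so a rejected record always shows the
full set of reasons:

| criterion | rule (panel / WES defaults) |
|---|---|
| `vaf_range` | `0.02 <= VAF <= 0.35`, endpoints inclusive |
| `depth` | site depth strictly `> 500x` / `> 40x` |
| `strand_pairs` | `>= 4` / `>= 2` alt-supporting read pairs in *each* direction |
| `population` | gnomAD AF strictly `< 1e-5`, or `< 1e-3` if in COSMIC |
| `cohort_recurrence` | identical variant in strictly `< 5%` of processed samples |
| `homopolymer` | no run of `>= 4` identical bases within 6 bp either side |
| `protein_altering` | consequence alters the protein (incl. exonic splice) |

VAF is `alt_depth / total_depth`. The window endpoints are inclusive
because the calling range is stated inclusively ("2–35%"), while the
depth, population and recurrence bounds are written as strict
inequalities and are implemented that way; boundary behaviour is pinned by
unit tests (a VAF of exactly 0.02 passes, a depth of exactly 500 fails).

Three rules deserve comment because the underlying convention is not
universal:

* **"Variant depth" means total site depth.** At a panel median of ~600x,
  an *alt-read* depth above 500 would be unreachable for clones at VAF
  <= 0.35, so the `depth` criterion tests total coverage at the site.
* **The recurrence filter is a panel-of-normals-like rule.** The same
  chrom:pos:ref:alt call recurring across unrelated samples at low VAF is
  characteristic of artifacts or germline leakage, so a variant carried by
  >= 5% of all processed samples is rejected. The denominator is the whole
  processed run — the cascade therefore needs all samples of a run
  together (`nSamples` can be supplied when some samples produced no
  candidates).
* **The homopolymer run length is a choice.** The filter definition says
  only that a homopolymer signature within 6 bp disqualifies a call; it
  does not pin the run length. We use the conventional indel-artifact
  threshold of 4 identical bases (`homopolymerMinRun`), configurable
  because reasonable pipelines differ here. `N` bases never extend a run.

Classification of passing calls (`classifyChip()`) follows a driver
catalog: a call is CHIP-PD ("with putative drivers") when a matching
catalog entry has been reported strictly more than 10 times or belongs to
a predefined hotspot list; otherwise it is plain CHIP. The shipped catalog
(`inst/extdata/chip_drivers.tsv`) is a synthetic seed list of canonical
CHIP drivers and hotspots (DNMT3A p.Arg882, JAK2 p.Val617Phe, SRSF2
p.Pro95, ...), intended to be edited or replaced — curated driver lists
are institution-specific.

Manual IGV review cannot be automated; all passing calls carry
`needs_review = TRUE` as its stand-in. Duplicate (sample, variant) records
collapse to the highest-alt-depth record before filtering, with a logged
count.

## Burden and prevalence statistics

`classifyBurden()` stratifies samples into `negative` (no passing call),
`high_burden` (largest clone VAF strictly > 10%) and `chip` (everything
else). The 10% boundary is strict; the categories partition the cohort by
construction.

For categorical comparisons, `exact2x2Test()` implements the conditional
exact test on a 2x2 table: condition on both margins, enumerate the
hypergeometric support, and sum the probabilities of all tables no more
likely than the observed one (the minimum-likelihood two-sided rule). The
method tag is recorded in every result because "exact 2x2 test" is an
ambiguous label in the literature; this construction matches the classical
conditional test, and our tests verify it against full enumeration and
against the reference implementation in `stats`.

`ageAdjustedLogistic()` fits outcome ~ group + age by plain
maximum-likelihood IRLS — convergence when the largest coefficient change
drops below 1e-8, at most 100 iterations — rather than a penalised fit.
At cohort sizes of tens to low hundreds, quasi-complete separation is a
real possibility, and we prefer a transparent flag (`separation = TRUE`,
raised on non-convergence, diverging coefficients, or fitted probabilities
pinned to the outcomes) over a silently shrunk estimate. Null calibration
(type-I error at the nominal 5%) and parameter recovery are part of the
test suite.

`bhAdjust()` is the Benjamini–Hochberg step-up, applied across all
comparisons of one run and reported alongside raw p-values. Pre/post
treatment comparisons (`vafConcordance()`) inner-join calls on the variant
key; variants present at one timepoint only are reported as gained/lost
and never imputed with pseudo-VAFs, and correlations are undefined (NA)
below 3 matched pairs.

## The exclusive-detection power model

For a specific variant that constitutes a fraction `p` of gene-level CHIP
carriers, the probability of observing it at least once among `n` carriers
is `1 - (1 - p)^n` (`detectionPower()`, evaluated via `log1p` so small `p`
does not lose precision). This is the *conditional* form — the variant is
assumed absent in the comparison group — and it is the form behind the
headline numbers: at `p = 0.10` (the DNMT3A p.Arg882 share of DNMT3A
CHIP), `minGroupSize(0.10, 0.8)` returns 16, since `1 - 0.9^15 = 0.794 <
0.8 <= 1 - 0.9^16 = 0.815`. With a gene-level prevalence of 8 carriers
per 50 CHIP-positive samples, `requiredCohortSize(16, numerator = 8,
denominator = 50)` gives 100 CHIP samples per group; the count form uses
exact integer arithmetic because a floating `ceil(16 / 0.16)` is exactly
the kind of expression that lands off by one.

The general engine is exact: `poissonBinomialPmf()` convolves
heterogeneous per-sample carriage probabilities by dynamic programming (no
normal or Poisson approximation — the n involved are small), and
`exclusiveDetectionProb()` gives the unconditional two-group form
`P(>=1 in A) P(0 in B) + P(0 in A) P(>=1 in B)`. Both are tested against
exhaustive enumeration.

## AUC ranking and preranked GSEA

Within one cell cluster, `rankGenes()` scores every gene by the Wilcoxon
rank-sum AUC of one burden group versus another: `u / (n1 * n2)` with
midranks for ties, i.e. the probability that a random cell of group A
exceeds a random cell of group B, ties counting one half. Genes detected
in under 5% of cells in both groups are dropped (configurable). The
ranking metric is the *centred* AUC, `auc - 0.5`: the AUC itself lives on
[0, 1] and carries no sign, and centring gives the antisymmetry (group
swap flips every score) that two-sided enrichment needs. Cells are
compared individually (one cell, one observation), not pseudobulked; with
hundreds of cells per group the rank-sum p-values are anti-conservative
under within-sample correlation, which is why downstream inference rests
on the permutation test, not on the per-gene p-values.

`gseaEs()` is the classical weighted Kolmogorov–Smirnov statistic on the
ranked list: in-set genes add `|score|^w / sum(|score|^w)` (weight `w = 1`
by default), out-of-set genes subtract `1/(N - K)`; the enrichment score
is the extremum of the larger excursion and the leading edge collects the
in-set genes up to (positive ES) or after (negative ES) that extremum. If
every in-set score is zero the weights degenerate to equal steps. The
implementation is verified against a hand-computed running sum and against
the reference preranked statistic in `fgsea`.

`gseaPermutation()` builds the null by drawing random gene positions of
the same set size from the ranking — the preranked-GSEA convention; with a
single ranked list as input there is no sample-level structure left to
permute. NES divides the observed ES by the mean |ES| of same-sign nulls,
and `p = (1 + b) / (1 + m)` counts the `b` same-sign nulls at least as
extreme among `m`. Nulls are drawn fresh for every gene set, so p-values
are independent across sets; BH adjustment is applied across all sets of
the call. Everything is reproducible from the seed argument. When no null
of matching sign occurs, the p-value is floored at `1/(1 + nPerm)` and
flagged rather than reported as zero.

## The synthetic-data generator

`simulateCohort()` emulates the structure the analysis assumes, not raw
sequencing: ages N(64, 8) (echoing a metastatic NSCLC cohort's mean age);
CHIP carriage logistic in age with slope 0.08/yr and intercept -5.36,
chosen once so that prevalence at the mean age is ~44%, in line with
reported NSCLC cohorts; clone genes drawn from a DNMT3A/TET2/PPM1D-
dominated frequency table; 10% of DNMT3A clones placed at the p.Arg882His
hotspot; clone counts `1 + Poisson(0.4)` truncated at 4; true VAFs
log-normal truncated to the calling window; site depths negative binomial
(panel mean 600x, WES 80x; `depthSize = Inf` gives constant depth); alt
reads Binomial(depth, VAF) with a symmetric Binomial(alt, 0.5) strand
split. Sequencing error and mapping bias are deliberately absent — the
recovery tests need controlled signatures, and an error channel would blur
which criterion a planted artifact exercises.

Four artifact classes are planted by default, each with a margin that
makes its targeted criterion essentially certain to trip: a homopolymer
run of 5 placed inside the examined window; gnomAD frequency at 1e-4
(10x the threshold) without COSMIC membership; one fixed variant planted
in 8% of samples (recurrence bound is 5%); and germline leakage at true
VAF ~ 0.5 (the VAF ceiling rejects it at 600x with overwhelming
probability). A fifth class with a Binomial(alt, 0.95) strand split is
available but has default rate 0: at typical alt depths a 0.95 split
leaves a non-negligible chance of >= 4 reads on the minor strand, so it
cannot guarantee per-instance rejection and is meant for sensitivity
experiments rather than the recovery harness. Every emitted record has
exactly one ground-truth row, and the generator is a pure function of its
config (which carries the seed); determinism is asserted byte-for-byte on
the written VCFs.

The recovery harness used by the tests and the acceptance script plants
clones at VAF 3–30% at constant 600x depth in 300 samples. Under those
conditions the cascade's sensitivity for true clones exceeds 0.95 (losses
come from binomial VAF drift below the 2% floor and strand-split
fluctuations at the lowest VAFs) and every planted artifact is rejected
with its targeted flag set. With VAFs planted down to the 2% boundary
sensitivity necessarily drops — a clone sitting on the calling threshold
is detected only half the time — which is a property of thresholded
calling, not of the implementation.

`simulateExpression()` produces a negative-binomial cell-by-gene matrix
(three clusters, two burden groups, samples nested in groups) with the
planted gene set multiplied by a configurable effect in the high-burden
cells of one target, myeloid-like cluster only. It emulates what the
enrichment stage consumes — library-scale counts with a localised group
effect — and none of the things the upstream single-cell pipeline deals
with (ambient RNA, doublets, integration, clustering). Passing tests
therefore show that the ranking and permutation machinery recovers a
planted signal at realistic cell numbers; they say nothing about
normalisation or clustering quality on real data.

## Problem sizes and numerical choices

The test and acceptance workloads were sized to be decisive yet quick: the
recovery harness uses 300 samples (roughly 600 true clones and 550
artifacts); logistic null calibration uses 1000 replicates at n = 150;
GSEA null calibration uses 500 random sets at 200 permutations and the
planted-pathway check 1000 permutations against 10 decoy sets; the
Poisson-binomial engine is checked against full 2^n enumeration up to
n = 12. Exact-arithmetic claims are tested exactly (AUC pair counting,
integer cohort sizes); floating-point agreement (pmf vs enumeration, ES vs
reference) is asserted at 1e-10 or tighter. `computeVaf` returns the
IEEE-rounded quotient; it is correct to one ulp, and tests assert
`vaf * depth == alt` to within 1e-9 relative rather than bit equality,
which division cannot promise.

## Known limitations

* The cascade consumes annotations; it cannot rescue a mis-annotated
  consequence or a stale population frequency.
* The recurrence filter needs the whole run; calling samples one at a
  time silently disables it (the denominator becomes 1).
* CHIP-PD assignment is only as good as the driver catalog; the shipped
  list is a seed, not a curation.
* Per-cell rank-sum p-values ignore within-sample correlation; treat the
  permutation-based pathway results, not per-gene p-values, as the
  inferential output.
* The generator does not simulate read-level error, CNV-distorted VAFs,
  tumor-derived contamination of plasma, or clonal phylogenies.
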