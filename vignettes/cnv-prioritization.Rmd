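---
title: "Prioritizing copy number variants in family-structured cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing copy number variants in family-structured cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvkindred)
```

## The problem

Whole-genome genotyping arrays support CNV calling through hidden-Markov
segmentation of probe intensities, but raw call sets are dominated by short,
poorly supported segments and by polymorphic copy-number regions common in
healthy populations. In a dementia cohort that contains small families, the
scientific question is which calls behave like rare, disease-relevant
variants: segregating with affection inside a family, recurring on the same
genes across unrelated patients, or hitting genes already implicated in
neurodegeneration. `cnvkindred` implements that prioritization as a chain of
small, separately testable stages over plain data.frames, with
GenomicRanges doing the bulk interval joins internally.

## Coordinate model

Everything is 1-based and fully closed, the convention of PennCNV-style
callers: a single base is `start == end` and
`length = end - start + 1`. The bundled example-loci table
(`inst/extdata/example_candidates.tsv`) is used in the tests to pin this
convention: every printed length in it is reproduced exactly from its printed
positions. BED input (0-based half-open) is converted on read by adding one
to the start. Only autosomes chr1–chr22 are analyzed; calls elsewhere are
dropped with a warning, because sex-chromosome dosage needs a different
copy-number model.

## Filtering model and parameters

* `min_snps = 10`, `min_length = 50000` — array CNV calls below ~10 probes
  or ~50 kb have high false-positive rates at OmniExpress-like densities;
  both thresholds are exposed in `filter_config()`.
* `merge_gap_fraction = 0.2` — the HMM caller tends to split one CNV into
  adjacent fragments; two same-sample, same-chromosome, same-copy-number
  calls merge when the gap between them is at most 20% of the merged span,
  iterated to a fixpoint (merging grows the span, which can newly qualify a
  neighbour, so one left-to-right pass is not enough). Supporting-SNP counts
  are summed.
* Exclusion masks (telomeres, centromeres, segmental duplications, Ig/TCR
  loci) remove calls on *any* overlap, not containment: these regions cause
  artifactual calls whose boundaries are unreliable, so partial contact is
  already disqualifying.
* Common-variant flagging requires *complete containment* of the call in a
  reference SV of the same dosage class. Dosage class (LOSS for CN 0/1,
  GAIN for CN 3/4) rather than exact integer copy number is compared,
  because reference databases report DEL/DUP types, not integer CN.
  "Common" is per source: gnomAD-style records need > 50 bp, ≥ 100
  carriers and allele frequency ≥ 0.01; DGV-style records need ≥ 100
  carriers in a single record. We deliberately evaluate the DGV criterion
  per record rather than aggregated across studies: the slim TSV schema has
  no study column, and summing carriers across heterogeneous studies would
  overstate commonness. Flagged calls are kept with their annotation and
  removed only where a stage's contract says so, which lets reports label a
  call "likely benign" instead of silently hiding it.

## Segregation model

Array boundaries jitter between samples, so "the same CNV" in two people is
defined as same dosage class plus reciprocal overlap ≥ 0.5, where the
denominator is the larger call (`segregation_config()`). Matching is closed
under transitivity (union–find), and each maximal cluster is classified by
its carriers: at least one affected and no unaffected carrier makes a
CANDIDATE; all-unaffected carriers make a PROTECTIVE candidate; anything
else is dropped. At-risk relatives — unaffected so far but below the
family's onset ages — are treated as unknown: they neither create nor veto
candidates. The literal rule admits single-carrier candidates (a private
call in one affected member with no unaffected carrier); we keep that
behaviour because the veto, not multiplicity, is the rule's content.

Two regions are reported per candidate: the intersection of the member
calls (the conservative core every carrier shares) and the union span. The
union — the largest encompassing region — is what the case/control
intersection queries, since a carrier in an external cohort may overlap any
part of the family's variant. When a cluster's chained matches leave no
common core (possible but rare at threshold 0.5), the union is reported as
the region.

## Shared-CNV and gene-screen stages

The shared stage groups calls by (overlapped gene, exact copy number),
keeps groups with ≥ 2 distinct individuals, and consolidates groups backed
by the identical member calls into one row keyed by the shared gene set.
Intergenic shared CNVs are invisible to this stage by construction — a
documented limitation, since grouping is gene-keyed. Calls entirely within
2 Mb of an autosome end are removed first: subtelomeric regions are
CNV-hotspots in healthy genomes and enrich for artifacts. The gene screen
is a string-normalized symbol match against a user-supplied list (no alias
resolution; the gene-model table is the single source of coordinates).

## Association model

The counting unit is the individual, not the call: the 2×2 table needs
person-level denominators (cohort sizes after QC), so an individual with
several overlapping calls is one carrier. Per-copy-number counts are
reported alongside in the `"T (a|b|c|d)"` layout for compatibility with
printed tables, where an individual carrying two CN classes at a locus
contributes to both strata. `fisher_two_sided()` computes the exact
two-sided p by hypergeometric enumeration, summing all tables at the
observed margins whose point probability is at most that of the observed
table within relative tolerance 1e-7 (absorbing floating-point ties); the
all-zero table returns p = 1 by convention. The test suite checks it
against an independent `choose()`-product enumeration on every 2×2 table
with N ≤ 40 and against `stats::fisher.test` on random tables. Likelihood
ratios follow the diagnostic-test formulas; a zero false-positive cell with
carriers present yields LR+ = Inf, rendered as `"inf"` in reports rather
than dropped. No multiple-testing correction is applied by default — the
pipeline reports a handful of pre-selected candidate loci, not a
genome-wide scan.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates: an SNP grid with exponential spacing (mean
4 kb, the density of an OmniExpress-class array), genes tiled with
log-normal spans (median 30 kb), telomere/centromere exclusion masks,
Poisson background CNVs per sample (default rate 5) with log-normal
lengths (median 80 kb), and three kinds of planted signal — a family CNV
copied to designated pedigree members with boundary jitter, a shared CNV
given to unrelated samples with identical copy number, and a common CNV
emitted together with a flagged-common reference SV that contains it.
Each call's `n_snps` is the exact count of grid SNPs inside its interval.
Per-sample random streams are split from the master seed, so growing the
cohort never perturbs existing samples' draws.

Two design guards keep the planted truth unambiguous: a plant overlapping
an exclusion region is an error, and randomly placed common reference SVs
are rejected when they overlap a planted family/shared locus (otherwise a
random common SV can contain the planted rare variant and contradict its
role by construction). Boundary jitter is truncated at 12.5% of the core
length per boundary, which guarantees every jittered copy keeps ≥ 50%
reciprocal overlap with the core — recovery at the default matching
threshold is therefore decidable, not probabilistic.

The simulator does not model probe-level intensity noise, GC waves, the
HMM caller itself, linkage disequilibrium, or realistic chromosome-length
and gene-density heterogeneity. Passing recovery tests therefore
demonstrates the correctness of the prioritization logic downstream of
calling, not robustness to raw-intensity artifacts.

## Test problem sizes and numerical choices

The recovery properties run 20 simulated cohorts of three 30-Mb
chromosomes with a sibling-pair family, a trio, and 12 unrelated samples —
small enough to keep the default test run fast while exercising every code
path; the recovery scenario sets the background rate to zero so "exactly
one candidate" isolates the planted signal (the literal segregation rule
makes every private call of an affected member a candidate, so background
calls would add true-by-definition candidates, not errors). The null
calibration uses 2000 replicated tables at carrier probability 0.01 with
cohort sizes 2323/4567, checking that the Fisher rejection rate at
alpha = 0.05 stays below the exact binomial 99% upper bound — Fisher is
conservative on discrete tables, so rates well under 0.05 are expected.
Ties in the hypergeometric enumeration are the main numerical hazard and
are handled by the 1e-7 relative tolerance; merge and scan outputs are
sorted by (sample, chromosome, start) so results are invariant to input
order, which the tests assert by permutation.

## Known limitations

* Gene-keyed sharing misses intergenic recurrent CNVs.
* Symbol-string gene matching; no alias/synonym resolution.
* No sex chromosomes, no liftover, no IBD estimation (relatedness is an
  input annotation), no calling from raw intensities.
* Likelihood ratios for very sparse tables are unstable by nature; they are
  reported, not tested against thresholds.
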