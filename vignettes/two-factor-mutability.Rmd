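---
title: "Two-factor gene mutability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-factor gene mutability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomut)
```

## The model

Two genomic characteristics are repeatedly associated with elevated
mutation rates in human chromosomes: the physical proximity of a gene to a
telomere, and a high adenine + thymine fraction in its sequence. `telomut`
operationalizes these as two boolean factors per gene:

* **F(i) — telomere proximity.** The distance, in megabases, from the gene
  locus to its nearest telomere. Loci within 50 centimorgans of a telomere
  are genetically *linked* to it; under the common 1 cM ≈ 1 Mbp
  approximation the criterion becomes a 50 Mb physical distance. F(i) is
  satisfied when the distance is *below* 50 Mb.
* **F(ii) — A+T content.** The percentage of A plus T over the gene's
  full-length nucleotide sequence. F(ii) is satisfied when it *exceeds*
  59%, the human genome-wide average.

Each gene then falls into one of four categories: `BOTH` (predicted most
mutable), `FI_ONLY`, `FII_ONLY`, or `NONE` (predicted least mutable — the
attractive drug targets). The cohort-level statistic is the **matching
rate**: the fraction of genes meeting at least one factor.

```{r}
t1 <- drug_target_table("ion_channels")
summarize_cohort(classify_genes(t1))
```

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `proximity_cutoff` | 50 | Mb | the 50 cM linkage criterion under 1 cM ≈ 1 Mbp |
| `at_cutoff` | 59 | % | human genome-wide average A+T content |
| `strict_fi`, `strict_fii` | `TRUE` | — | see below |

Strict inequalities are the defaults because they are the only reading
consistent with the reference tables' own markings: the diazepam target
GABRB3 sits at exactly 59% A+T and is marked as meeting *neither* factor,
which requires "> 59" rather than "≥ 59". Prose summaries elsewhere in the
source material (a "~36%" F(ii) rate for the same 11 genes, implying ≥)
contradict those markings; we follow the tables, and
`run_two_factor_analysis()` surfaces both the strict and relaxed factor
counts in its `diagnostics` block, with the boundary genes listed, so the
discrepancy is visible rather than silently resolved. Both comparisons can
be relaxed for sensitivity analysis.

## Distances, coordinates, and tie-breaks

Coordinates are megabases from the p-terminus, with the p telomere
idealized at 0 and the q telomere at the chromosome length. A gene is
reduced to a single point locus (the viewer-readout convention; for an
interval we take its start). `nearest_telomere_distance()` takes the
smaller of the two arm distances; an exact tie at the centromere-free
midpoint goes to the p arm (documented, deterministic). When a BED3 file of
telomere intervals is supplied the distance is to the nearest interval
edge, zero inside an interval.

Two computation modes coexist, per field and with provenance recorded:
values present in the input table ("table mode") always take precedence,
because the reference tables carry viewer-read values whose reproduction
must be exact; only missing fields are computed from a chromosome-sizes
map or supplied sequences ("compute mode"). Note the reference tables mix
p-arm and q-arm telomere references and are not always the *nearest*
telomere — table mode reproduces the printed distance rather than
recomputing it.

Composition percentages are computed over unambiguous bases only; IUPAC
ambiguity codes are counted separately and excluded from the denominator,
and an entirely ambiguous sequence is an error rather than a silent 0/0.
Classification always uses the unrounded A+T value; integer percentages
appear only in reports, rounded half-up (63.6% → 64%) to match the
printed style of the reference tables.

## Size bins and statistics

Genes are grouped into three full-length-size bins: 1–3000, 3001–6000 and
6001+ bases. The third bin is displayed as "6001–17,000" after the
cohorts it was defined on, but is mathematically open-ended — the
ion-channel table itself contains a 19,659 bp gene, so the label is
cosmetic and the math is `[6001, ∞)`.

The statistical layer is deliberately thin wrappers with explicit
preconditions: Pearson's r with the two-sided p from
`t = r√((n−2)/(1−r²))` on `n−2` df; Shapiro–Wilk via `stats::shapiro.test`;
one-way ANOVA via `stats::aov` followed by `stats::TukeyHSD`, whose
studentized-range adjustment is the Tukey–Kramer form and therefore valid
for the unbalanced bins (e.g. 47/51/20). All tests are two-sided with
significance at p < 0.05. Degenerate inputs are defined rather than left
to chance: all-identical groups give F = 0, p = 1; constant vectors and
n < 3 are errors; cohorts too small for a correlation produce a logged
notice, not a failure.

## The synthetic cohort generator

The full druggable-genome cohorts (118 ion-channel and 143 GPCR genes)
live in a supplementary appendix that is not redistributed here, so the
pipeline is validated on synthetic cohorts that reproduce those cohorts'
*marginal* structure as reported: roughly 62% of ion-channel genes within
50 Mb of a telomere and ~15% above 59% A+T (71% / 29% for the GPCR-like
setting), an A+T cluster with spread ~7 percentage points, proximities up
to 250 Mb (150 for GPCRs), and size-bin occupancies 47/51/20 (88/46/8).

Generation draws F(i) membership as a Bernoulli variable and then places
the distance uniformly inside or outside the 50 Mb region; each gene is
put on a length-weighted random chromosome long enough to hold the
distance, referenced to a random arm, so locus, telomere and proximity
are mutually consistent. The A+T marginal is a normal with sd `at_sd`
whose mean is shifted so the exceedance probability at 59% equals
`frac_fii` exactly, truncated to [0, 100] by resampling (negligible mass
at the defaults). When a target size/A+T correlation is requested the two
margins are coupled through a Gaussian copula; because the size marginal
(a uniform mixture over bins with a wide upper bin) is a nonlinear
transform of the latent normal, the raw copula attenuates the Pearson
correlation, so the latent parameter is divided by the attenuation factor
`corr(F⁻¹(Φ(Z)), Z)`, computed once by deterministic numerical
integration. At n = 2000 the sample correlation then lands within ±0.1 of
the target, and the factor fractions within binomial 3σ.

What this does *not* emulate: the true per-chromosome placement of the
real gene lists, linkage between chromosome choice and composition, or
any sequence-level structure — a generated gene has consistent summary
fields, not a sequence. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline measures what the generator implanted; they
do not re-derive the published cohort-level correlations, which depend on
the appendix data.

## Problem sizes and reproducibility

The validation suite uses cohorts of up to 2000 synthetic genes and
simulation checks of 100–200 replicates (ANOVA power, Shapiro–Wilk
separation), sizes at which the binomial and copula tolerances above are
sharp; the whole suite runs in well under a minute. All generation is
seed-driven and field-for-field reproducible; the end-to-end report is
deterministic given inputs, thresholds and seed, down to byte-identical
TSV/JSON serializations.

## Known limitations

* The 1 cM ≈ 1 Mbp conversion is a genome-wide heuristic; no genetic map
  is integrated, by design.
* "Full-length size" is treated as an opaque per-gene integer as printed
  in the source tables; whether it refers to the primary transcript or
  the gene span is not stated there, and the package does not attempt to
  re-derive it (compute mode records which sequence the user supplied).
* One GPCR table row (the aripiprazole-lauroxil/HTR1A row) prints
  coordinates identical to another row and inconsistent with its stated
  chromosome; it is reproduced verbatim and flagged in
  `?drug_target_table` rather than corrected.
* Prioritization within the Both/None groups uses the package's
  documented ranking keys (A+T, then proximity, then symbol); the source
  material names its top-5 candidates but never states an ordering rule,
  so exact reproduction of those lists is out of scope.
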