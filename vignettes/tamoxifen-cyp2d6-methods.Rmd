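---
title: "CYP2D6 genotype and (Z)-endoxifen-directed tamoxifen metabolism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CYP2D6 genotype and (Z)-endoxifen-directed tamoxifen metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TamoxPGx)
```

## The problem

Tamoxifen is a prodrug: its clinical activity in estrogen-receptor-positive
breast cancer is carried mainly by (Z)-endoxifen, produced largely by the
polymorphic CYP2D6 enzyme. Patients whose steady-state plasma (Z)-endoxifen
stays below roughly 5.97 ng/ml may not benefit from a standard 20 mg/day
regimen, so two monitoring strategies compete: genotype the *CYP2D6* gene
and predict who will under-convert, or measure the metabolite directly.
TamoxPGx implements the full analysis chain needed to compare the two on a
per-patient table: star-allele diplotype calling, metabolizer-category
classification, metabolite-panel curation, the (Z)-endoxifen metabolic
ratio with its regression-derived cutoff, and the genotype-concentration
association battery. A calibrated synthetic-cohort generator stands in for
patient data, which cannot be redistributed.

## Star-allele calling

The genotyping model is an 11-variant allelic-discrimination panel plus a
gene copy-number assay. An unphased diplotype (a, b) implies at every panel
variant an alternate-allele *dose*: the number of the two alleles whose
defining set contains the variant. `callDiplotype()` enumerates all allele
pairs consistent with the observed doses and keeps the most parsimonious
assignment (fewest non-reference alleles, then highest total match
priority, which defaults to the number of defining variants so specific
alleles beat \*1/\*2). Equally ranked survivors are returned in
`ambiguous_alternatives` rather than dropped. Copy number enters as data,
not annotation: 1 copy forces one allele to the deletion allele \*5 and
makes the retained haplotype's variants read as homozygous; 0 copies gives
\*5/\*5; 3 or more copies flags a duplication.

The shipped definition table (`extdata/cyp2d6_alleles.yaml`) is a
deliberately simplified, auditable mapping: each non-wild-type allele is
recognised by one canonical defining signature (\*4 by 1846G>A, \*3 by
2549delA, \*6 by 1707delT, \*10 by 100C>T, \*41 by 2988G>A, \*7 by
2935A>C, \*9 by its AAG deletion), \*2 by a three-variant signature and
\*17 by a two-variant signature sharing 2851C>T with \*2. Real CYP2D6
haplotypes share more variants than this; the table is config-driven
precisely so a laboratory can substitute its own panel. Hybrid alleles and
sequencing-based calling are out of scope.

Classification follows the four activity classes (EM: \*1, \*2; IM: \*9,
\*10, \*17, \*41; PM: \*3-\*7) folded into seven ordered diplotype
categories, PM/PM < IM/PM < IM/IM < EM/PM < EM/IM < EM/EM < EM/UM. A
duplication promotes EM/EM to EM/UM. A duplication co-occurring with a
reduced or null allele has no defined category in this scheme and none
occurred in the cohort the scheme comes from; `classifyPhenotype()`
therefore raises an explicit indeterminate error by default (or returns
the unpromoted label with a flag), rather than guessing.

Variants with a `no_call` state exclude the alleles they define from
matching and mark the diplotype low-confidence - a fail-soft rule that
keeps provenance visible instead of silently defaulting to \*1.

## The metabolite panel

Thirteen analytes are carried per patient (tamoxifen plus 12 metabolites);
the two isobaric pairs - (Z)-endoxifen + 3-OH-NDM-Tam and (Z)-4-OH-Tam +
3-OH-Tam - are single summed analytes end-to-end, as they cannot be
separated chromatographically, and are referred to by their dominant
component. Each measurement has a quantitation status: `quantified` inside
the calibration linearity range; `estimated_below_lolr` below the lower
linearity bound when the signal-to-noise ratio exceeds 10; `not_detected`
otherwise. Values above the upper bound stay quantified with an
extrapolation flag. Not-detected values contribute 0 to all downstream
sums (the MR denominator) but are excluded from location/scale summaries,
which report a separate not-detected count; estimated values are included
in summaries by default with a switch to drop them, since the source
summary table does not state its own convention.

Patients whose plasma tamoxifen is below 10% of the cohort mean are
excluded before any association analysis (non-adherence or recent start).
The mean is computed once over the pre-exclusion cohort and the rule is
applied in a single pass: iterating the operator could remove further
patients as the mean shifts, and the tests document a crafted case where
it would. The data container is a `SummarizedExperiment` subclass
(`TamoxifenCohort`, analytes x patients) with parallel concentration and
status assays.

## Metabolic ratio and the efficacy cutoff

The metabolic ratio is MR = (Z)-endoxifen / (sum of the other 12 measured
compounds). Tamoxifen itself belongs in the denominator: at the cohort's
scale the 6 ng/ml threshold divided by the 0.0146 cutoff implies a
denominator near 410 ng/ml, which only the tamoxifen- and NDM-Tam-
dominated total reaches. MR is dimensionless and invariant to a common
rescaling of the panel, which is why a shared exposure factor (dose
timing, adherence) cancels in it but not in the raw concentration.

The cutoff translating the concentration threshold into MR units is read
off a simple linear regression between the two. The source analysis says
only "simple linear regression fit"; the package's default regresses MR on
concentration with an intercept and evaluates the fit at the 6 ng/ml
reference level, and the reverse direction (concentration on MR, solved
for MR) is implemented and exposed because the choice is genuinely open.
Two distinct reference levels are kept in `thresholdConfig()` - 5.97 ng/ml
for below-threshold prevalence, 6.0 ng/ml for cutoff derivation - because
both figures are used in the source analysis. Boundary handling is strict
(`<`) on both axes, following the "low (<6 ng/ml)" wording; values exactly
at a threshold count as not-below.

## Association battery

* **Hardy-Weinberg**: per-variant 1-df Pearson chi-square against
  expectations at the allele frequencies estimated from the same counts,
  no continuity correction; only copy-number-2 patients contribute
  (hemizygous and duplicated genotypes do not observe two alleles);
  monomorphic variants return chi-square 0, p = 1 by convention.
* **Indicator OLS**: each outcome is regressed on category indicators with
  EM/EM as reference, so the intercept is the EM/EM mean and every
  coefficient a group-mean difference (this closed-form identity is the
  test oracle). Two-sided Student t p-values; significance at the
  Bonferroni threshold 0.05/(12 outcomes x 6 groups) = 6.9e-4. Groups
  with a single observation are retained.
* **Spearman with AS 89 p-values**: r from midranks; for n <= 9 without
  ties the exact permutation distribution of S = sum of squared rank
  differences is enumerated; otherwise the AS 89 Edgeworth tail expansion
  is used, applied under ties to the S value implied by the midrank
  correlation. The smaller tail is doubled and capped at 1. Far in the
  tail the Edgeworth polynomial can overwhelm (and sign-flip) the leading
  normal term; the implementation then falls back to the leading term,
  keeping p-values positive and monotone. The n <= 9 exact cutoff is the
  published algorithm's split and a documented constant.
* **Contingency chi-square**: Pearson without continuity correction, with
  a low-expected-count flag (any expected cell below 1).

The 12 outcomes are the 10 reliably quantifiable metabolite concentrations
(excluding tamoxifen itself and the two essentially undetectable trace
isomers, (E)-endoxifen and (Z)-alpha-OH-Tam) plus the two metabolic
ratios. The ordinal genotype encoding for Spearman is the category rank
0-6 by default; a functional-allele activity score (EM = 1, IM = 0.5,
PM = 0 per allele, +1 per duplication) is provided as an alternative
because the original encoding is not stated. All tests are two-sided.

## The synthetic cohort generator

The generator emulates the study conditions: 285 enrolled patients,
Hardy-Weinberg diplotypes at the cohort's allele frequencies (\*4 = 0.223
and \*41 = 0.077 as printed; the remaining frequencies derived by allele
counting from the genotype-frequency table and rescaled), duplication
probability 0.163 calibrated so EM/UM is about 6.5% of patients, and
6/285 low-exposure patients whose whole panel is scaled to about 2% of
typical exposure so the 10% exclusion rule always catches them.

Concentrations are log-normal per analyte. Category multipliers encode the
five genotype-dependent compounds: (Z)-endoxifen anchored to the printed
group means (1.8, 2.3, 4.9, 7.3 ng/ml for PM/PM, IM/PM, EM/PM, EM/EM,
with the unreported EM/IM, IM/IM and EM/UM levels interpolated at 0.70,
0.45 and 1.10 of the EM/EM level), (Z)-4-OH-Tam geometrically interpolated
between its printed 1.5 and 2.7 ng/ml extremes, and NDM-Tam,
4'-OH-NDM-Tam (rising with impairment) and the 4-OH-NDM glucuronide
(falling with impairment) given geometric per-step factors reproducing the
reported directions. Given the multipliers and the theoretical category
weights, a closed-form calibration sets the per-category log-normal
locations and the shared within-category log-variance so each analyte's
cohort-level arithmetic mean and SD match the published summary table
exactly in expectation. A mean-one log-normal exposure factor
(sdlog = 0.25) multiplies every analyte of a patient, modelling adherence
and dose-interval variability; it widens concentrations but cancels in the
MR, which is what makes the MR more strongly genotype-determined than the
raw concentration in the generated data, as in the source cohort.
Detection limits sit at the log-normal quantiles matching the published
not-detected rates (89.2% for (E)-endoxifen, 41.6% for (Z)-alpha-OH-Tam,
2.9% for (E)-alpha-OH-Tam).

What the generator does **not** emulate: co-medication with CYP2D6
inhibitors, non-compliance beyond a single scale factor, phase-II enzyme
polymorphisms, assay drift, or any within-patient correlation structure
beyond the shared exposure factor. Passing tests therefore demonstrate
that the pipeline recovers the structure this model encodes - not that
real cohorts satisfy the model.

One calibration tension is worth stating openly: the published
cohort-level SD for (Z)-endoxifen (3.26 ng/ml) is barely larger than the
spread implied by the printed genotype-group means alone, so a clean
log-normal mixture matching both necessarily attributes more variance to
genotype than the study's Spearman r-squared of 0.27 reports. The
generator follows the explicit mean/SD calibration; consequently its
genotype r-squared for the (Z)-endoxifen concentration comes out near
0.45, and the MR r-squared near 0.55 (against the printed 0.51). Real
cohorts carry non-genotype variance sources (inhibitors, adherence) that
a marginal-moment calibration cannot see. The within-category spread is
configurable for users who prefer to target the correlation instead.

## Numerical choices and edge cases

* Exact arithmetic-moment calibration uses
  `exp(V) = (SD^2 + M^2) / sum(w_g * mu_g^2)` for the within-category
  log-variance, floored at 1e-4; the analyte-specific component is the
  remainder after the exposure variance, also floored.
* The AS 89 Edgeworth coefficients are the published constants; the exact
  branch enumerates all n! permutations (n <= 9, at most 362,880 rows).
* Diplotype tie-breaking is deterministic: candidate pairs are ordered by
  (non-reference allele count, -total priority) and the first is returned,
  with exact ties reported as alternatives.
* Degenerate inputs error loudly: empty cohorts, zero MR denominators,
  constant outcomes (zero residual variance), constant correlation inputs,
  frequencies not summing to 1, copy-number QC failures.
* Seeds: `generatorConfig(seed =)` makes generation byte-deterministic;
  concentration draws use seed + 1 so genotype and concentration layers
  can be reproduced independently.

## Known limitations

* The pooled-variance t test on a log-normal outcome is anti-conservative
  when a genotype group holds only 1-3 patients (IM/IM at these allele
  frequencies). Under the null generator the realised family-wise error
  of the 72-test battery exceeds the nominal 0.05 (about 0.15 in the
  package's 200-replicate check) even though the same battery is exactly
  calibrated under normal errors. This is a property of the published
  analysis design interacting with skewed concentrations, and the
  acceptance test records it as a failure rather than relaxing the bound.
  Log-transforming outcomes would restore calibration but would no longer
  mirror the source analysis.
* Diplotype calling is limited by the one-signature-per-allele default
  table; laboratories should supply their own definitions for panels with
  shared tag variants.
* The per-patient study table is not redistributable, so the study's exact
  headline counts (167/279 below threshold; quadrants 84/142/25/28) are
  checked against the calibrated synthetic surrogate at stochastic slack,
  not reproduced patient-for-patient.

## Problem sizes used in the test suite

Module tests run on cohorts of 10-150 patients; calibration checks use
20,000-100,000 genotype draws; the null family-wise-error check runs 200
replicates of the full 279-patient battery; the acceptance script runs the
285-patient study configuration once end-to-end.
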