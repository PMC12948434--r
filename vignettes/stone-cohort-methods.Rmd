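---
title: "Methods: rare-variant interpretation and recurrence analysis for adult kidney stone cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant interpretation and recurrence analysis for adult kidney stone cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoneRisk)
```

## Scope and model

`stoneRisk` implements a cohort-scale pipeline for interpreting rare
variants in a 39-gene kidney stone disease (KSD) panel in adults, and for
asking whether carrying a "strong" genetic risk factor predicts stone
recurrence. The pipeline has five analytic stages, each an independent
module with a plain-data interface:

1. **Variant filtering** (`runFilterCascade()`): panel restriction, then
   quality, cohort-frequency, population-frequency and consequence filters
   in a fixed order.
2. **ACMG/AMP classification** (`combineEvidence()`): per-variant evidence
   codes are combined into the 5-tier scale (P / LP / VUS / LB / B).
   Evidence codes are *inputs*: curation is upstream of this package.
3. **Diagnosis** (`diagnoseCohort()`): classified variants plus gene
   inheritance modes give each individual exactly one category, a
   monogenic-KSD flag, and — after biochemistry-driven reclassification —
   a strong-risk-factor flag.
4. **Biochemical phenotyping** (`deriveBiochem()`): TmP/GFR,
   creatinine-normalized ratios, a simplified supersaturation index, and
   the cystinuria amino-acid profile.
5. **Cohort statistics** (`chiSquare2x2()`, `mannWhitney()`,
   `kruskalWallis()`, `kmEstimate()`, `logrankTest()`, `coxPh()`).

Because per-patient sequencing data for such cohorts are not publicly
shareable, the package ships a first-class synthetic cohort generator
(`simulateCohort()`) that emulates the joint structure the analysis
assumes — planted diagnosis categories, genotype-conditional biochemistry,
and a two-group recurrence process — so that every stage is testable end to
end without any download.

## Variant filtering

A site is identified by (chrom, pos, ref, alt) across individuals. The
stages, with defaults in `FilterConfig()`:

* **Quality.** A site is removed for all carriers when more than 60% of
  its carrier individuals have a variant allele fraction below 0.3, or
  when its quality score is below 25. The low-allele-fraction proportion
  is computed over *carriers* of the site, not all genotyped individuals:
  the rule targets recurrent alignment artifacts, which manifest as
  skewed allele fractions in the individuals that show the call. This is
  a deliberate reading of an ambiguous rule, flagged for sensitivity
  analysis; the proportion basis is configurable only by code change,
  the thresholds via `FilterConfig`.
* **Cohort frequency.** Sites carried by more than 10% of cohort
  individuals are removed.
* **Population frequency.** gnomAD AF strictly greater than 1% removes a
  record. A missing AF is treated as rare and retained — novel variants
  must reach classification. Whitelisted known-pathogenic intronic
  variants are exempt.
* **Consequence.** Nonsynonymous coding (missense, stop gain, frameshift,
  in-frame indel), canonical splice, splice-region variants up to 10 bp
  into the intron, and whitelisted intronic variants are retained;
  synonymous and deep-intronic records are removed.

All frequency comparisons are strict (`>`), matching the wording of the
filter they implement. The stages are site- or record-local, so quality
and cohort-frequency commute, as do population-frequency and consequence;
every stage is idempotent, and the cascade report attributes each removed
record to the first stage that would drop it, so counts conserve
(`n_in = n_out + sum(removed)`). All of these are property-tested.

## ACMG/AMP combining rules

`combineEvidence()` implements the published rule table over evidence
counts per strength tier, after applying optional per-code strength
overrides (so ClinGen-calibrated PP3/BP4 usage at non-default strengths is
expressible without embedding any in-silico predictor). Two deliberate
conventions:

* **Conflicts.** If both a pathogenic-side and a benign-side rule match,
  the class is VUS. The guideline calls this "uncertain"; no attempt is
  made to adjudicate.
* **Functional upgrade.** Published functional evidence may justify
  upgrading a would-be VUS, but only through an explicit two-flag path
  (`functionalSupport` + `applyFunctionalUpgrade`), never silently, and it
  never touches a non-VUS result.

The engine is verified two ways: frozen examples of the rule table, and
exhaustive agreement with an independently coded oracle — the rule table
transcribed as data and matched with minimum-count semantics — over all
evidence sets with up to three codes per strength tier (4096 sets).
A property test checks monotonicity: adding pathogenic-family evidence
never moves a class toward benign and vice versa (a conflict collapse to
VUS moves *toward the middle*, which is consistent with that ordering).

## Diagnosis and reclassification

Within one gene of one individual, likely-pathogenic/pathogenic (LP/P)
variants are resolved to a biallelic status: homozygous is proven
biallelic; two heterozygous variants proven in *trans* by reads are proven
biallelic; proven in *cis* they count as one allele; unknown phase is
*presumed* biallelic. Biochemical corroboration of presumed trans (e.g.
dibasic aminoaciduria in cystinuria genes) is recorded as an annotation
but never changes the category by itself — discordant biochemistry in a
presumed compound heterozygote is a finding, not a reassignment.

Categories are assigned by precedence — biallelic (AR, then AD/AR gene) >
X-linked hemizygous (males) > monoallelic in an AD gene > monoallelic in
an AD/AR gene > AR carrier > VUS carrier > LB/B carrier > none — so each
individual lands in exactly one category (the "pie" view). Individuals
with monogenic findings in several genes keep the highest category in the
pie but appear once per gene in `geneBarView()` (the "bar" view). X-linked
heterozygous females map to the carrier class, since the category set has
no dedicated X-linked carrier label.

**Reclassification.** Monoallelic LP/P findings in genes whose carriers
lacked the expected biochemical signature (`SLC9A3R1`, `SLC34A1`,
`CYP24A1`), and the recurrent hypomorphic `SLC7A9` p.(Ala182Thr) allele in
the monoallelic state, are demoted: they no longer support the
strong-risk-factor flag. Biallelic and hemizygous findings are never
demoted — p.(Ala182Thr) in *trans* with a second LP/P allele still counts.
An individual is a strong-risk carrier iff at least one monogenic-tier
finding survives demotion; hence reclassification can only reduce the
solve rate, which is asserted as a monotonicity test.

Printed percentages use half-up rounding to one decimal
(`roundHalfUp()`), the convention of clinical cohort tables, rather than
R's round-half-even.

## Biochemical phenotyping

* **TRP / TmP/GFR.** TRP = 1 − (U~P~·P~cr~)/(U~cr~·P~P~) with plasma
  creatinine in µmol/L converted internally. TmP/GFR uses the
  Payne/Barth algebraic approximation of the Walton–Bijvoet nomogram:
  linear (TRP·P~P~) for TRP ≤ 0.86, and 0.3·TRP/(1 − 0.8·TRP)·P~P~ above.
  The quantity is named in clinical practice without a formula; this
  approximation is the universal clinical standard. The two branches do
  not meet exactly at 0.86 (0.860 vs 0.827 · P~P~) — that step is a
  property of the published nomogram approximation, documented and
  asserted exactly rather than smoothed.
* **Supersaturation.** A deliberately simplified ion-activity-product
  index SS = γ²·[Ca²⁺]·[anion]/K~sp~ for calcium oxalate and brushite:
  Davies activity coefficients from an ionic strength estimate (measured
  di-/trivalent ions plus a configurable 0.15 M monovalent background),
  divalent phosphate fraction from urine pH with pK~a2~ = 7.20, and an
  optional single Ca-citrate 1:1 pairing correction (K = 1600 L/mol).
  Full iterative speciation (the EQUIL2 program) is a declared non-goal:
  this index is suitable for rank and direction comparisons only and its
  values are **not** numerically comparable to EQUIL2 scores. Its tested
  contract is qualitative: zero when either ion is absent, strictly
  increasing in calcium, brushite increasing in pH, and invariant to
  consistent unit rescaling.
* **Cystinuria profile.** Creatinine-normalized cystine, ornithine,
  lysine and arginine are classified against editable reference upper
  bounds (defaults from the adult clinical literature; `markedFactor = 3`
  separates moderate from marked elevation). The summary flag is
  "marked" when cystine is markedly elevated or at least two dibasic
  amino acids are elevated.
* **Visit policy.** The study design measures baseline biochemistry at
  visit 2; `deriveBiochem(visitSelect = "V2")` makes the selection
  explicit rather than implicit, and no imputation of missing visits is
  attempted.

## Cohort statistics

Group comparisons follow the cohort's reporting conventions:
Shapiro-Wilk-gated summaries (`shapiroGate()`), Mann-Whitney U for two
groups (exact for small tie-free samples, tie-corrected normal
approximation otherwise, no continuity correction), Kruskal-Wallis across
variant classes, and Pearson's chi-square for categorical contrasts
**without** Yates continuity correction — the uncorrected statistic on the
published carrier table (107/594 vs 18/182) reproduces the printed
p = 0.0238, while the corrected one gives 0.032. No multiple-testing
correction is applied by default, matching the source analysis; p-values
are reported as-is.

The survival suite wraps the `survival` package: Kaplan-Meier
product-limit curves with risk tables, the log-rank test, and Cox
proportional hazards with Efron tie handling (the tie method is not
dictated by the analysis being reproduced; Efron is the robust default)
and age/sex as covariates. Each wrapped routine is cross-checked in the
tests against an independent oracle: a hand product-limit computation for
KM, the score test of the unadjusted Cox fit for the log-rank statistic,
and a brute-force partial-likelihood maximization on a six-record dataset
for the Cox coefficient. Degenerate inputs (fully tied rank samples, zero
margins, all-censored records) are defined or fail fast rather than
returning NaN.

## The synthetic cohort generator

The generator's defaults *are* the study conditions, not tuning knobs:

* **Composition.** 701 stone formers and 200 controls. The planted LP/P
  findings reproduce the internally consistent published counts: 11
  biallelic individuals (SLC3A1 homozygotes and compound heterozygotes,
  biallelic SLC7A9, homozygous CYP24A1), one OCRL hemizygote, 57
  monoallelic AD / AD-AR individuals with the published per-gene counts,
  and 38 AR carriers — 107 LP/P carriers (15.2%). Demotion leaves 48
  strong-risk individuals (6.8%). One biallelic-SLC7A9 individual also
  carries the recurrent monoallelic SLC9A3R1 allele, exercising the
  pie-versus-bar double-listing and the demotion-immunity of biallelic
  findings. The published VUS / LB/B / none percentages are mutually
  inconsistent with the LP/P arithmetic (they sum past the cohort size);
  the generator keeps the published VUS (256) and LB/B (143) counts and
  derives "none" as the remainder (195).
* **Biochemistry.** Log-normal baselines centred inside adult reference
  ranges (positivity and right skew, consistent with nonparametric
  reporting), a per-individual random intercept for within-individual
  correlation across the 7 visits, and genotype-conditional shifts in SD
  units on the log scale. Directions are anchored to the reported
  effects (SLC34A3 heterozygotes: phosphate wasting and hypercalciuria;
  biallelic cystinuria genes: marked cystine and dibasic elevation;
  monoallelic SLC7A9 except p.(Ala182Thr): moderate cystine elevation;
  demoted genotypes: null). Magnitudes are generator configuration, set
  once to values a clinical chemist would call realistic for those
  phenotypes (1 SD for the heterozygous phosphate phenotype, 1.5 SD for
  moderate cystine elevation, 4-6 SD for overt cystinuria), because the
  exact group medians live in supplementary material not reproduced
  here.
* **Recurrence.** Exponential time to first recurrence, administrative
  censoring at 1095 days, true hazard ratio 2.4506 for the strong-risk
  group, baseline hazard set so roughly 30% of non-strong individuals
  recur within three years. The analysis subset is all 48 strong-risk
  stone formers plus 302 others with complete follow-up; 5 and 7
  individuals respectively are planted with more than one recurrence.
* **Determinism.** The full bundle is byte-identical for identical
  configurations (seed included), and the generator only emits variants
  that survive the filter cascade, so filter → classify → diagnose
  recovers the planted categories exactly. Infeasible plans and a zero
  censoring horizon fail fast.

What passing these tests does **not** show: the generator has no
sequencing error process, no relatedness, no ancestry structure, no
medication effects, no missing visits, and treats stone-former and
control carriers identically at the biochemical level. Agreement on the
synthetic cohort validates the *logic* of the pipeline, not the
biological effect sizes.

## Problem sizes and numerical choices

The shipped tests run the full 901-individual cohort for the
count-partition checks, 4096 evidence sets for the classifier oracle,
200 replicate cohorts (n = 2000, and n = 350 at the study's 48 vs 302
split) for Cox recovery and CI coverage, 2000 replicates per test for
type-I calibration, and a 1000-composition grid for the supersaturation
properties — sizes chosen so each check is statistically meaningful while
the whole suite stays interactive. Tolerances: exact equality for counts
and rounded percentages, 1e-9 for closed-form arithmetic, 1e-4 against
the brute-force Cox oracle, ±10% for stochastic parameter recovery, and
[0.035, 0.065] for nominal-5% type-I rates.

## Known limitations

* Evidence codes are inputs; no automated criterion assignment.
* No family segregation, polygenic scores, ancestry inference, or eGFR
  trajectory modeling.
* The supersaturation index is a documented surrogate (see above).
* The AD versus AD/AR split of the 57 monoallelic individuals cannot be
  reconciled exactly with the published per-gene counts; the generator
  matches the per-gene counts and the combined 8.1%, which is the
  quantity the category table prints.
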