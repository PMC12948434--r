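# stoneRisk

Rare-variant interpretation and biochemical phenotyping for adult kidney
stone disease (KSD) cohorts.

About 10% of adults form kidney stones, and a minority carry rare variants
in established KSD genes. Deciding which of those variants are *strong*
genetic risk factors — worth genetic counseling and predictive of
recurrence — is hard: many reportedly pathogenic monoallelic variants are
equally common in people who never form stones. `stoneRisk` implements the
full interpretation pipeline for this problem, for analysts working with
case/control stone cohorts that pair panel sequencing with 24-hour urine
and blood phenotyping:

* a four-stage **variant filter cascade** over a 39-gene panel
  (quality: allele fraction < 0.3 in > 60% of carriers or quality < 25;
  cohort carrier fraction > 10%; gnomAD AF > 1%; nonsynonymous coding /
  splice-window consequences);
* an **ACMG/AMP evidence-combining engine** mapping per-variant criteria
  (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7, with strength
  overrides) to the 5-tier P/LP/VUS/LB/B scale;
* an **inheritance-aware diagnosis engine**: biallelic resolution with
  compound-heterozygote phasing (reads in *trans*/*cis*/unknown), one
  category per individual, and biochemistry-driven **reclassification**
  that demotes monoallelic findings in `SLC9A3R1`, `SLC34A1`, `CYP24A1`
  and the `SLC7A9` p.(Ala182Thr) allele from strong-risk status;
* **derived biochemistry**: TRP and TmP/GFR (Walton–Bijvoet
  approximation, branch at TRP = 0.86), creatinine ratios, a simplified
  calcium-oxalate/brushite supersaturation index (Davies activity
  coefficients, pH-dependent phosphate speciation), and cystinuria
  amino-acid profiles;
* a **statistics suite**: uncorrected Pearson chi-square, Mann-Whitney,
  Kruskal-Wallis, Shapiro-gated summaries, Kaplan-Meier / log-rank, and
  Cox proportional hazards (Efron ties, age/sex covariates) for
  time-to-recurrence, where HR = exp(β) from the partial likelihood;
* a seeded **synthetic cohort generator** reproducing the study-scale
  structure (701 stone formers, 200 controls, planted diagnosis
  categories, genotype-conditional biochemistry, true recurrence
  HR = 2.4506) so the whole pipeline runs without patient data.

## Worked example

```r
library(stoneRisk)

panel <- defaultGenePanel()
sim   <- simulateCohort(SimConfig(seed = 1))

res <- runFilterCascade(sim$variants, panel,
                        nIndividuals = nrow(sim$individuals))
dx  <- diagnoseCohort(classifyVariants(res$variants), sim$individuals,
                      panel, sim$phase)

subset(cohortCounts(dx, "KSF"), n > 0)
#>            category   n  pct
#> 1      biallelic_AR   5  0.7
#> 2   biallelic_AD_AR   6  0.9
#> 3    XLR_hemizygous   1  0.1
#> 4    monoallelic_AD  16  2.3
#> 5 monoallelic_AD_AR  41  5.8
#> 6        carrier_AR  38  5.4
#> 7       VUS_carrier 256 36.5
#> 8      LB_B_carrier 143 20.4
#> 9              none 195 27.8

solveRate(dx, "pre_reclassification")   # 9.8  (% monogenic KSD)
solveRate(dx, "post_reclassification")  # 6.8  (% after demotion)

multiRecurrenceSummary(sim$survival)
#>            group   n n_multi  pct
#> 1    strong_risk  48       5 10.4
#> 2 no_strong_risk 302       7  2.3

coxPh(sim$survival)[1, c("HR", "ci_low", "ci_high", "p_value")]
```

Reading: 1.6% of stone formers carry (presumed) biallelic variants, 8.1%
monoallelic variants in dominant or mixed-mode genes, and 5.4% are
recessive-disease carriers; 9.8% qualify as monogenic KSD before
reclassification and 6.8% retain a strong risk factor afterwards. Among
strong-risk carriers, 10.4% had multiple stone recurrences within three
years versus 2.3% of the others, and the Cox model estimates the
recurrence hazard ratio of the strong-risk group (the generator's true
value is 2.4506).

See `vignettes/stone-cohort-methods.Rmd` for the model, parameter and
design documentation.

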