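Package: stoneRisk
Title: Rare-Variant Interpretation and Biochemical Phenotyping for Adult
    Kidney Stone Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort-scale interpretation of rare variants in a 39-gene
    kidney stone disease panel: quality/frequency/consequence variant
    filtering, ACMG/AMP evidence combining into the 5-tier classification,
    inheritance-mode-aware monogenic diagnosis with compound-heterozygote
    phasing logic and biochemistry-driven reclassification of monoallelic
    risk factors, derived biochemical phenotyping (TmP/GFR, urinary
    creatinine ratios, a simplified supersaturation index, cystinuria
    amino-acid profiles), nonparametric group comparison and stone
    recurrence survival analysis, plus a seeded synthetic cohort generator
    emulating the joint genotype-biochemistry-recurrence structure so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
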