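# shared fixture builders; everything is generated in code at test time

# one annotated variant row with sensible pass-everything defaults
vrow <- function(id = "S1", gene = "SLC7A9", chrom = "19", pos = 1000L,
                 ref = "A", alt = "G", genotype = "het",
                 allele_fraction = 0.5, site_quality = 60,
                 consequence = "missense", splice_distance_bp = 0L,
                 gnomad_af = 0.001, whitelist = FALSE, hgvs_p = "p.(X1Y)",
                 evidence = NA_character_) {
  data.frame(individual_id = id, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, genotype = genotype,
             allele_fraction = allele_fraction, site_quality = site_quality,
             consequence = consequence,
             splice_distance_bp = splice_distance_bp, gnomad_af = gnomad_af,
             whitelist_pathogenic_intronic = whitelist, hgvs_p = hgvs_p,
             evidence_codes = evidence, stringsAsFactors = FALSE)
}

vtab <- function(...) do.call(rbind, list(...))

indrow <- function(id, sex = "M", group = "KSF") {
  data.frame(individual_id = id, sex = sex, group = group,
             stringsAsFactors = FALSE)
}

# small, fast cohort configuration for property tests
smallSimConfig <- function(seed = 1L) {
  plan <- defaultPlan()
  SimConfig(nKsf = 150L, nNksf = 60L, seed = seed,
            plan = plan[plan$kind %in% c("hom", "ch_trans", "ch_presumed",
                                         "hemi") |
                          plan$gene %in% c("SLC34A3", "SLC34A1", "CYP24A1",
                                           "SLC9A3R1", "SLC7A9"), ],
            nVus = c(KSF = 20L, NKSF = 10L), nLbb = c(KSF = 10L, NKSF = 5L),
            nRecurrenceControls = 80L,
            multiRecurrence = c(strong = 2L, other = 2L))
}

# stable row identity for set comparisons in filter property tests
.rowkey <- function(v) paste(v$individual_id, v$chrom, v$pos, v$ref, v$alt)
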