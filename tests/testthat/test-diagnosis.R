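panel <- defaultGenePanel()

# classified LP variant row
lpv <- function(id, gene, pos, genotype = "het", hgvs = "p.(X1Y)",
                class = "LP", chrom = "1") {
  v <- vrow(id = id, gene = gene, chrom = chrom, pos = pos,
            genotype = genotype, hgvs_p = hgvs)
  v$acmg_class <- class
  v
}

test_that("biallelic resolution follows zygosity and read-backed phase", {
  expect_equal(resolveBiallelic("hom_alt")$status, "biallelic_proven")
  expect_equal(resolveBiallelic(c("het", "het"), "trans_by_reads")$status,
               "biallelic_proven")
  expect_equal(resolveBiallelic(c("het", "het"), "cis_by_reads")$status,
               "monoallelic_only")
  expect_equal(resolveBiallelic(c("het", "het"), "unknown")$status,
               "biallelic_presumed")
  expect_equal(resolveBiallelic("het")$status, "monoallelic_only")
  expect_true(resolveBiallelic(c("het", "het", "het"))$flagged_for_review)
  # corroboration is recorded, not category-changing
  rb <- resolveBiallelic(c("het", "het"), "unknown",
                         biochemCorroboration = FALSE)
  expect_equal(rb$status, "biallelic_presumed")
  expect_false(rb$corroborated)
})

test_that("category precedence: biallelic > XLR > monoallelic AD > AD_AR >
          carrier > VUS > LB/B", {
  inds <- rbind(indrow("hemi_m"), indrow("multi"), indrow("vus_only"),
                indrow("cis_pair"), indrow("xl_f", sex = "F"))
  v <- rbind(
    lpv("hemi_m", "OCRL", 1L, genotype = "hemi", chrom = "X"),
    # monoallelic SLC9A3R1 on top of biallelic SLC7A9: pie keeps biallelic
    lpv("multi", "SLC9A3R1", 10L, chrom = "17"),
    lpv("multi", "SLC7A9", 20L, chrom = "19", hgvs = "p.(A1B)"),
    lpv("multi", "SLC7A9", 30L, chrom = "19", hgvs = "p.(C2D)"),
    lpv("vus_only", "ALPL", 40L, class = "VUS"),
    lpv("cis_pair", "SLC3A1", 50L, chrom = "2", hgvs = "p.(E3F)"),
    lpv("cis_pair", "SLC3A1", 60L, chrom = "2", hgvs = "p.(G4H)"),
    lpv("xl_f", "CLCN5", 70L, chrom = "X"))
  phase <- data.frame(
    individual_id = c("multi", "cis_pair"),
    gene = c("SLC7A9", "SLC3A1"),
    phase = c("trans_by_reads", "cis_by_reads"), stringsAsFactors = FALSE)
  dx <- diagnoseCohort(v, inds, panel, phase)
  get <- function(id, col) dx[[col]][dx$individual_id == id]
  expect_equal(get("hemi_m", "category"), "XLR_hemizygous")
  expect_equal(get("multi", "category"), "biallelic_AD_AR")
  expect_equal(get("vus_only", "category"), "VUS_carrier")
  # cis pair counts as one allele: AR carrier, never biallelic
  expect_equal(get("cis_pair", "category"), "carrier_AR")
  # X-linked heterozygous female maps to the carrier class
  expect_equal(get("xl_f", "category"), "carrier_AR")
  # bar view lists the multi-gene individual twice
  bars <- geneBarView(v, inds, panel, phase)
  expect_equal(sort(bars$gene[bars$individual_id == "multi"]),
               c("SLC7A9", "SLC9A3R1"))
  # hemizygous call in a female is rejected
  expect_error(
    diagnoseCohort(lpv("xl_f", "OCRL", 1L, genotype = "hemi", chrom = "X"),
                   indrow("xl_f", sex = "F"), panel),
    "hemizygous")
})

test_that("reclassification demotes monoallelic findings in demoted genes
          and the demoted allele, never biallelic ones", {
  inds <- rbind(indrow("cyp_mono"), indrow("cyp_bi"), indrow("s34a3"),
                indrow("a182t"), indrow("a182t_ch"), indrow("multi"))
  v <- rbind(
    lpv("cyp_mono", "CYP24A1", 1L, chrom = "20"),
    lpv("cyp_bi", "CYP24A1", 2L, chrom = "20", genotype = "hom_alt"),
    lpv("s34a3", "SLC34A3", 3L, chrom = "9"),
    lpv("a182t", "SLC7A9", 4L, chrom = "19", hgvs = "p.(Ala182Thr)"),
    # Ala182Thr in trans with a second LP allele is biallelic: not demoted
    lpv("a182t_ch", "SLC7A9", 4L, chrom = "19", hgvs = "p.(Ala182Thr)"),
    lpv("a182t_ch", "SLC7A9", 5L, chrom = "19", hgvs = "p.(Q9R)"),
    # demoted SLC9A3R1 finding plus a non-demoted SLC34A3 finding
    lpv("multi", "SLC9A3R1", 6L, chrom = "17"),
    lpv("multi", "SLC34A3", 7L, chrom = "9"))
  dx <- diagnoseCohort(v, inds, panel)
  get <- function(id) dx$strong_risk_factor[dx$individual_id == id]
  expect_false(get("cyp_mono"))
  expect_true(get("cyp_bi"))
  expect_true(get("s34a3"))
  expect_false(get("a182t"))
  expect_true(get("a182t_ch"))
  expect_true(get("multi"))
  # every strong-risk individual is monogenic
  expect_true(all(dx$monogenic_ksd[dx$strong_risk_factor]))
  # demotion is monotone: an undemoted panel never has fewer strong calls
  plain <- panel@genes
  plain$monoallelic_demoted <- FALSE
  dxPlain <- diagnoseCohort(v, inds, GenePanel(plain))
  expect_true(all(dxPlain$strong_risk_factor >= dx$strong_risk_factor))
})

test_that("reclassifyStrongRisk recomputes flags under a modified panel", {
  inds <- indrow("p1")
  v <- lpv("p1", "SLC34A3", 1L, chrom = "9")
  dx <- diagnoseCohort(v, inds, panel)
  expect_true(dx$strong_risk_factor)
  demoted <- panel@genes
  demoted$monoallelic_demoted[demoted$symbol == "SLC34A3"] <- TRUE
  dx2 <- reclassifyStrongRisk(dx, GenePanel(demoted), v)
  expect_false(dx2$strong_risk_factor)
})

test_that("cohort counts partition the group and reproduce printed-style
          percentages", {
  n <- 701
  cats <- c(rep("biallelic_AR", 5), rep("biallelic_AD_AR", 6),
            "XLR_hemizygous", rep("monoallelic_AD", 16),
            rep("monoallelic_AD_AR", 41), rep("carrier_AR", 38),
            rep("VUS_carrier", 256), rep("LB_B_carrier", 143),
            rep("none", 195))
  dx <- data.frame(individual_id = sprintf("I%03d", seq_len(n)),
                   group = "KSF", sex = "M", category = cats,
                   monogenic_ksd = cats %in% c(
                     "biallelic_AR", "biallelic_AD_AR", "XLR_hemizygous",
                     "monoallelic_AD", "monoallelic_AD_AR"),
                   strong_risk_factor = FALSE, presumed = FALSE,
                   flagged_for_review = FALSE, supporting_variants = "",
                   stringsAsFactors = FALSE)
  cc <- cohortCounts(dx, "KSF")
  expect_equal(sum(cc$n), n)
  expect_equal(cc$n[cc$category == "carrier_AR"], 38)
  expect_equal(cc$pct[cc$category == "carrier_AR"], 5.4)
  biallelic <- sum(cc$n[grepl("^biallelic", cc$category)])
  expect_equal(roundHalfUp(100 * biallelic / n, 1), 1.6)
  # solve rates from the same composition
  expect_equal(solveRate(dx, "pre_reclassification"), 9.8)
  dx$strong_risk_factor <- c(rep(TRUE, 48), rep(FALSE, n - 48))
  expect_equal(solveRate(dx, "post_reclassification"), 6.8)
  # degenerate inputs
  empty <- dx[0, ]
  expect_equal(sum(cohortCounts(empty, "KSF")$n), 0)
  expect_equal(solveRate(empty), 0)
  expect_error(cohortCounts(rbind(dx, dx[1, ])), "duplicate")
})

test_that("diagnosis results survive a serialization round trip", {
  inds <- rbind(indrow("r1"), indrow("r2", sex = "F", group = "NKSF"))
  v <- rbind(lpv("r1", "SLC34A3", 1L, chrom = "9"),
             lpv("r2", "AGXT", 2L, chrom = "2"))
  dx <- diagnoseCohort(v, inds, panel)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeDiagnoses(dx, path)
  back <- readDiagnoses(path)
  expect_equal(back$category, dx$category)
  expect_equal(cohortCounts(back, "KSF"), cohortCounts(dx, "KSF"))
})
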