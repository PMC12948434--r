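panel <- defaultGenePanel()
cfg <- FilterConfig()

test_that("loading restricts to panel genes and tolerates empty input", {
  v <- vtab(vrow(gene = "SLC7A9"), vrow(gene = "AGXT", chrom = "2"),
            vrow(gene = "NOTAGENE", chrom = "5"))
  expect_warning(out <- loadVariants(v, panel), "NOTAGENE")
  expect_equal(sort(unique(out$gene)), c("AGXT", "SLC7A9"))

  empty <- loadVariants(data.frame(), panel)
  expect_equal(nrow(empty), 0)
  expect_silent(qualityFilter(empty, cfg))
})

test_that("loading validates genotype, coordinates and consequence values", {
  expect_error(loadVariants(vrow(genotype = "diploid"), panel), "genotype")
  expect_error(loadVariants(vrow(pos = 0L), panel), "pos")
  expect_error(loadVariants(vrow(consequence = "nonsense_vocab"), panel),
               "nonsense_vocab")
  expect_error(loadVariants(vrow(allele_fraction = 1.2), panel),
               "allele_fraction")
})

test_that("VCF ingestion decomposes multi-allelic sites, keeps 1-based
          coordinates and drops non-panel genes", {
  vcf <- system.file("extdata", "example_panel_variants.vcf",
                     package = "stoneRisk")
  expect_warning(v <- loadVariantsVcf(vcf, panel), "MADEUPGENE")
  # S1 carries 1/2 at the SLC7A9 site: two decomposed het records
  s1 <- v[v$individual_id == "S1" & v$gene == "SLC7A9", ]
  expect_equal(nrow(s1), 2)
  expect_setequal(s1$alt, c("T", "G"))
  expect_true(all(s1$genotype == "het"))
  expect_equal(unique(s1$pos), 1010101L)
  # hemizygous X call
  expect_equal(v$genotype[v$gene == "OCRL"], "hemi")
  # whitelisted deep-intronic record survives the whole cascade
  expect_warning(out <- runFilterCascade(vcf, panel, cfg, nIndividuals = 50),
                 "MADEUPGENE")
  expect_true("SLC34A3" %in% out$variants$gene)
})

test_that("quality filter removes low-quality and low-allele-fraction
          sites for all carriers", {
  lowq <- vrow(id = "A", pos = 10L, site_quality = 24)
  boundary <- vrow(id = "A", pos = 20L, site_quality = 25)
  # 7 of 10 carriers below 0.3 allele fraction -> 0.7 > 0.6 -> removed
  manyLow <- do.call(rbind, lapply(1:10, function(i)
    vrow(id = paste0("C", i), pos = 30L,
         allele_fraction = if (i <= 7) 0.2 else 0.5)))
  # 6 of 10 low -> 0.6, not > 0.6 -> retained
  atBoundary <- do.call(rbind, lapply(1:10, function(i)
    vrow(id = paste0("C", i), pos = 40L,
         allele_fraction = if (i <= 6) 0.2 else 0.5)))
  out <- qualityFilter(rbind(lowq, boundary, manyLow, atBoundary), cfg)
  expect_setequal(unique(out$pos), c(20L, 40L))
})

test_that("cohort frequency filter uses a strict 10% carrier threshold", {
  mk <- function(pos, n) do.call(rbind, lapply(seq_len(n), function(i)
    vrow(id = paste0("I", i), pos = pos)))
  over <- mk(1L, 71)    # 71/701 = 10.13% -> removed
  under <- mk(2L, 70)   # 70/701 = 9.99% -> retained
  out <- cohortFrequencyFilter(rbind(over, under), cfg, nIndividuals = 701)
  expect_equal(unique(out$pos), 2L)
  # degenerate single-individual cohort: 1/1 = 100% -> removed
  expect_equal(nrow(cohortFrequencyFilter(vrow(), cfg, nIndividuals = 1)), 0)
  expect_error(cohortFrequencyFilter(vrow(), cfg, nIndividuals = 0),
               "nIndividuals")
})

test_that("population frequency filter: strict 1% cut, missing AF rare,
          whitelist exempt", {
  v <- vtab(vrow(pos = 1L, gnomad_af = 0.02),
            vrow(pos = 2L, gnomad_af = NA),
            vrow(pos = 3L, gnomad_af = 0.01),
            vrow(pos = 4L, gnomad_af = 0.5, consequence = "intronic",
                 splice_distance_bp = 30L, whitelist = TRUE))
  out <- populationFrequencyFilter(v, cfg)
  expect_setequal(out$pos, c(2L, 3L, 4L))
})

test_that("consequence filter keeps nonsynonymous coding, canonical and
          windowed splice, whitelisted intronic", {
  v <- vtab(vrow(pos = 1L, consequence = "missense"),
            vrow(pos = 2L, consequence = "synonymous"),
            vrow(pos = 3L, consequence = "intronic",
                 splice_distance_bp = 25L, whitelist = TRUE),
            vrow(pos = 4L, consequence = "intronic",
                 splice_distance_bp = 25L),
            vrow(pos = 5L, consequence = "splice_region",
                 splice_distance_bp = 10L),
            vrow(pos = 6L, consequence = "splice_region",
                 splice_distance_bp = 11L),
            vrow(pos = 7L, consequence = "canonical_splice",
                 splice_distance_bp = 2L))
  out <- consequenceFilter(v, cfg)
  expect_setequal(out$pos, c(1L, 3L, 5L, 7L))
  expect_error(consequenceFilter(vrow(consequence = "weird"), cfg), "weird")
})

test_that("cascade attributes removals to the first failing stage and
          conserves counts", {
  v <- vtab(
    vrow(id = "A", pos = 1L),                                   # passes
    vrow(id = "A", pos = 2L, site_quality = 10),                # quality
    vrow(id = "A", pos = 3L, gnomad_af = 0.05),                 # population
    vrow(id = "A", pos = 4L, consequence = "synonymous"),       # consequence
    # fails both quality and population: attributed to quality
    vrow(id = "A", pos = 5L, site_quality = 5, gnomad_af = 0.9))
  shared <- do.call(rbind, lapply(1:3, function(i)                # cohort
    vrow(id = paste0("B", i), pos = 6L)))
  res <- runFilterCascade(rbind(v, shared), panel, cfg, nIndividuals = 10)
  expect_equal(unname(removedPerStage(res$report)),
               c(2L, 3L, 1L, 1L))
  expect_equal(res$report@nIn,
               res$report@nOut + sum(removedPerStage(res$report)))
  expect_equal(res$variants$pos, 1L)

  allPass <- vtab(vrow(pos = 1L), vrow(pos = 2L, id = "B"))
  res2 <- runFilterCascade(allPass, panel, cfg, nIndividuals = 10)
  expect_equal(res2$variants[, names(allPass)], allPass,
               ignore_attr = TRUE)
  expect_true(all(removedPerStage(res2$report) == 0))

  res3 <- runFilterCascade(vrow(site_quality = 1), panel, cfg,
                           nIndividuals = 1)
  expect_equal(nrow(res3$variants), 0)
})

test_that("filters are idempotent, subset-monotone, and independent stages
          commute", {
  set.seed(42)
  v <- do.call(rbind, lapply(1:120, function(i)
    vrow(id = sprintf("I%d", sample(30, 1)), pos = sample(40L, 1),
         site_quality = sample(c(10, 30, 60), 1),
         allele_fraction = runif(1, 0.1, 0.9),
         gnomad_af = sample(c(NA, 0.001, 0.05), 1),
         consequence = sample(c("missense", "synonymous", "splice_region",
                                "intronic"), 1),
         splice_distance_bp = sample(0:30, 1))))
  n <- 30
  for (f in list(qualityFilter, cohortFrequencyFilter,
                 populationFrequencyFilter, consequenceFilter)) {
    once <- f(v, cfg, nIndividuals = n)
    expect_true(nrow(once) <= nrow(v))
    expect_true(all(.rowkey(once) %in% .rowkey(v)))
    expect_equal(f(once, cfg, nIndividuals = n), once)  # idempotent
  }
  # population-frequency and consequence commute (record-level predicates)
  ab <- consequenceFilter(populationFrequencyFilter(v, cfg), cfg)
  ba <- populationFrequencyFilter(consequenceFilter(v, cfg), cfg)
  expect_equal(ab[order(.rowkey(ab)), ], ba[order(.rowkey(ba)), ],
               ignore_attr = TRUE)
  # quality and cohort-frequency commute (independent site-level predicates)
  ab <- cohortFrequencyFilter(qualityFilter(v, cfg), cfg, n)
  ba <- qualityFilter(cohortFrequencyFilter(v, cfg, n), cfg)
  expect_equal(ab[order(.rowkey(ab)), ], ba[order(.rowkey(ba)), ],
               ignore_attr = TRUE)
})
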