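#' Synthetic cohort configuration
#'
#' Configuration of the synthetic stone-former cohort generator. The
#' defaults emulate the study composition: 701 stone formers (KSF) and 200
#' non-stone-formers (NKSF); the planted LP/P findings reproduce the
#' internally consistent published category counts (11 biallelic, 1 XLR
#' hemizygote, 57 monoallelic AD / AD-AR individuals, 38 AR carriers among
#' KSFs; demotion of monoallelic SLC9A3R1 / SLC34A1 / CYP24A1 and the
#' SLC7A9 p.(Ala182Thr) allele leaves 48 strong-risk individuals);
#' genotype-conditional biochemical shifts are configured in SD units on
#' the log scale with study-anchored directions; and the recurrence process
#' is exponential with a true hazard ratio of 2.4506 for the strong-risk
#' group and administrative censoring at 1095 days.
#'
#' @slot nKsf,nNksf group sizes (defaults 701 / 200).
#' @slot seed integer RNG seed; identical configurations generate
#'   byte-identical fixture bundles.
#' @slot plan data.frame of planted LP/P findings: \code{group},
#'   \code{gene}, \code{kind} (\code{hom}, \code{ch_trans},
#'   \code{ch_presumed}, \code{hemi}, \code{mono}), \code{n},
#'   \code{allele} (fixed protein allele or \code{NA}),
#'   \code{extra_gene} (additional monoallelic LP/P finding or \code{NA}).
#' @slot nVus,nLbb named integer vectors (\code{KSF}, \code{NKSF}) of
#'   VUS-only and LB/B-only carriers; remaining individuals carry no
#'   variant.
#' @slot effectSizes named list mapping biochemistry effect class to a
#'   named vector of log-scale shifts in SD units.
#' @slot trueHR hazard ratio of the strong-risk group (default 2.4506).
#' @slot baselineHazard events/day in the non-strong group (default
#'   chosen so ~30\% of controls recur within 3 years).
#' @slot censorDays administrative censoring horizon (default 1095).
#' @slot nRecurrenceControls non-strong KSFs with complete follow-up
#'   entering the recurrence analysis (default 302).
#' @slot multiRecurrence integer vector \code{c(strong, other)}: planted
#'   counts of individuals with more than one recurrence (default 5, 7).
#' @seealso [simulateCohort()], [writeFixtureBundle()]
#' @export
setClass("SimConfig",
  representation(nKsf = "integer", nNksf = "integer", seed = "integer",
                 plan = "data.frame", nVus = "integer", nLbb = "integer",
                 effectSizes = "list", trueHR = "numeric",
                 baselineHazard = "numeric", censorDays = "integer",
                 nRecurrenceControls = "integer",
                 multiRecurrence = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nKsf < 0 || object@nNksf < 0)
    msgs <- c(msgs, "group sizes must be nonnegative")
  if (object@censorDays <= 0)
    msgs <- c(msgs, "censorDays must be > 0 (a zero horizon censors every record at time 0)")
  if (object@trueHR <= 0 || object@baselineHazard <= 0)
    msgs <- c(msgs, "hazards must be > 0")
  for (g in c("KSF", "NKSF")) {
    p <- object@plan[object@plan$group == g, , drop = FALSE]
    tot <- sum(p$n) + object@nVus[[g]] + object@nLbb[[g]]
    size <- if (g == "KSF") object@nKsf else object@nNksf
    if (tot > size)
      msgs <- c(msgs, sprintf(
        "infeasible %s plan: %d planted individuals exceed group size %d",
        g, tot, size))
  }
  if (length(object@multiRecurrence) != 2)
    msgs <- c(msgs, "multiRecurrence must have two entries (strong, other)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d KSF + %d NKSF, seed %d\n",
              object@nKsf, object@nNksf, object@seed))
  cat(sprintf("  planted LP/P findings: %d KSF, %d NKSF individuals\n",
              sum(object@plan$n[object@plan$group == "KSF"]),
              sum(object@plan$n[object@plan$group == "NKSF"])))
  cat(sprintf("  recurrence: true HR %.4f, baseline %.3g/day, censor %d d\n",
              object@trueHR, object@baselineHazard, object@censorDays))
})

#' Default planted-findings plan and effect sizes
#'
#' \code{defaultPlan()} returns the study-composition plan of planted LP/P
#' findings (see [SimConfig-class]); \code{defaultEffectSizes()} the
#' default genotype-conditional biochemistry shifts in SD units on the log
#' scale (signs anchored to the reported effect directions, magnitudes are
#' generator configuration).
#'
#' @return \code{defaultPlan()}: data.frame; \code{defaultEffectSizes()}:
#'   named list of named numeric vectors.
#' @export
defaultPlan <- function() {
  p <- function(group, gene, kind, n, allele = NA, extra = NA)
    data.frame(group = group, gene = gene, kind = kind, n = n,
               allele = allele, extra_gene = extra, stringsAsFactors = FALSE)
  rbind(
    # KSF biallelic: 11 individuals
    p("KSF", "SLC3A1", "hom", 3),
    p("KSF", "SLC3A1", "ch_trans", 1),
    p("KSF", "SLC3A1", "ch_presumed", 1),
    # one biallelic SLC7A9 individual also carries monoallelic SLC9A3R1
    p("KSF", "SLC7A9", "ch_trans", 1, extra = "SLC9A3R1"),
    p("KSF", "SLC7A9", "ch_trans", 1),
    p("KSF", "SLC7A9", "ch_presumed", 2),
    p("KSF", "CYP24A1", "hom", 2),
    # KSF X-linked
    p("KSF", "OCRL", "hemi", 1),
    # KSF monoallelic AD_AR: 41 individuals
    p("KSF", "SLC7A9", "mono", 5, allele = "p.(Ala182Thr)"),
    p("KSF", "SLC7A9", "mono", 4),
    p("KSF", "SLC34A3", "mono", 9),
    p("KSF", "SLC34A1", "mono", 3),
    p("KSF", "CYP24A1", "mono", 8),
    p("KSF", "ALPL", "mono", 8),
    p("KSF", "SLC4A1", "mono", 4),
    # KSF monoallelic AD: 16 individuals
    p("KSF", "SLC9A3R1", "mono", 5, allele = "p.(Arg153Gln)"),
    p("KSF", "CASR", "mono", 6),
    p("KSF", "ADCY10", "mono", 5),
    # KSF AR carriers: 38 individuals
    p("KSF", "SLC3A1", "carrier", 15),
    p("KSF", "AGXT", "carrier", 8),
    p("KSF", "GRHPR", "carrier", 6),
    p("KSF", "CLDN16", "carrier", 5),
    p("KSF", "APRT", "carrier", 4),
    # NKSF monoallelic: 11 individuals (one with findings in two genes)
    p("NKSF", "SLC7A9", "mono", 3),
    p("NKSF", "SLC7A9", "mono", 1, allele = "p.(Ala182Thr)"),
    p("NKSF", "SLC9A3R1", "mono", 2, allele = "p.(Arg153Gln)"),
    p("NKSF", "SLC9A3R1", "mono", 1, allele = "p.(Arg153Gln)",
      extra = "SLC7A9"),
    p("NKSF", "CYP24A1", "mono", 2),
    p("NKSF", "SLC34A1", "mono", 2),
    # NKSF AR carriers: 7 individuals
    p("NKSF", "SLC3A1", "carrier", 2),
    p("NKSF", "AGXT", "carrier", 3),
    p("NKSF", "GRHPR", "carrier", 2))
}

#' @rdname defaultPlan
#' @export
defaultEffectSizes <- function() {
  list(
    slc34a3_monoallelic = c(plasma_phosphate = -1.0, urine_phosphate = 1.0,
                            urine_calcium = 1.0),
    cystinuria_biallelic = c(cystine = 6.0, ornithine = 4.0, lysine = 4.0,
                             arginine = 4.0),
    slc7a9_monoallelic = c(cystine = 1.5))
}

#' Construct a SimConfig
#'
#' @param nKsf,nNksf group sizes.
#' @param seed integer seed.
#' @param plan planted-findings data.frame (see [SimConfig-class]); the
#'   default reproduces the study composition.
#' @param nVus,nLbb named integer vectors (\code{KSF}, \code{NKSF}).
#' @param effectSizes named list of biochemistry shifts (SD units).
#' @param trueHR,baselineHazard,censorDays recurrence process parameters.
#' @param nRecurrenceControls,multiRecurrence recurrence analysis subset
#'   and planted multi-recurrence counts.
#' @return a validated [SimConfig-class].
#' @examples
#' SimConfig(seed = 1)
#' @export
SimConfig <- function(nKsf = 701L, nNksf = 200L, seed = 1L,
                      plan = defaultPlan(),
                      nVus = c(KSF = 256L, NKSF = 90L),
                      nLbb = c(KSF = 143L, NKSF = 34L),
                      effectSizes = defaultEffectSizes(),
                      trueHR = 2.4506,
                      baselineHazard = -log(0.7) / 1095,
                      censorDays = 1095L,
                      nRecurrenceControls = 302L,
                      multiRecurrence = c(strong = 5L, other = 7L)) {
  new("SimConfig", nKsf = as.integer(nKsf), nNksf = as.integer(nNksf),
      seed = as.integer(seed), plan = plan,
      nVus = vapply(nVus, as.integer, integer(1)),
      nLbb = vapply(nLbb, as.integer, integer(1)),
      effectSizes = effectSizes, trueHR = trueHR,
      baselineHazard = baselineHazard, censorDays = as.integer(censorDays),
      nRecurrenceControls = as.integer(nRecurrenceControls),
      multiRecurrence = vapply(multiRecurrence, as.integer, integer(1)))
}

# deterministic amino-acid letters for invented protein alleles
.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Val")

# allele registry: recurrent alleles (fixed hgvs_p) share one site across
# carriers; novel alleles get fresh sites
.newAlleleRegistry <- function(panel) {
  reg <- new.env(parent = emptyenv())
  reg$chrom <- structure(panel@genes$chrom, names = panel@genes$symbol)
  reg$sites <- list()
  reg
}

.alleleSite <- function(reg, gene, hgvs) {
  key <- paste0(gene, ":", hgvs)
  if (!is.null(reg$sites[[key]])) return(reg$sites[[key]])
  chrom <- unname(reg$chrom[[gene]])
  repeat {
    pos <- sample.int(2e6, 1) + 1e6
    probe <- paste0(chrom, "@", pos)
    if (is.null(reg$sites[[probe]])) break
  }
  site <- list(chrom = chrom, pos = pos,
               ref = sample(c("A", "C", "G", "T"), 1))
  site$alt <- sample(setdiff(c("A", "C", "G", "T"), site$ref), 1)
  reg$sites[[key]] <- site
  reg$sites[[probe]] <- site
  site
}

.randomHgvs <- function() {
  sprintf("p.(%s%d%s)", sample(.AA3, 1), sample.int(900, 1) + 20,
          sample(.AA3, 1))
}

# one variant record; evidence determines the class the classifier returns
.mkVariant <- function(reg, id, gene, genotype, hgvs, evidence) {
  site <- .alleleSite(reg, gene, hgvs)
  data.frame(
    individual_id = id, gene = gene, chrom = site$chrom, pos = site$pos,
    ref = site$ref, alt = site$alt, genotype = genotype,
    allele_fraction = if (genotype == "het") round(stats::runif(1, .38, .58), 3)
                      else round(stats::runif(1, .92, 1), 3),
    site_quality = round(stats::runif(1, 40, 95), 1),
    consequence = "missense", splice_distance_bp = 0L,
    gnomad_af = if (stats::runif(1) < 0.4) NA_real_
                else signif(stats::runif(1, 1e-6, 5e-3), 3),
    whitelist_pathogenic_intronic = FALSE, hgvs_p = hgvs,
    evidence_codes = evidence, stringsAsFactors = FALSE)
}

.EV_LP <- "PVS1,PM2"
.EV_P <- "PVS1,PS3,PM2"
.EV_VUS <- "PM2,PP3"
.EV_LB <- "BP4,BP7"
.EV_B <- "BS1,BS2"

# biochemistry effect class of a planted finding
.effectClass <- function(gene, kind, allele) {
  if (gene %in% c("SLC3A1", "SLC7A9") &&
      kind %in% c("hom", "ch_trans", "ch_presumed"))
    return("cystinuria_biallelic")
  if (gene == "SLC7A9" && kind == "mono") {
    if (identical(allele, "p.(Ala182Thr)")) return("none")
    return("slc7a9_monoallelic")
  }
  if (gene == "SLC34A3" && kind == "mono") return("slc34a3_monoallelic")
  "none"
}

#' Generate synthetic genotypes with ground truth
#'
#' Emits one individual table, one annotated variant table (with ACMG
#' evidence codes chosen so the classifier reproduces the intended class),
#' a phase-evidence table for compound heterozygotes, and the planted
#' ground truth. All planted variants are constructed to survive the
#' filter cascade (good quality, rare, nonsynonymous coding), so
#' filter-classify-diagnose recovers the planted categories exactly.
#'
#' @param config a [SimConfig-class].
#' @param panel a [GenePanel-class].
#' @return list \code{individuals}, \code{variants}, \code{phase},
#'   \code{truth} (one row per individual: planted \code{category},
#'   \code{strong_risk_factor}, \code{biochem_class}).
#' @export
simulateGenotypes <- function(config, panel = defaultGenePanel()) {
  validObject(config)
  set.seed(config@seed)
  reg <- .newAlleleRegistry(panel)
  inh <- inheritanceMode(panel)

  mkIds <- function(prefix, n) sprintf("SIM_%s_%04d", prefix, seq_len(n))
  individuals <- rbind(
    data.frame(individual_id = mkIds("KSF", config@nKsf), group = "KSF",
               sex = sample(c("M", "F"), config@nKsf, TRUE, c(0.65, 0.35)),
               age = round(pmax(18, stats::rnorm(config@nKsf, 53, 14))),
               stringsAsFactors = FALSE),
    data.frame(individual_id = mkIds("NKSF", config@nNksf), group = "NKSF",
               sex = sample(c("M", "F"), config@nNksf, TRUE, c(0.55, 0.45)),
               age = round(pmax(18, stats::rnorm(config@nNksf, 46, 13))),
               stringsAsFactors = FALSE))

  variants <- list(); phase <- list()
  truth <- data.frame(individual_id = individuals$individual_id,
                      group = individuals$group,
                      category = "none", strong_risk_factor = FALSE,
                      biochem_class = "none", stringsAsFactors = FALSE)
  cursor <- c(KSF = 0L, NKSF = 0L)
  nextId <- function(group) {
    cursor[[group]] <<- cursor[[group]] + 1L
    individuals$individual_id[individuals$group == group][cursor[[group]]]
  }
  setTruth <- function(id, category, strong, bclass) {
    i <- match(id, truth$individual_id)
    truth$category[i] <<- category
    truth$strong_risk_factor[i] <<- strong
    truth$biochem_class[i] <<- bclass
  }
  addVariant <- function(...) variants[[length(variants) + 1L]] <<-
    .mkVariant(reg, ...)

  plantMono <- function(id, gene, allele) {
    hgvs <- if (is.na(allele)) .randomHgvs() else allele
    addVariant(id, gene, "het", hgvs, .EV_LP)
    hgvs
  }

  plan <- config@plan
  for (r in seq_len(nrow(plan))) {
    row <- plan[r, ]
    for (k in seq_len(row$n)) {
      id <- nextId(row$group)
      gene <- row$gene
      mode <- unname(inh[gene])
      kind <- row$kind
      if (kind == "hom") {
        addVariant(id, gene, "hom_alt", .randomHgvs(), .EV_P)
        cat_ <- if (mode == "AR") "biallelic_AR" else "biallelic_AD_AR"
        setTruth(id, cat_, TRUE, .effectClass(gene, kind, row$allele))
      } else if (kind %in% c("ch_trans", "ch_presumed")) {
        addVariant(id, gene, "het", .randomHgvs(), .EV_LP)
        addVariant(id, gene, "het", .randomHgvs(), .EV_LP)
        phase[[length(phase) + 1L]] <- data.frame(
          individual_id = id, gene = gene,
          phase = if (kind == "ch_trans") "trans_by_reads" else "unknown",
          stringsAsFactors = FALSE)
        cat_ <- if (mode == "AR") "biallelic_AR" else "biallelic_AD_AR"
        setTruth(id, cat_, TRUE, .effectClass(gene, kind, row$allele))
      } else if (kind == "hemi") {
        individuals$sex[individuals$individual_id == id] <- "M"
        addVariant(id, gene, "hemi", .randomHgvs(), .EV_LP)
        setTruth(id, "XLR_hemizygous", TRUE, "none")
      } else if (kind == "mono") {
        hgvs <- plantMono(id, gene, row$allele)
        cat_ <- if (mode == "AD") "monoallelic_AD" else "monoallelic_AD_AR"
        demoted <- unname(isDemotedGene(panel, gene)) ||
          paste0(gene, ":", hgvs) %in% demotedAlleles(panel)
        setTruth(id, cat_, !demoted, .effectClass(gene, kind, row$allele))
      } else if (kind == "carrier") {
        plantMono(id, gene, row$allele)
        setTruth(id, "carrier_AR", FALSE, "none")
      } else {
        .err("unknown plan kind: %s", kind)
      }
      if (!is.na(row$extra_gene)) {
        # additional monoallelic LP/P finding; category precedence keeps
        # the primary finding on top, bar view lists both
        exAllele <- if (row$extra_gene == "SLC9A3R1") "p.(Arg153Gln)"
                    else NA
        plantMono(id, row$extra_gene, exAllele)
        if (kind == "mono" && !truth$strong_risk_factor[
              match(id, truth$individual_id)]) {
          exDem <- unname(isDemotedGene(panel, row$extra_gene))
          if (!exDem) truth$strong_risk_factor[
            match(id, truth$individual_id)] <- TRUE
        }
      }
    }
  }
  for (g in c("KSF", "NKSF")) {
    for (k in seq_len(config@nVus[[g]])) {
      id <- nextId(g)
      addVariant(id, sample(panelGenes(panel), 1), "het", .randomHgvs(),
                 .EV_VUS)
      setTruth(id, "VUS_carrier", FALSE, "none")
    }
    for (k in seq_len(config@nLbb[[g]])) {
      id <- nextId(g)
      addVariant(id, sample(panelGenes(panel), 1), "het", .randomHgvs(),
                 if (k %% 3 == 0) .EV_B else .EV_LB)
      setTruth(id, "LB_B_carrier", FALSE, "none")
    }
  }

  variants <- do.call(rbind, variants)
  if (is.null(variants)) {
    variants <- data.frame()
    variants <- loadVariants(variants, panel)
    variants$evidence_codes <- character(0)
  }
  phase <- if (length(phase)) do.call(rbind, phase) else
    data.frame(individual_id = character(), gene = character(),
               phase = character(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(individuals = individuals, variants = variants, phase = phase,
       truth = truth)
}

# analyte generation parameters: log-normal inside the reference range
.analyteParams <- function() {
  rr <- defaultReferenceRanges()
  analytes <- setdiff(names(rr), "urine_ph")
  params <- lapply(analytes, function(a) {
    lo <- max(rr[[a]][["low"]], 1e-3)
    hi <- rr[[a]][["high"]]
    list(meanlog = (log(lo) + log(hi)) / 2, sdlog = (log(hi) - log(lo)) / 4)
  })
  names(params) <- analytes
  params
}

#' Generate per-visit biochemistry with genotype-conditional shifts
#'
#' Log-normal analyte values centred inside adult reference ranges with a
#' per-individual random intercept (within-individual correlation across
#' visits) and genotype-conditional shifts, in SD units on the log scale,
#' per the configured effect classes. Stone formers get 7 visits, controls
#' one.
#'
#' @param genotypes output of [simulateGenotypes()].
#' @param config a [SimConfig-class].
#' @return data.frame in the [deriveBiochem()] visit schema.
#' @export
simulateBiochem <- function(genotypes, config) {
  set.seed(config@seed + 1L)
  params <- .analyteParams()
  rr <- defaultReferenceRanges()
  ind <- genotypes$individuals
  bclass <- genotypes$truth$biochem_class[
    match(ind$individual_id, genotypes$truth$individual_id)]
  out <- vector("list", nrow(ind))
  for (i in seq_len(nrow(ind))) {
    nVisits <- if (ind$group[i] == "KSF") 7L else 1L
    shifts <- config@effectSizes[[bclass[i]]]
    rows <- data.frame(individual_id = ind$individual_id[i],
                       visit = paste0("V", seq_len(nVisits)),
                       stringsAsFactors = FALSE)
    for (a in names(params)) {
      p <- params[[a]]
      shift <- if (!is.null(shifts) && a %in% names(shifts))
        shifts[[a]] * p$sdlog else 0
      intercept <- stats::rnorm(1, p$meanlog + shift, 0.8 * p$sdlog)
      rows[[a]] <- exp(stats::rnorm(nVisits, intercept, 0.6 * p$sdlog))
    }
    phMid <- mean(rr$urine_ph)
    phInt <- stats::rnorm(1, phMid, 0.35)
    rows$urine_ph <- pmin(pmax(stats::rnorm(nVisits, phInt, 0.25), 4.5), 8)
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate stone-recurrence survival records
#'
#' Exponential time to first recurrence with the configured hazard ratio
#' multiplying the baseline hazard for strong-risk individuals,
#' administrative censoring at the configured horizon, and planted
#' multi-recurrence counts among individuals with an observed event. The
#' analysis subset is every strong-risk stone former plus the configured
#' number of non-strong stone formers with complete follow-up.
#'
#' @param genotypes output of [simulateGenotypes()] (uses the planted
#'   strong-risk ground truth).
#' @param config a [SimConfig-class].
#' @return data.frame with \code{individual_id}, \code{time_days},
#'   \code{event}, \code{n_recurrences}, \code{age}, \code{sex},
#'   \code{strong_risk_factor}.
#' @export
simulateRecurrence <- function(genotypes, config) {
  validObject(config)
  set.seed(config@seed + 2L)
  ind <- genotypes$individuals
  truth <- genotypes$truth
  ksf <- ind[ind$group == "KSF", , drop = FALSE]
  strong <- truth$strong_risk_factor[
    match(ksf$individual_id, truth$individual_id)]
  ids <- c(ksf$individual_id[strong],
           sample(ksf$individual_id[!strong],
                  min(config@nRecurrenceControls, sum(!strong))))
  sel <- match(ids, ksf$individual_id)
  isStrong <- strong[sel]
  hazard <- config@baselineHazard * ifelse(isStrong, config@trueHR, 1)
  tEvent <- stats::rexp(length(ids), hazard)
  event <- tEvent <= config@censorDays
  rec <- data.frame(
    individual_id = ids,
    time_days = pmin(tEvent, config@censorDays),
    event = event,
    n_recurrences = as.integer(event),
    age = ksf$age[sel], sex = ksf$sex[sel],
    strong_risk_factor = isStrong, stringsAsFactors = FALSE)
  # plant multi-recurrence individuals among those with an observed event
  for (side in c(TRUE, FALSE)) {
    want <- config@multiRecurrence[[if (side) 1L else 2L]]
    pool <- which(rec$strong_risk_factor == side & rec$event)
    if (length(pool) < want)
      .err("cannot plant %d multi-recurrence individuals among %d events",
           want, length(pool))
    rec$n_recurrences[pool[seq_len(want)]] <- 2L
  }
  rec
}

#' Generate the complete synthetic cohort
#'
#' Convenience wrapper chaining [simulateGenotypes()],
#' [simulateBiochem()] and [simulateRecurrence()].
#'
#' @param config a [SimConfig-class].
#' @param panel a [GenePanel-class].
#' @return list \code{individuals}, \code{variants}, \code{phase},
#'   \code{truth}, \code{biochem}, \code{survival}, \code{panel},
#'   \code{config}.
#' @examples
#' sim <- simulateCohort(SimConfig(seed = 7, nKsf = 50L, nNksf = 20L,
#'                                 plan = defaultPlan()[0, ],
#'                                 nVus = c(KSF = 5L, NKSF = 2L),
#'                                 nLbb = c(KSF = 5L, NKSF = 2L),
#'                                 nRecurrenceControls = 40L,
#'                                 multiRecurrence = c(0L, 0L)))
#' @export
simulateCohort <- function(config = SimConfig(), panel = defaultGenePanel()) {
  g <- simulateGenotypes(config, panel)
  list(individuals = g$individuals, variants = g$variants,
       phase = g$phase, truth = g$truth,
       biochem = simulateBiochem(g, config),
       survival = simulateRecurrence(g, config),
       panel = panel, config = config)
}

#' Write a fixture bundle to disk
#'
#' Serializes a simulated cohort as plain-text files (variants, panel,
#' individuals, phase, biochemistry, survival TSVs) plus a JSON manifest
#' carrying the seed, the planted ground-truth category counts and file
#' checksums. Re-running with the same configuration is byte-identical.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory (created if needed).
#' @param panel a [GenePanel-class].
#' @return invisible character vector of written file paths.
#' @export
writeFixtureBundle <- function(config, outdir, panel = defaultGenePanel()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    .err("cannot create output directory %s", outdir)
  sim <- simulateCohort(config, panel)
  wt <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- c(wt(sim$variants, "variants.tsv"),
             wt(sim$individuals, "individuals.tsv"),
             wt(sim$phase, "phase.tsv"),
             wt(sim$truth, "truth.tsv"),
             wt(sim$biochem, "biochem.tsv"),
             wt(sim$survival, "survival.tsv"))
  files <- c(files, writeGenePanel(panel, file.path(outdir, "panel.tsv")))
  manifest <- list(
    seed = config@seed,
    n_ksf = config@nKsf, n_nksf = config@nNksf,
    truth_category_counts = as.list(table(
      sim$truth$category[sim$truth$group == "KSF"])),
    n_strong_risk_ksf = sum(sim$truth$strong_risk_factor[
      sim$truth$group == "KSF"]),
    md5 = as.list(tools::md5sum(files)))
  manifestPath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, manifestPath))
}

#' Read a fixture bundle written by [writeFixtureBundle()]
#'
#' @param dir bundle directory.
#' @return list \code{variants}, \code{individuals}, \code{phase},
#'   \code{truth}, \code{biochem}, \code{survival}, \code{panel},
#'   \code{manifest}.
#' @export
readFixtureBundle <- function(dir) {
  rd <- function(name) utils::read.delim(file.path(dir, name),
                                         stringsAsFactors = FALSE)
  list(variants = rd("variants.tsv"), individuals = rd("individuals.tsv"),
       phase = rd("phase.tsv"), truth = rd("truth.tsv"),
       biochem = rd("biochem.tsv"), survival = rd("survival.tsv"),
       panel = readGenePanel(file.path(dir, "panel.tsv")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}
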