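#' Diagnosis categories
#'
#' The mutually exclusive per-individual categories, in precedence order
#' (highest first): biallelic LP/P in an AR gene, biallelic LP/P in an
#' AD/AR gene, hemizygous LP/P in an XLR gene (males), monoallelic LP/P in
#' an AD gene, monoallelic LP/P in an AD/AR gene, heterozygous carrier of
#' an LP/P variant in an AR gene, VUS carrier, LB/B carrier, none.
#'
#' @return character vector of category names in precedence order.
#' @export
diagnosisCategories <- function() {
  c("biallelic_AR", "biallelic_AD_AR", "XLR_hemizygous", "monoallelic_AD",
    "monoallelic_AD_AR", "carrier_AR", "VUS_carrier", "LB_B_carrier",
    "none")
}

.MONOGENIC <- c("biallelic_AR", "biallelic_AD_AR", "XLR_hemizygous",
                "monoallelic_AD", "monoallelic_AD_AR")

#' Resolve biallelic status of LP/P variants within one gene
#'
#' Determines whether LP/P variants in one gene of one individual affect
#' both alleles. A homozygous variant is proven biallelic. Two
#' heterozygous variants proven in \emph{trans} by sequencing reads are
#' proven biallelic (compound heterozygous); proven in \emph{cis} they
#' count as a single allele; with unknown phase they are presumed
#' biallelic. Biochemical corroboration (e.g. dibasic aminoaciduria for
#' cystinuria genes) is recorded but does not change the category by
#' itself.
#'
#' @param genotypes character vector of genotypes (\code{het},
#'   \code{hom_alt}, \code{hemi}) of the LP/P variants in the gene.
#' @param phase \code{trans_by_reads}, \code{cis_by_reads} or
#'   \code{unknown}; used when two or more heterozygous variants are
#'   present.
#' @param biochemCorroboration logical or \code{NA}; recorded in the
#'   \code{corroborated} field of the result.
#' @return list with \code{status} (\code{biallelic_proven},
#'   \code{biallelic_presumed} or \code{monoallelic_only}),
#'   \code{corroborated}, and \code{flagged_for_review} (more than two
#'   LP/P heterozygous variants in one gene).
#' @examples
#' resolveBiallelic("hom_alt")$status                    # proven
#' resolveBiallelic(c("het", "het"), "unknown")$status   # presumed
#' resolveBiallelic(c("het", "het"), "cis_by_reads")$status
#' @export
resolveBiallelic <- function(genotypes, phase = "unknown",
                             biochemCorroboration = NA) {
  if (!length(genotypes)) .err("resolveBiallelic: no LP/P variants supplied")
  phase <- match.arg(phase, c("unknown", "trans_by_reads", "cis_by_reads"))
  nHet <- sum(genotypes == "het")
  status <- if (any(genotypes == "hom_alt")) {
    "biallelic_proven"
  } else if (nHet >= 2) {
    switch(phase,
           trans_by_reads = "biallelic_proven",
           cis_by_reads = "monoallelic_only",
           unknown = "biallelic_presumed")
  } else {
    "monoallelic_only"
  }
  list(status = status, corroborated = biochemCorroboration,
       flagged_for_review = nHet > 2)
}

# per-individual gene-level genotype summary used by category assignment
# and by the bar view; one row per (individual, gene) with LP/P variants,
# plus class aggregation over all variants
.geneLevelStatus <- function(vind, panel, phase) {
  lp <- vind[vind$acmg_class %in% c("LP", "P"), , drop = FALSE]
  if (nrow(lp) == 0) return(NULL)
  out <- lapply(split(lp, lp$gene), function(gv) {
    gene <- gv$gene[1]
    ph <- "unknown"
    if (!is.null(phase) && nrow(phase)) {
      hit <- phase$phase[phase$individual_id == gv$individual_id[1] &
                           phase$gene == gene]
      if (length(hit)) ph <- hit[1]
    }
    hemi <- any(gv$genotype == "hemi")
    rb <- resolveBiallelic(gv$genotype, ph)
    data.frame(gene = gene,
               inheritance = unname(inheritanceMode(panel, gene)),
               status = rb$status, hemi = hemi,
               presumed = rb$status == "biallelic_presumed",
               flagged = rb$flagged_for_review,
               alleles = paste(unique(paste0(gene, ":", gv$hgvs_p)),
                               collapse = ";"),
               n_lp = nrow(gv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# category contributed by one gene-level status row
.geneCategory <- function(row, sex) {
  inh <- row$inheritance
  if (inh == "XLR") {
    if (row$hemi && sex == "M") return("XLR_hemizygous")
    return("carrier_AR")  # X-linked heterozygous carrier
  }
  if (row$status %in% c("biallelic_proven", "biallelic_presumed")) {
    if (inh == "AR") return("biallelic_AR")
    if (inh == "AD_AR") return("biallelic_AD_AR")
    return("monoallelic_AD")  # biallelic in a pure-AD gene: dominant dx
  }
  switch(inh, AD = "monoallelic_AD", AD_AR = "monoallelic_AD_AR",
         AR = "carrier_AR")
}

#' Assign one diagnosis category per individual and reclassify
#'
#' Combines classified variants with gene inheritance modes to give every
#' individual exactly one category (the pie view), flags monogenic kidney
#' stone disease, and applies the biochemistry-driven reclassification that
#' demotes monoallelic LP/P variants in demoted genes (and individually
#' demoted alleles) from strong-risk-factor status. Biallelic and
#' hemizygous findings are never demoted.
#'
#' @param variants classified [variantTable] data.frame (with
#'   \code{acmg_class}), typically the filter cascade output after
#'   [classifyVariants()].
#' @param individuals data.frame with columns \code{individual_id},
#'   \code{sex} (\code{M}/\code{F}), \code{group} (\code{KSF}/\code{NKSF});
#'   individuals absent from \code{variants} get category \code{none}.
#' @param panel a [GenePanel-class].
#' @param phase optional data.frame \code{individual_id}, \code{gene},
#'   \code{phase} (\code{trans_by_reads}/\code{cis_by_reads}/
#'   \code{unknown}) for same-gene heterozygous pairs.
#' @return data.frame with one row per individual: \code{individual_id},
#'   \code{group}, \code{sex}, \code{category}, \code{monogenic_ksd},
#'   \code{strong_risk_factor}, \code{presumed}, \code{flagged_for_review},
#'   \code{supporting_variants}.
#' @seealso [cohortCounts()], [solveRate()], [geneBarView()]
#' @export
diagnoseCohort <- function(variants, individuals, panel, phase = NULL) {
  .checkCols(individuals, c("individual_id", "sex", "group"),
             "individuals table")
  if (anyDuplicated(individuals$individual_id))
    .err("duplicate individual_id in individuals table")
  if (nrow(variants) > 0)
    .checkCols(variants, c("acmg_class"), "classified variant table")
  vs <- if (nrow(variants)) split(variants, variants$individual_id) else list()

  res <- lapply(seq_len(nrow(individuals)), function(i) {
    id <- individuals$individual_id[i]
    sex <- individuals$sex[i]
    vind <- vs[[id]]
    base <- data.frame(individual_id = id, group = individuals$group[i],
                       sex = sex, category = "none", monogenic_ksd = FALSE,
                       strong_risk_factor = FALSE, presumed = FALSE,
                       flagged_for_review = FALSE,
                       supporting_variants = "",
                       stringsAsFactors = FALSE)
    if (is.null(vind) || nrow(vind) == 0) return(base)
    if (sex == "F" && any(vind$genotype == "hemi"))
      .err("hemizygous call in female individual %s", id)

    gl <- .geneLevelStatus(vind, panel, phase)
    if (!is.null(gl)) {
      gl$category <- vapply(seq_len(nrow(gl)),
                            function(j) .geneCategory(gl[j, ], sex),
                            character(1))
      gl$rank <- match(gl$category, diagnosisCategories())
      top <- gl[which.min(gl$rank), ]
      base$category <- top$category
      base$monogenic_ksd <- top$category %in% .MONOGENIC
      base$presumed <- top$presumed
      base$flagged_for_review <- any(gl$flagged)
      base$supporting_variants <- paste(gl$alleles, collapse = ";")
      base$strong_risk_factor <- .strongRisk(gl, panel)
      return(base)
    }
    agg <- aggregateIndividualClass(vind$acmg_class)
    base$category <- if (agg == "VUS") "VUS_carrier"
                     else if (agg %in% c("LB", "B")) "LB_B_carrier"
                     else "none"
    base$supporting_variants <- paste(
      unique(paste0(vind$gene, ":", vind$hgvs_p)), collapse = ";")
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# strong-risk decision over all gene-level monogenic supports: at least one
# support must survive demotion. Monoallelic support in a demoted gene is
# removed; monoallelic support whose only LP/P allele is an individually
# demoted allele is removed; biallelic / hemizygous supports always stand.
.strongRisk <- function(gl, panel) {
  sup <- gl[gl$category %in% .MONOGENIC, , drop = FALSE]
  if (nrow(sup) == 0) return(FALSE)
  demAll <- demotedAlleles(panel)
  survives <- vapply(seq_len(nrow(sup)), function(j) {
    row <- sup[j, ]
    if (row$status %in% c("biallelic_proven", "biallelic_presumed") ||
        row$hemi)
      return(TRUE)
    if (isTRUE(unname(isDemotedGene(panel, row$gene)))) return(FALSE)
    alleles <- strsplit(row$alleles, ";", fixed = TRUE)[[1]]
    if (row$n_lp == 1 && all(alleles %in% demAll)) return(FALSE)
    TRUE
  }, logical(1))
  any(survives)
}

#' Re-evaluate strong-risk flags on an existing diagnosis table
#'
#' @param diagnoses output of [diagnoseCohort()].
#' @param panel a [GenePanel-class] (possibly with changed demotion flags).
#' @param variants,phase the inputs used for the original diagnosis.
#' @return \code{diagnoses} with \code{strong_risk_factor} recomputed.
#' @export
reclassifyStrongRisk <- function(diagnoses, panel, variants, phase = NULL) {
  redo <- diagnoseCohort(variants,
                         diagnoses[, c("individual_id", "sex", "group")],
                         panel, phase)
  diagnoses$strong_risk_factor <-
    redo$strong_risk_factor[match(diagnoses$individual_id,
                                  redo$individual_id)]
  diagnoses
}

#' Cohort category counts and percentages
#'
#' One row per diagnosis category with count and percentage of the group
#' (half-up rounding to one decimal, the printed-table convention). The
#' counts partition the group: each individual appears exactly once.
#'
#' @param diagnoses output of [diagnoseCohort()].
#' @param group \code{KSF}, \code{NKSF}, or \code{NULL} for all rows.
#' @return data.frame \code{category}, \code{n}, \code{pct}.
#' @export
cohortCounts <- function(diagnoses, group = NULL) {
  if (anyDuplicated(diagnoses$individual_id))
    .err("duplicate individual_id in diagnosis table")
  d <- if (is.null(group)) diagnoses
       else diagnoses[diagnoses$group == group, , drop = FALSE]
  cats <- diagnosisCategories()
  n <- vapply(cats, function(k) sum(d$category == k), integer(1))
  data.frame(category = cats, n = unname(n),
             pct = unname(.pct1(n, nrow(d))),
             stringsAsFactors = FALSE)
}

#' Non-exclusive per-gene view of monogenic findings
#'
#' The bar-plot companion of the single-category pie: every (individual,
#' gene) monogenic finding is listed, so an individual with findings in two
#' genes appears twice.
#'
#' @inheritParams diagnoseCohort
#' @return data.frame \code{individual_id}, \code{group}, \code{gene},
#'   \code{inheritance}, \code{category}, \code{biallelic}.
#' @export
geneBarView <- function(variants, individuals, panel, phase = NULL) {
  .checkCols(individuals, c("individual_id", "sex", "group"),
             "individuals table")
  vs <- if (nrow(variants)) split(variants, variants$individual_id) else list()
  rows <- lapply(seq_len(nrow(individuals)), function(i) {
    id <- individuals$individual_id[i]
    vind <- vs[[id]]
    if (is.null(vind) || nrow(vind) == 0) return(NULL)
    gl <- .geneLevelStatus(vind, panel, phase)
    if (is.null(gl)) return(NULL)
    gl$category <- vapply(seq_len(nrow(gl)),
                          function(j) .geneCategory(gl[j, ],
                                                    individuals$sex[i]),
                          character(1))
    gl <- gl[gl$category %in% .MONOGENIC, , drop = FALSE]
    if (nrow(gl) == 0) return(NULL)
    data.frame(individual_id = id, group = individuals$group[i],
               gene = gl$gene, inheritance = gl$inheritance,
               category = gl$category,
               biallelic = gl$status %in%
                 c("biallelic_proven", "biallelic_presumed"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(individual_id = character(), group = character(),
                      gene = character(), inheritance = character(),
                      category = character(), biallelic = logical())
  rownames(out) <- NULL
  out
}

#' Monogenic solve rate
#'
#' Percentage of a group with a monogenic diagnosis.
#' \code{pre_reclassification} counts every monogenic category;
#' \code{post_reclassification} counts only individuals whose finding
#' survives demotion (the strong-risk-factor flag).
#'
#' @param diagnoses output of [diagnoseCohort()].
#' @param mode \code{"pre_reclassification"} or
#'   \code{"post_reclassification"}.
#' @param group group label, default \code{"KSF"}.
#' @return percentage, half-up rounded to one decimal.
#' @export
solveRate <- function(diagnoses,
                      mode = c("pre_reclassification",
                               "post_reclassification"),
                      group = "KSF") {
  mode <- match.arg(mode)
  d <- diagnoses[diagnoses$group == group, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  n <- if (mode == "pre_reclassification") sum(d$monogenic_ksd)
       else sum(d$strong_risk_factor)
  unname(.pct1(n, nrow(d)))
}

#' Serialize / reload diagnosis results (JSON lines)
#'
#' @param diagnoses output of [diagnoseCohort()].
#' @param path file path.
#' @return \code{writeDiagnoses}: \code{path} invisibly;
#'   \code{readDiagnoses}: the diagnosis data.frame.
#' @export
writeDiagnoses <- function(diagnoses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(diagnoses)))
    writeLines(jsonlite::toJSON(as.list(diagnoses[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

#' @rdname writeDiagnoses
#' @export
readDiagnoses <- function(path) {
  rows <- lapply(readLines(path), function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
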