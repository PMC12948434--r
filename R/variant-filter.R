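#' @name variantTable
#' @title The annotated variant table
#' @description
#' All filtering and diagnosis functions operate on a plain data.frame with
#' one row per variant call per individual ("annotated variant"):
#' \describe{
#'   \item{individual_id}{opaque sample identifier}
#'   \item{gene}{panel gene symbol}
#'   \item{chrom, pos, ref, alt}{1-based VCF-convention coordinates;
#'     variant identity across individuals is (chrom, pos, ref, alt)}
#'   \item{genotype}{\code{het}, \code{hom_alt} or \code{hemi}}
#'   \item{allele_fraction}{variant read fraction in [0,1]}
#'   \item{site_quality}{nonnegative call quality score}
#'   \item{consequence}{one of \code{missense}, \code{stop_gain},
#'     \code{frameshift}, \code{inframe_indel}, \code{canonical_splice},
#'     \code{splice_region}, \code{synonymous}, \code{intronic},
#'     \code{other}}
#'   \item{splice_distance_bp}{distance into the intron (0 for exonic)}
#'   \item{gnomad_af}{population allele frequency, \code{NA} when the
#'     variant is absent from gnomAD}
#'   \item{whitelist_pathogenic_intronic}{logical; intronic variant with
#'     established pathogenicity, exempt from frequency/consequence removal}
#'   \item{hgvs_p}{protein notation or \code{""}}
#'   \item{evidence_codes}{comma-separated ACMG/AMP codes (optional until
#'     classification)}
#' }
NULL

.CONSEQUENCES <- c("missense", "stop_gain", "frameshift", "inframe_indel",
                   "canonical_splice", "splice_region", "synonymous",
                   "intronic", "other")
.NONSYN_CODING <- c("missense", "stop_gain", "frameshift", "inframe_indel")

.VARIANT_COLS <- c("individual_id", "gene", "chrom", "pos", "ref", "alt",
                   "genotype", "allele_fraction", "site_quality",
                   "consequence", "splice_distance_bp", "gnomad_af",
                   "whitelist_pathogenic_intronic", "hgvs_p")

.validateVariants <- function(variants, what = "variant table") {
  .checkCols(variants, .VARIANT_COLS, what)
  badPos <- which(variants$pos < 1)
  if (length(badPos))
    .err("%s: pos must be >= 1 (row %d)", what, badPos[1L])
  af <- variants$allele_fraction
  if (any(!is.na(af) & (af < 0 | af > 1)))
    .err("%s: allele_fraction outside [0,1]", what)
  gaf <- variants$gnomad_af
  if (any(!is.na(gaf) & (gaf < 0 | gaf > 1)))
    .err("%s: gnomad_af outside [0,1]", what)
  badGt <- setdiff(unique(variants$genotype), c("het", "hom_alt", "hemi"))
  if (length(badGt))
    .err("%s: unknown genotype value(s): %s", what,
         paste(badGt, collapse = ", "))
  invisible(variants)
}

#' Load annotated variants and restrict to the gene panel
#'
#' Reads an annotated flat variant table (data.frame or TSV path) and keeps
#' only records in panel genes. Records whose \code{gene} is not on the
#' panel are dropped with a warning.
#'
#' @param source data.frame in the [variantTable] schema, or path to a TSV
#'   with those columns.
#' @param panel a [GenePanel-class].
#' @return panel-restricted variant data.frame.
#' @seealso [loadVariantsVcf()] for VCF input.
#' @export
loadVariants <- function(source, panel) {
  variants <- if (is.character(source)) {
    utils::read.delim(source, stringsAsFactors = FALSE)
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (nrow(variants) == 0) {
    for (col in setdiff(.VARIANT_COLS, names(variants)))
      variants[[col]] <- logical(0)
    return(variants)
  }
  .validateVariants(variants)
  badCons <- setdiff(unique(variants$consequence), .CONSEQUENCES)
  if (length(badCons))
    .err("unknown consequence value(s): %s (first offending row %d)",
         paste(badCons, collapse = ", "),
         which(variants$consequence %in% badCons)[1L])
  unknown <- setdiff(unique(variants$gene), panelGenes(panel))
  if (length(unknown)) {
    warning(sprintf("dropping %d record(s) in non-panel gene(s): %s",
                    sum(variants$gene %in% unknown),
                    paste(unknown, collapse = ", ")), call. = FALSE)
    variants <- variants[!variants$gene %in% unknown, , drop = FALSE]
  }
  rownames(variants) <- NULL
  variants
}

#' Load variants from a VCF into the annotated variant table
#'
#' Parses a VCF (v4.x, single- or multi-sample) whose INFO field carries the
#' annotations \code{GENE}, \code{CSQ} (consequence vocabulary of
#' [variantTable]), \code{SPLICE_DIST}, \code{GNOMAD_AF} and \code{WL}
#' (whitelisted pathogenic intronic, 0/1), with per-sample \code{GT} and
#' allele-fraction \code{AF} (or \code{AD}) FORMAT fields. Multi-allelic
#' records are decomposed into one row per alternate allele; coordinates are
#' kept 1-based.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param panel a [GenePanel-class].
#' @return panel-restricted variant data.frame in the [variantTable] schema.
#' @export
loadVariantsVcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(loadVariants(data.frame(), panel))
  info <- function(key) vcfR::extract.info(vcf, element = key)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  afm <- tryCatch(vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE),
                  error = function(e) NULL)
  samples <- colnames(gt)
  gene <- info("GENE")
  csq <- info("CSQ")
  sdist <- suppressWarnings(as.integer(info("SPLICE_DIST")))
  gaf <- suppressWarnings(as.numeric(info("GNOMAD_AF")))
  wl <- info("WL") %in% c("1", "TRUE")
  hgvs <- info("HGVSP")
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  out <- vector("list", nrow(fix) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      al <- strsplit(g, "[/|]")[[1]]
      al <- suppressWarnings(as.integer(al))
      al <- al[!is.na(al)]
      if (!length(al) || all(al == 0L)) next
      # one decomposed record per distinct carried alt allele
      for (a in unique(al[al > 0L])) {
        if (a > length(alts))
          .err("malformed VCF record at %s:%s — GT allele %d but %d ALT(s)",
               fix$CHROM[i], fix$POS[i], a, length(alts))
        gtype <- if (length(al) == 1L) "hemi"
                 else if (sum(al == a) == 2L) "hom_alt" else "het"
        k <- k + 1L
        out[[k]] <- data.frame(
          individual_id = s, gene = gene[i], chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[a],
          genotype = gtype,
          allele_fraction = if (!is.null(afm)) afm[i, s] else NA_real_,
          site_quality = qual[i], consequence = csq[i],
          splice_distance_bp = sdist[i], gnomad_af = gaf[i],
          whitelist_pathogenic_intronic = wl[i],
          hgvs_p = if (is.na(hgvs[i])) "" else hgvs[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- do.call(rbind, out[seq_len(k)])
  if (is.null(variants)) variants <- data.frame()
  loadVariants(variants, panel)
}

# per-site predicate evaluation used by the two site-level filters ----------

.qualityFailSites <- function(variants, cfg) {
  key <- .siteKey(variants)
  lowAf <- !is.na(variants$allele_fraction) &
    variants$allele_fraction < cfg@minAlleleFraction
  fracLow <- tapply(lowAf, key, mean)
  minQual <- tapply(variants$site_quality, key, min)
  names(which(fracLow > cfg@maxFractionLowAf | minQual < cfg@minQuality))
}

.cohortFailSites <- function(variants, cfg, nIndividuals) {
  key <- .siteKey(variants)
  carriers <- tapply(variants$individual_id, key,
                     function(x) length(unique(x)))
  names(which(carriers / nIndividuals > cfg@maxCohortCarrierFraction))
}

.popFailRecords <- function(variants, cfg) {
  !is.na(variants$gnomad_af) & variants$gnomad_af > cfg@maxGnomadAf &
    !variants$whitelist_pathogenic_intronic
}

.consequenceKeep <- function(variants, cfg) {
  cons <- variants$consequence
  bad <- setdiff(unique(cons), .CONSEQUENCES)
  if (length(bad))
    .err("unknown consequence value(s): %s (first offending row %d)",
         paste(bad, collapse = ", "), which(cons %in% bad)[1L])
  cons %in% .NONSYN_CODING |
    cons == "canonical_splice" |
    (cons == "splice_region" &
       variants$splice_distance_bp <= cfg@spliceWindowBp) |
    variants$whitelist_pathogenic_intronic
}

#' Quality filter: low allele fraction and low site quality
#'
#' A site (chrom, pos, ref, alt) is removed for \emph{all} carriers when
#' more than \code{maxFractionLowAf} of its carrier individuals have a
#' variant allele fraction below \code{minAlleleFraction}, or when its
#' quality score is below \code{minQuality}.
#'
#' @param variants [variantTable] data.frame.
#' @param config a [FilterConfig-class].
#' @param nIndividuals number of individuals in the cohort (unused by this
#'   stage; accepted for a uniform stage signature).
#' @return filtered subset of \code{variants}.
#' @export
qualityFilter <- function(variants, config = FilterConfig(),
                          nIndividuals = NULL) {
  if (nrow(variants) == 0) return(variants)
  fail <- .qualityFailSites(variants, config)
  out <- variants[!.siteKey(variants) %in% fail, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort frequency filter
#'
#' Removes sites carried by more than \code{maxCohortCarrierFraction}
#' (default 10\%) of cohort individuals — recurrent artifacts and common
#' local variation.
#'
#' @inheritParams qualityFilter
#' @param nIndividuals total number of genotyped individuals (> 0).
#' @return filtered subset.
#' @export
cohortFrequencyFilter <- function(variants, config = FilterConfig(),
                                  nIndividuals) {
  if (nrow(variants) == 0) return(variants)
  if (missing(nIndividuals) || is.null(nIndividuals) || nIndividuals <= 0)
    .err("cohortFrequencyFilter requires nIndividuals > 0")
  fail <- .cohortFailSites(variants, config, nIndividuals)
  out <- variants[!.siteKey(variants) %in% fail, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population frequency filter
#'
#' Removes variants with gnomAD allele frequency strictly above
#' \code{maxGnomadAf} (default 1\%). A missing AF is treated as rare (the
#' variant is retained): novel variants must survive to classification.
#' Whitelisted pathogenic intronic variants are always retained.
#'
#' @inheritParams qualityFilter
#' @return filtered subset.
#' @export
populationFrequencyFilter <- function(variants, config = FilterConfig(),
                                      nIndividuals = NULL) {
  if (nrow(variants) == 0) return(variants)
  out <- variants[!.popFailRecords(variants, config), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consequence filter: nonsynonymous coding and splice regions
#'
#' Retains nonsynonymous coding variants (missense, stop gain, frameshift,
#' in-frame indel), canonical splice-site variants, splice-region variants
#' up to \code{spliceWindowBp} into the intron, and whitelisted pathogenic
#' intronic variants. Synonymous and deep-intronic non-whitelisted records
#' are removed.
#'
#' @inheritParams qualityFilter
#' @return filtered subset.
#' @export
consequenceFilter <- function(variants, config = FilterConfig(),
                              nIndividuals = NULL) {
  if (nrow(variants) == 0) return(variants)
  out <- variants[.consequenceKeep(variants, config), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full variant filter cascade
#'
#' Applies quality, cohort-frequency, population-frequency and consequence
#' filters in that fixed order, with per-stage removal accounting (each
#' record is attributed to the first stage that removes it).
#'
#' @param source variant data.frame, TSV path, or VCF path (detected by
#'   \code{.vcf}/\code{.vcf.gz} extension).
#' @param panel a [GenePanel-class].
#' @param config a [FilterConfig-class].
#' @param nIndividuals total genotyped individuals (> 0).
#' @return list with elements \code{variants} (the surviving records) and
#'   \code{report} (a [FilterReport-class]).
#' @examples
#' panel <- defaultGenePanel()
#' v <- data.frame(individual_id = "S1", gene = "SLC7A9", chrom = "19",
#'                 pos = 1000L, ref = "A", alt = "G", genotype = "het",
#'                 allele_fraction = 0.48, site_quality = 60,
#'                 consequence = "missense", splice_distance_bp = 0L,
#'                 gnomad_af = 0.001, whitelist_pathogenic_intronic = FALSE,
#'                 hgvs_p = "p.(Gly105Arg)")
#' runFilterCascade(v, panel, nIndividuals = 100)$report
#' @export
runFilterCascade <- function(source, panel, config = FilterConfig(),
                             nIndividuals) {
  variants <- if (is.character(source) &&
                  grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE)) {
    loadVariantsVcf(source, panel)
  } else {
    loadVariants(source, panel)
  }
  stages <- list(quality = qualityFilter,
                 cohort_frequency = cohortFrequencyFilter,
                 population_frequency = populationFrequencyFilter,
                 consequence = consequenceFilter)
  nIn <- nrow(variants)
  removed <- integer(length(stages))
  names(removed) <- names(stages)
  cur <- variants
  for (s in names(stages)) {
    nxt <- stages[[s]](cur, config, nIndividuals = nIndividuals)
    removed[[s]] <- nrow(cur) - nrow(nxt)
    cur <- nxt
  }
  report <- new("FilterReport", nIn = as.integer(nIn),
                nOut = as.integer(nrow(cur)), removed = removed)
  list(variants = cur, report = report)
}
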