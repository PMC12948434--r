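#' @import methods
NULL

# ---------------------------------------------------------------------------
# GenePanel
# ---------------------------------------------------------------------------

#' Gene panel with inheritance modes and demotion flags
#'
#' Container for the virtual kidney-stone-disease gene panel: one row per
#' gene with its reported Mendelian inheritance mode, a flag marking genes
#' whose monoallelic likely-pathogenic/pathogenic (LP/P) variants are demoted
#' from "strong risk factor" status after biochemical reclassification, and a
#' set of individually demoted protein alleles (e.g. a recurrent hypomorphic
#' missense allele).
#'
#' @slot genes data.frame with columns \code{symbol}, \code{inheritance}
#'   (one of \code{AR}, \code{AD}, \code{AD_AR}, \code{XLR}),
#'   \code{chrom}, \code{monoallelic_demoted} (logical).
#' @slot demotedAlleles character vector of \code{"GENE:p.(Xxx000Yyy)"} ids
#'   demoted individually when found in the monoallelic state.
#'
#' @seealso [defaultGenePanel()], [readGenePanel()]
#' @export
setClass("GenePanel",
  representation(genes = "data.frame", demotedAlleles = "character"))

setValidity("GenePanel", function(object) {
  g <- object@genes
  msgs <- character()
  need <- c("symbol", "inheritance", "chrom", "monoallelic_demoted")
  miss <- setdiff(need, names(g))
  if (length(miss))
    return(paste("genes lacks column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(g$symbol))
    msgs <- c(msgs, "gene symbols must be unique within the panel")
  bad <- setdiff(unique(g$inheritance), c("AR", "AD", "AD_AR", "XLR"))
  if (length(bad))
    msgs <- c(msgs, paste("unknown inheritance mode(s):",
                          paste(bad, collapse = ", ")))
  xl <- g$symbol[g$inheritance == "XLR" & g$chrom != "X"]
  if (length(xl))
    msgs <- c(msgs, paste("XLR gene(s) not on chromosome X:",
                          paste(xl, collapse = ", ")))
  da <- object@demotedAlleles
  if (length(da)) {
    dg <- sub(":.*$", "", da)
    ug <- setdiff(dg, g$symbol)
    if (length(ug))
      msgs <- c(msgs, paste("demoted allele(s) in non-panel gene(s):",
                            paste(ug, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GenePanel number of genes in the panel.
#' @param x,object a \code{GenePanel}.
#' @export
setMethod("length", "GenePanel", function(x) nrow(x@genes))

setMethod("show", "GenePanel", function(object) {
  g <- object@genes
  cat(sprintf("GenePanel with %d genes\n", nrow(g)))
  tab <- table(g$inheritance)
  cat("  inheritance:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  monoallelic-demoted genes: %s\n",
              paste(g$symbol[g$monoallelic_demoted], collapse = ", ")))
  if (length(object@demotedAlleles))
    cat(sprintf("  demoted alleles: %s\n",
                paste(object@demotedAlleles, collapse = ", ")))
})

#' Construct a GenePanel
#'
#' @param genes data.frame with columns \code{symbol}, \code{inheritance},
#'   \code{chrom}, and optionally \code{monoallelic_demoted}.
#' @param demotedAlleles character vector of \code{"GENE:hgvs_p"} allele ids.
#' @return a validated [GenePanel-class] object.
#' @export
GenePanel <- function(genes, demotedAlleles = character()) {
  if (is.null(genes$monoallelic_demoted))
    genes$monoallelic_demoted <- FALSE
  genes$symbol <- as.character(genes$symbol)
  genes$inheritance <- as.character(genes$inheritance)
  genes$chrom <- as.character(genes$chrom)
  new("GenePanel", genes = as.data.frame(genes, stringsAsFactors = FALSE),
      demotedAlleles = as.character(demotedAlleles))
}

#' @rdname GenePanel-accessors
#' @name GenePanel-accessors
#' @title Accessors for GenePanel objects
#' @param panel a [GenePanel-class].
#' @param gene character vector of gene symbols.
#' @return \code{panelGenes}: character vector of symbols;
#'   \code{inheritanceMode}: named character vector of modes;
#'   \code{isDemotedGene}: named logical; \code{demotedAlleles}: character.
#' @export
panelGenes <- function(panel) panel@genes$symbol

#' @rdname GenePanel-accessors
#' @export
inheritanceMode <- function(panel, gene = NULL) {
  modes <- structure(panel@genes$inheritance, names = panel@genes$symbol)
  if (is.null(gene)) modes else modes[gene]
}

#' @rdname GenePanel-accessors
#' @export
isDemotedGene <- function(panel, gene = NULL) {
  d <- structure(panel@genes$monoallelic_demoted, names = panel@genes$symbol)
  if (is.null(gene)) d else d[gene]
}

#' @rdname GenePanel-accessors
#' @export
demotedAlleles <- function(panel) panel@demotedAlleles

# ---------------------------------------------------------------------------
# FilterConfig
# ---------------------------------------------------------------------------

#' Variant filter thresholds
#'
#' Thresholds for the four-stage variant filter cascade. All frequency
#' comparisons are strict (\code{>}): a site is removed when its offending
#' statistic strictly exceeds the threshold.
#'
#' @slot minAlleleFraction a carrier read (variant allele) fraction below
#'   this marks the carrier as low-support (default 0.3).
#' @slot maxFractionLowAf site removed when more than this fraction of its
#'   carriers are low-support (default 0.6).
#' @slot minQuality minimum site quality score retained (default 25).
#' @slot maxCohortCarrierFraction site removed when carried by more than
#'   this fraction of cohort individuals (default 0.10).
#' @slot maxGnomadAf maximum gnomAD allele frequency retained (default 0.01).
#' @slot spliceWindowBp intronic distance (bp) still counted as splice
#'   region (default 10).
#' @export
setClass("FilterConfig",
  representation(minAlleleFraction = "numeric",
                 maxFractionLowAf = "numeric",
                 minQuality = "numeric",
                 maxCohortCarrierFraction = "numeric",
                 maxGnomadAf = "numeric",
                 spliceWindowBp = "integer"))

setValidity("FilterConfig", function(object) {
  msgs <- character()
  inUnit <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!inUnit(object@minAlleleFraction))
    msgs <- c(msgs, "minAlleleFraction must be a single value in [0,1]")
  if (!inUnit(object@maxFractionLowAf))
    msgs <- c(msgs, "maxFractionLowAf must be a single value in [0,1]")
  if (!inUnit(object@maxCohortCarrierFraction))
    msgs <- c(msgs, "maxCohortCarrierFraction must be in [0,1]")
  if (!inUnit(object@maxGnomadAf))
    msgs <- c(msgs, "maxGnomadAf must be in [0,1]")
  if (length(object@minQuality) != 1L || object@minQuality < 0)
    msgs <- c(msgs, "minQuality must be a single nonnegative value")
  if (length(object@spliceWindowBp) != 1L || object@spliceWindowBp < 0L)
    msgs <- c(msgs, "spliceWindowBp must be a single nonnegative integer")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  allele fraction < %.2f in > %.0f%% of carriers -> drop site\n",
              object@minAlleleFraction, 100 * object@maxFractionLowAf))
  cat(sprintf("  site quality < %g -> drop site\n", object@minQuality))
  cat(sprintf("  carried by > %.0f%% of cohort -> drop site\n",
              100 * object@maxCohortCarrierFraction))
  cat(sprintf("  gnomAD AF > %g -> drop (unless whitelisted)\n",
              object@maxGnomadAf))
  cat(sprintf("  splice window: %d bp into intron\n", object@spliceWindowBp))
})

#' Construct a FilterConfig
#'
#' Defaults reproduce the study filter: read fraction < 0.3 in > 60% of
#' carriers, quality < 25, cohort carrier fraction > 10%, gnomAD AF > 1%,
#' splice window 10 bp.
#'
#' @param minAlleleFraction,maxFractionLowAf,minQuality numeric thresholds.
#' @param maxCohortCarrierFraction,maxGnomadAf numeric thresholds.
#' @param spliceWindowBp integer splice window.
#' @return a validated [FilterConfig-class].
#' @examples
#' FilterConfig()
#' @export
FilterConfig <- function(minAlleleFraction = 0.3,
                         maxFractionLowAf = 0.6,
                         minQuality = 25,
                         maxCohortCarrierFraction = 0.10,
                         maxGnomadAf = 0.01,
                         spliceWindowBp = 10L) {
  new("FilterConfig",
      minAlleleFraction = minAlleleFraction,
      maxFractionLowAf = maxFractionLowAf,
      minQuality = minQuality,
      maxCohortCarrierFraction = maxCohortCarrierFraction,
      maxGnomadAf = maxGnomadAf,
      spliceWindowBp = as.integer(spliceWindowBp))
}

#' Read / write a FilterConfig as JSON
#'
#' @param path file path.
#' @param config a [FilterConfig-class].
#' @return \code{readFilterConfig} returns a [FilterConfig-class];
#'   \code{writeFilterConfig} returns \code{path} invisibly.
#' @export
readFilterConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(FilterConfig, x)
}

#' @rdname readFilterConfig
#' @export
writeFilterConfig <- function(config, path) {
  x <- list(minAlleleFraction = config@minAlleleFraction,
            maxFractionLowAf = config@maxFractionLowAf,
            minQuality = config@minQuality,
            maxCohortCarrierFraction = config@maxCohortCarrierFraction,
            maxGnomadAf = config@maxGnomadAf,
            spliceWindowBp = config@spliceWindowBp)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FilterReport
# ---------------------------------------------------------------------------

#' Per-stage removal accounting for the filter cascade
#'
#' @slot nIn number of variant records entering the cascade.
#' @slot nOut number of records surviving all stages.
#' @slot removed named integer vector of records removed per stage, with
#'   first-removing-stage attribution (a record is counted against the first
#'   stage that would drop it).
#' @export
setClass("FilterReport",
  representation(nIn = "integer", nOut = "integer", removed = "integer"))

setValidity("FilterReport", function(object) {
  if (object@nIn != object@nOut + sum(object@removed))
    "removal counts do not conserve: nIn != nOut + sum(removed)"
  else TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d in, %d out\n", object@nIn, object@nOut))
  for (s in names(object@removed))
    cat(sprintf("  %-22s -%d\n", s, object@removed[[s]]))
})

#' @rdname FilterReport-class
#' @param report a \code{FilterReport}.
#' @return named integer vector of per-stage removals.
#' @export
removedPerStage <- function(report) report@removed
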