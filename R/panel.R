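#' Default 39-gene kidney stone disease panel
#'
#' The virtual panel of established nephrolithiasis / nephrocalcinosis genes
#' with their reported inheritance modes (AR, AD, AD_AR where both modes have
#' been reported, XLR). Genes whose monoallelic LP/P variants lacked the
#' expected biochemical signature in the cohort analysis — \emph{SLC9A3R1},
#' \emph{SLC34A1}, \emph{CYP24A1} — carry \code{monoallelic_demoted = TRUE},
#' and the recurrent hypomorphic \emph{SLC7A9} p.(Ala182Thr) allele is
#' demoted individually. Inheritance modes follow the clinical genetics
#' literature for each gene; the demotion flags drive
#' [reclassifyStrongRisk()].
#'
#' @return a [GenePanel-class] with 39 genes.
#' @examples
#' defaultGenePanel()
#' @export
defaultGenePanel <- function() {
  g <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol     inheritance chrom
ADCY10     AD          1
AGXT       AR          2
ALPL       AD_AR       1
APRT       AR          16
ATP6V0A4   AR          7
ATP6V1B1   AR          2
BSND       AR          1
CA2        AR          8
CASR       AD          3
CLCN5      XLR         X
CLCNKA     AR          1
CLCNKB     AR          1
CLDN14     AD          21
CLDN16     AR          3
CLDN19     AR          1
CYP24A1    AD_AR       20
FAM20A     AR          17
GRHPR      AR          9
HNF4A      AD          20
HOGA1      AR          10
HPRT1      XLR         X
KCNJ1      AR          11
OCRL       XLR         X
SLC12A1    AR          15
SLC22A12   AR          11
SLC26A1    AR          4
SLC26A6    AR          3
SLC2A9     AD_AR       4
SLC34A1    AD_AR       5
SLC34A3    AD_AR       9
SLC3A1     AR          2
SLC4A1     AD_AR       17
SLC7A9     AD_AR       19
SLC9A3     AR          5
SLC9A3R1   AD          17
TRPV5      AR          7
UMOD       AD          16
VDR        AR          12
XDH        AR          2
")
  g$monoallelic_demoted <- g$symbol %in% c("SLC9A3R1", "SLC34A1", "CYP24A1")
  GenePanel(g, demotedAlleles = "SLC7A9:p.(Ala182Thr)")
}

#' Read / write a gene panel specification
#'
#' Tab-separated panel files carry columns \code{symbol}, \code{inheritance},
#' \code{chrom}, \code{monoallelic_demoted}; individually demoted alleles are
#' stored in an optional \code{demoted_allele} column (one allele id per row,
#' \code{NA} elsewhere).
#'
#' @param path TSV file path.
#' @param panel a [GenePanel-class].
#' @return \code{readGenePanel}: a [GenePanel-class]; \code{writeGenePanel}:
#'   \code{path}, invisibly.
#' @export
readGenePanel <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkCols(g, c("symbol", "inheritance", "chrom"), "panel file")
  da <- character()
  if (!is.null(g$demoted_allele))
    da <- g$demoted_allele[!is.na(g$demoted_allele) & g$demoted_allele != ""]
  g$demoted_allele <- NULL
  GenePanel(g, demotedAlleles = da)
}

#' @rdname readGenePanel
#' @export
writeGenePanel <- function(panel, path) {
  g <- panel@genes
  da <- demotedAlleles(panel)
  g$demoted_allele <- c(da, rep(NA_character_, nrow(g) - length(da)))[
    seq_len(nrow(g))]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
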