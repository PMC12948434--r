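#' ACMG/AMP evidence codes and classes
#'
#' The recognized evidence codes, grouped by family and default strength:
#' pathogenic very strong (PVS1), strong (PS1-PS4), moderate (PM1-PM6),
#' supporting (PP1-PP5); benign stand-alone (BA1), strong (BS1-BS4),
#' supporting (BP1-BP7). Classes are the 5-tier scale \code{P}, \code{LP},
#' \code{VUS}, \code{LB}, \code{B}, plus the \code{none} sentinel for an
#' individual with no retained variant.
#'
#' @return \code{acmgCodes()}: data.frame of code, family, default strength;
#'   \code{acmgLevels()}: the class levels in pathogenicity order.
#' @examples
#' acmgLevels()
#' @export
acmgCodes <- function() {
  data.frame(
    code = c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7)),
    family = c(rep("pathogenic", 16), rep("benign", 12)),
    strength = c("very_strong", rep("strong", 4), rep("moderate", 6),
                 rep("supporting", 5), "stand_alone", rep("strong", 4),
                 rep("supporting", 7)),
    stringsAsFactors = FALSE)
}

#' @rdname acmgCodes
#' @export
acmgLevels <- function() c("B", "LB", "VUS", "LP", "P")

#' Validate and normalize an ACMG evidence set
#'
#' Upper-cases codes, rejects unknown ones, forbids duplicates and checks
#' that strength overrides refer to codes that are present.
#'
#' @param codes character vector of evidence codes (case-insensitive).
#' @param strengthOverrides optional named character vector mapping a code
#'   to \code{very_strong}, \code{strong}, \code{moderate} or
#'   \code{supporting} (e.g. ClinGen-calibrated PP3 at strong).
#' @return list with canonical \code{codes} and \code{strengthOverrides}.
#' @examples
#' validateEvidence(c("pvs1", "pm2"))
#' @export
validateEvidence <- function(codes, strengthOverrides = NULL) {
  codes <- toupper(trimws(as.character(codes)))
  codes <- codes[codes != ""]
  known <- acmgCodes()$code
  bad <- setdiff(codes, known)
  if (length(bad))
    .err("unknown ACMG evidence code(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(codes))
    .err("duplicated ACMG evidence code(s): %s",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  if (!is.null(strengthOverrides) && length(strengthOverrides)) {
    names(strengthOverrides) <- toupper(names(strengthOverrides))
    orphan <- setdiff(names(strengthOverrides), codes)
    if (length(orphan))
      .err("strength override(s) for absent code(s): %s",
           paste(orphan, collapse = ", "))
    badS <- setdiff(unlist(strengthOverrides),
                    c("very_strong", "strong", "moderate", "supporting"))
    if (length(badS))
      .err("unknown override strength: %s", paste(badS, collapse = ", "))
  }
  list(codes = sort(codes), strengthOverrides = strengthOverrides)
}

# counts of evidence codes per effective strength tier, overrides applied
.evidenceCounts <- function(codes, strengthOverrides = NULL) {
  tab <- acmgCodes()
  strength <- structure(tab$strength, names = tab$code)[codes]
  family <- structure(tab$family, names = tab$code)[codes]
  if (!is.null(strengthOverrides) && length(strengthOverrides))
    strength[names(strengthOverrides)] <- unlist(strengthOverrides)
  path <- family == "pathogenic"
  list(
    nVS = sum(path & strength == "very_strong"),
    nS  = sum(path & strength == "strong"),
    nM  = sum(path & strength == "moderate"),
    nP  = sum(path & strength == "supporting"),
    nBA = sum(!path & strength == "stand_alone"),
    nBS = sum(!path & strength == "strong"),
    nBP = sum(!path & strength == "supporting"))
}

#' Combine ACMG/AMP evidence into a 5-tier class
#'
#' Implements the published combining rules. Pathogenic: one very-strong
#' plus (>=1 strong | >=2 moderate | 1 moderate + 1 supporting |
#' >=2 supporting), or >=2 strong, or 1 strong plus (>=3 moderate |
#' 2 moderate + >=2 supporting | 1 moderate + >=4 supporting); two
#' very-strong criteria (possible via strength overrides) are also
#' pathogenic. Likely pathogenic: 1 very-strong + 1 moderate, 1 strong +
#' 1-2 moderate, 1 strong + >=2 supporting, >=3 moderate, 2 moderate +
#' >=2 supporting, or 1 moderate + >=4 supporting. Benign: stand-alone BA1
#' or >=2 benign-strong. Likely benign: 1 benign-strong + >=1 benign
#' supporting, or >=2 benign supporting. Anything else — including
#' simultaneous pathogenic- and benign-side matches (conflicting evidence)
#' — is VUS.
#'
#' A variant whose evidence alone is VUS may be upgraded to LP when
#' published functional experiments support its effect; the upgrade is
#' never silent: both \code{functionalSupport} and
#' \code{applyFunctionalUpgrade} must be set.
#'
#' @param codes character vector of evidence codes (or the output of
#'   [validateEvidence()]).
#' @param strengthOverrides see [validateEvidence()].
#' @param functionalSupport logical; published functional evidence exists.
#' @param applyFunctionalUpgrade logical; opt-in to the VUS -> LP upgrade
#'   path when \code{functionalSupport} is \code{TRUE}.
#' @return a single class from [acmgLevels()].
#' @examples
#' combineEvidence(c("PVS1", "PM2"))   # LP
#' combineEvidence("BA1")              # B
#' combineEvidence(character())        # VUS
#' @export
combineEvidence <- function(codes, strengthOverrides = NULL,
                            functionalSupport = FALSE,
                            applyFunctionalUpgrade = FALSE) {
  if (is.list(codes) && !is.null(codes$codes)) {
    strengthOverrides <- codes$strengthOverrides
    codes <- codes$codes
  }
  e <- validateEvidence(codes, strengthOverrides)
  n <- .evidenceCounts(e$codes, e$strengthOverrides)

  pathP <- (n$nVS >= 2) ||
    (n$nVS >= 1 && (n$nS >= 1 || n$nM >= 2 ||
                    (n$nM == 1 && n$nP >= 1) || n$nP >= 2)) ||
    (n$nS >= 2) ||
    (n$nS == 1 && (n$nM >= 3 || (n$nM == 2 && n$nP >= 2) ||
                   (n$nM == 1 && n$nP >= 4)))
  pathLP <- (n$nVS >= 1 && n$nM >= 1) ||
    (n$nS == 1 && n$nM >= 1 && n$nM <= 2) ||
    (n$nS == 1 && n$nP >= 2) ||
    (n$nM >= 3) ||
    (n$nM == 2 && n$nP >= 2) ||
    (n$nM == 1 && n$nP >= 4)
  benB <- (n$nBA >= 1) || (n$nBS >= 2)
  benLB <- (n$nBS == 1 && n$nBP >= 1) || (n$nBP >= 2)

  pathSide <- pathP || pathLP
  benSide <- benB || benLB
  cls <- if (pathSide && benSide) "VUS"
         else if (pathP) "P"
         else if (pathLP) "LP"
         else if (benB) "B"
         else if (benLB) "LB"
         else "VUS"
  if (cls == "VUS" && isTRUE(functionalSupport) &&
      isTRUE(applyFunctionalUpgrade))
    cls <- "LP"
  cls
}

#' Classify every variant in a table
#'
#' Applies [combineEvidence()] row-wise using the \code{evidence_codes}
#' column (comma-separated codes) and appends an \code{acmg_class} column.
#' Optional columns \code{functional_support} and
#' \code{apply_functional_upgrade} (logical) drive the explicit functional
#' upgrade path per variant.
#'
#' @param variants [variantTable] data.frame with \code{evidence_codes}.
#' @return \code{variants} with an \code{acmg_class} column.
#' @export
classifyVariants <- function(variants) {
  .checkCols(variants, "evidence_codes", "variant table")
  fs <- if (!is.null(variants$functional_support))
    variants$functional_support else rep(FALSE, nrow(variants))
  up <- if (!is.null(variants$apply_functional_upgrade))
    variants$apply_functional_upgrade else rep(FALSE, nrow(variants))
  codeList <- strsplit(ifelse(is.na(variants$evidence_codes), "",
                              variants$evidence_codes), ",")
  variants$acmg_class <- vapply(seq_len(nrow(variants)), function(i) {
    combineEvidence(codeList[[i]], functionalSupport = isTRUE(fs[i]),
                    applyFunctionalUpgrade = isTRUE(up[i]))
  }, character(1))
  variants
}

#' Aggregate per-variant classes to one class per individual
#'
#' Returns the most clinically significant class under the precedence
#' P > LP > VUS > LB > B, so each individual is accounted for once in the
#' cohort class pie. An empty input yields the \code{"none"} sentinel.
#'
#' @param classes character vector of classes from [acmgLevels()].
#' @return a single class, or \code{"none"}.
#' @examples
#' aggregateIndividualClass(c("VUS", "LP"))  # "LP"
#' aggregateIndividualClass(character())     # "none"
#' @export
aggregateIndividualClass <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) return("none")
  bad <- setdiff(classes, acmgLevels())
  if (length(bad))
    .err("unknown ACMG class value(s): %s", paste(bad, collapse = ", "))
  acmgLevels()[max(match(classes, acmgLevels()))]
}
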