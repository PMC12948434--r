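#' Tubular reabsorption of phosphate (TRP)
#'
#' Fractional tubular reabsorption of phosphate from paired plasma and
#' urine measurements:
#' \deqn{TRP = 1 - (U_P \cdot P_{cr}) / (U_{cr} \cdot P_P)}
#' with plasma phosphate in mmol/L, plasma creatinine in umol/L (converted
#' internally), and urine phosphate/creatinine concentrations in mmol/L.
#'
#' @param plasmaPhosphate mmol/L, > 0.
#' @param plasmaCreatinine umol/L, > 0.
#' @param urinePhosphate mmol/L, >= 0.
#' @param urineCreatinine mmol/L, > 0.
#' @return TRP fraction (<= 1; negative with gross phosphate wasting).
#' @examples
#' trp(1.0, 80, 20, 8)  # 0.8
#' @export
trp <- function(plasmaPhosphate, plasmaCreatinine, urinePhosphate,
                urineCreatinine) {
  if (any(plasmaPhosphate <= 0, na.rm = TRUE))
    .err("plasma phosphate must be > 0")
  if (any(plasmaCreatinine <= 0, na.rm = TRUE))
    .err("plasma creatinine must be > 0")
  if (any(urineCreatinine <= 0, na.rm = TRUE))
    .err("urine creatinine must be > 0")
  if (any(urinePhosphate < 0, na.rm = TRUE))
    .err("urine phosphate must be >= 0")
  1 - (urinePhosphate * plasmaCreatinine / 1000) /
    (urineCreatinine * plasmaPhosphate)
}

#' Tubular maximum phosphate reabsorption per GFR (TmP/GFR)
#'
#' Algebraic approximation of the Walton-Bijvoet nomogram: below the branch
#' point TRP = 0.86 the relation is linear, TmP/GFR = TRP * P_P; above it
#' the saturation correction TmP/GFR = 0.3 * TRP / (1 - 0.8 * TRP) * P_P
#' applies. The two branches do not meet exactly at 0.86 (0.860 vs 0.827
#' times P_P), reflecting the published nomogram; the branch rule is applied
#' exactly as stated.
#'
#' @param trpValue TRP fraction, <= 1 (vectorized).
#' @param plasmaPhosphate mmol/L.
#' @return TmP/GFR in mmol/L.
#' @examples
#' tmpGfr(0.80, 1.0)  # 0.80
#' tmpGfr(0.95, 1.0)  # 1.1875
#' @export
tmpGfr <- function(trpValue, plasmaPhosphate) {
  if (any(trpValue > 1, na.rm = TRUE)) .err("TRP must be <= 1")
  ifelse(trpValue <= 0.86,
         trpValue * plasmaPhosphate,
         0.3 * trpValue / (1 - 0.8 * trpValue) * plasmaPhosphate)
}

#' Creatinine-normalized urinary ratio
#'
#' @param analyte analyte amount or concentration (any unit).
#' @param creatinine creatinine in the same basis, > 0.
#' @return analyte / creatinine; the unit is (analyte unit) per
#'   (creatinine unit), invariant to rescaling both by 24-h volume.
#' @export
urinaryRatio <- function(analyte, creatinine) {
  if (any(creatinine <= 0, na.rm = TRUE)) .err("creatinine must be > 0")
  analyte / creatinine
}

#' Simplified urinary supersaturation index
#'
#' Ion-activity-product ratio SS = a(Ca2+) * a(anion) / Ksp for calcium
#' oxalate or brushite (CaHPO4 . 2H2O), intended for rank and direction
#' comparisons only — it is \emph{not} a full iterative speciation program
#' and its values are not numerically comparable to EQUIL2 scores.
#' Activity coefficients come from the Davies equation with ionic strength
#' estimated from the measured calcium, magnesium, oxalate, citrate and
#' phosphate plus a configurable monovalent background electrolyte. The
#' divalent phosphate fraction follows from urine pH and the phosphoric
#' acid dissociation constants; an optional single-step Ca-citrate ion
#' pair correction reduces free calcium.
#'
#' @param urine one-row data.frame (or list) with 24-h urine fields
#'   \code{urine_calcium}, \code{urine_oxalate}, \code{urine_citrate},
#'   \code{urine_magnesium}, \code{urine_phosphate} (mmol/24 h),
#'   \code{urine_volume} (L) and \code{urine_ph}.
#' @param salt \code{"CaOx"} or \code{"brushite"}.
#' @param ksp solubility product (mol^2/L^2); defaults: calcium oxalate
#'   2.32e-9, brushite 2.37e-7 (37 C literature values, configurable).
#' @param backgroundIonic monovalent background electrolyte contribution to
#'   ionic strength, mol/L (default 0.15, typical urine NaCl).
#' @param caCitratePairing apply the Ca-citrate ion pair correction
#'   (association constant \code{kCaCit}).
#' @param kCaCit Ca-citrate association constant, L/mol (default 1600).
#' @return dimensionless supersaturation index, >= 0; > 1 indicates
#'   supersaturation of the salt.
#' @examples
#' u <- data.frame(urine_calcium = 5, urine_oxalate = 0.35,
#'                 urine_citrate = 2.5, urine_magnesium = 4,
#'                 urine_phosphate = 25, urine_volume = 1.5, urine_ph = 6)
#' supersaturationIndex(u, "CaOx")
#' supersaturationIndex(u, "brushite")
#' @export
supersaturationIndex <- function(urine, salt = c("CaOx", "brushite"),
                                 ksp = NULL, backgroundIonic = 0.15,
                                 caCitratePairing = TRUE, kCaCit = 1600) {
  salt <- match.arg(salt)
  need <- c("urine_calcium", "urine_oxalate", "urine_citrate",
            "urine_magnesium", "urine_phosphate", "urine_volume")
  .checkCols(as.data.frame(urine), need, "urine composition")
  vol <- urine$urine_volume
  if (any(vol <= 0)) .err("urine volume must be > 0")
  # mmol/24h over L -> mol/L
  conc <- function(x) x / vol / 1000
  ca <- conc(urine$urine_calcium)
  ox <- conc(urine$urine_oxalate)
  cit <- conc(urine$urine_citrate)
  mg <- conc(urine$urine_magnesium)
  ph4 <- conc(urine$urine_phosphate)
  if (any(c(ca, ox, cit, mg, ph4) < 0)) .err("concentrations must be >= 0")

  if (salt == "brushite") {
    if (is.null(urine$urine_ph) || any(is.na(urine$urine_ph)))
      .err("urine pH is required for the brushite index")
    pH <- urine$urine_ph
    if (any(pH < 4 | pH > 9)) .err("urine pH must lie in [4, 9]")
  }
  if (is.null(ksp)) ksp <- if (salt == "CaOx") 2.32e-9 else 2.37e-7

  # ionic strength: Ca2+, Mg2+, Ox2-, citrate ~3-, phosphate ~2-,
  # plus monovalent background
  ionicStrength <- 0.5 * (4 * ca + 4 * mg + 4 * ox + 9 * cit + 4 * ph4) +
    backgroundIonic
  # Davies equation for a divalent ion at 37 C
  sqI <- sqrt(ionicStrength)
  logGamma2 <- -0.509 * 4 * (sqI / (1 + sqI) - 0.3 * ionicStrength)
  gamma2 <- 10^logGamma2

  caFree <- ca
  if (caCitratePairing) {
    # 1:1 Ca-citrate complex: solve Ca_f from
    # K * Ca_f^2 + (1 + K*(Cit_t - Ca_t)) * Ca_f - Ca_t = 0
    K <- kCaCit
    b <- 1 + K * (cit - ca)
    caFree <- (-b + sqrt(b^2 + 4 * K * ca)) / (2 * K)
    caFree <- pmin(pmax(caFree, 0), ca)
  }

  anion <- if (salt == "CaOx") {
    ox
  } else {
    pKa2 <- 7.20
    pKa3 <- 12.35
    frac <- 1 / (1 + 10^(pKa2 - urine$urine_ph) +
                   10^(urine$urine_ph - pKa3))
    ph4 * frac
  }
  gamma2^2 * caFree * anion / ksp
}

#' Default reference ranges for the derived biochemistry
#'
#' Literature adult reference ranges used as generator baselines and as the
#' cystinuria profile thresholds; all editable. Urinary amino acids are in
#' mmol per mol creatinine.
#'
#' @return named list with \code{low}/\code{high} per analyte.
#' @export
defaultReferenceRanges <- function() {
  list(
    plasma_phosphate = c(low = 0.80, high = 1.45),        # mmol/L
    plasma_creatinine = c(low = 60, high = 100),          # umol/L
    plasma_calcium_albumin_adj = c(low = 2.20, high = 2.60),
    pth = c(low = 15, high = 65),                         # ng/L
    fgf23 = c(low = 40, high = 110),                      # RU/mL
    vitd_1_25 = c(low = 50, high = 150),                  # pmol/L
    vitd_25 = c(low = 50, high = 125),                    # nmol/L
    urine_phosphate = c(low = 15, high = 40),             # mmol/24h
    urine_calcium = c(low = 2.0, high = 7.5),
    urine_creatinine = c(low = 9, high = 18),
    urine_oxalate = c(low = 0.10, high = 0.50),
    urine_citrate = c(low = 1.5, high = 4.5),
    urine_magnesium = c(low = 3.0, high = 5.0),
    urine_volume = c(low = 1.0, high = 2.5),              # L
    urine_ph = c(low = 5.0, high = 7.0),
    cystine = c(low = 4, high = 25),   # mmol/mol creatinine
    ornithine = c(low = 1, high = 5),
    lysine = c(low = 8, high = 40),
    arginine = c(low = 1, high = 5))
}

#' Cystinuria amino-acid profile
#'
#' Classifies creatinine-normalized urinary cystine, ornithine, lysine and
#' arginine against reference upper bounds: \code{normal} at or below the
#' bound, \code{moderate_elevation} above it, \code{marked_elevation} above
#' \code{markedFactor} times the bound. The summary flag is
#' \code{marked} when cystine is markedly elevated or at least two dibasic
#' amino acids are elevated, \code{elevated} when any analyte is above its
#' bound, otherwise \code{normal}. Missing analytes give a partial profile.
#'
#' @param aminoAcids named numeric vector or one-row data.frame with any of
#'   \code{cystine}, \code{ornithine}, \code{lysine}, \code{arginine}
#'   (mmol/mol creatinine).
#' @param referenceRanges list as [defaultReferenceRanges()].
#' @param markedFactor multiple of the upper bound defining marked
#'   elevation (default 3).
#' @return list with per-analyte \code{levels} and a \code{summary} flag.
#' @examples
#' cystinuriaProfile(c(cystine = 250, ornithine = 30, lysine = 300,
#'                     arginine = 40))$summary  # marked
#' @export
cystinuriaProfile <- function(aminoAcids,
                              referenceRanges = defaultReferenceRanges(),
                              markedFactor = 3) {
  analytes <- c("cystine", "ornithine", "lysine", "arginine")
  aminoAcids <- unlist(as.list(aminoAcids))
  present <- intersect(analytes, names(aminoAcids))
  levels <- vapply(present, function(a) {
    x <- aminoAcids[[a]]
    if (is.na(x)) return(NA_character_)
    hi <- referenceRanges[[a]][["high"]]
    if (x <= hi) "normal"
    else if (x <= markedFactor * hi) "moderate_elevation"
    else "marked_elevation"
  }, character(1))
  dibasic <- levels[intersect(c("ornithine", "lysine", "arginine"),
                              names(levels))]
  nDibasicElev <- sum(dibasic %in% c("moderate_elevation",
                                     "marked_elevation"), na.rm = TRUE)
  cys <- if ("cystine" %in% names(levels)) levels[["cystine"]] else NA
  summary <- if (identical(cys, "marked_elevation") || nDibasicElev >= 2) {
    "marked"
  } else if (any(levels %in% c("moderate_elevation", "marked_elevation"))) {
    "elevated"
  } else "normal"
  list(levels = levels, summary = summary)
}

#' Derive the full biochemical index table from visit data
#'
#' Computes TRP, TmP/GFR, urinary calcium/creatinine and
#' cystine/creatinine ratios and both supersaturation indices for every
#' row of a per-visit biochemistry table.
#'
#' @param visits data.frame with columns \code{individual_id},
#'   \code{visit}, plasma fields (\code{plasma_phosphate} mmol/L,
#'   \code{plasma_creatinine} umol/L), 24-h urine fields (mmol and L, see
#'   [supersaturationIndex()]), and amino-acid ratios (mmol/mol
#'   creatinine).
#' @param visitSelect optional visit label (e.g. \code{"V2"}) to restrict
#'   to; the study design measures the baseline biochemistry at visit 2.
#' @return data.frame with \code{individual_id}, \code{visit}, \code{TRP},
#'   \code{TmP_GFR}, \code{Ca_crea_ratio}, \code{cystine_crea_ratio},
#'   \code{SS_CaOx}, \code{SS_brushite}.
#' @export
deriveBiochem <- function(visits, visitSelect = NULL) {
  need <- c("individual_id", "visit", "plasma_phosphate",
            "plasma_creatinine", "urine_phosphate", "urine_creatinine",
            "urine_calcium", "urine_oxalate", "urine_citrate",
            "urine_magnesium", "urine_volume", "urine_ph")
  .checkCols(visits, need, "visit biochemistry table")
  if (!is.null(visitSelect))
    visits <- visits[visits$visit == visitSelect, , drop = FALSE]
  if (nrow(visits) == 0)
    return(data.frame(individual_id = character(), visit = character(),
                      TRP = numeric(), TmP_GFR = numeric(),
                      Ca_crea_ratio = numeric(),
                      cystine_crea_ratio = numeric(),
                      SS_CaOx = numeric(), SS_brushite = numeric()))
  uP <- visits$urine_phosphate / visits$urine_volume
  uCr <- visits$urine_creatinine / visits$urine_volume
  trpv <- trp(visits$plasma_phosphate, visits$plasma_creatinine, uP, uCr)
  data.frame(
    individual_id = visits$individual_id,
    visit = visits$visit,
    TRP = trpv,
    TmP_GFR = tmpGfr(pmin(trpv, 1), visits$plasma_phosphate),
    Ca_crea_ratio = urinaryRatio(visits$urine_calcium,
                                 visits$urine_creatinine),
    cystine_crea_ratio = if (!is.null(visits$cystine)) visits$cystine
                         else NA_real_,
    SS_CaOx = supersaturationIndex(visits, "CaOx"),
    SS_brushite = supersaturationIndex(visits, "brushite"),
    stringsAsFactors = FALSE)
}
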