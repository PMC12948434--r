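# independent ACMG/AMP combining-rule oracle: the published rule table
# transcribed as data (minimum code counts per strength tier), matched with
# >= semantics after counting codes by their default strength prefix.
# Deliberately a different formulation from the package's boolean engine.

.oracleRules <- list(
  P = list(c(vs = 2),
           c(vs = 1, s = 1),
           c(vs = 1, m = 2),
           c(vs = 1, m = 1, pp = 1),
           c(vs = 1, pp = 2),
           c(s = 2),
           c(s = 1, m = 3),
           c(s = 1, m = 2, pp = 2),
           c(s = 1, m = 1, pp = 4)),
  LP = list(c(vs = 1, m = 1),
            c(s = 1, m = 1),
            c(s = 1, pp = 2),
            c(m = 3),
            c(m = 2, pp = 2),
            c(m = 1, pp = 4)),
  B = list(c(ba = 1),
           c(bs = 2)),
  LB = list(c(bs = 1, bp = 1),
            c(bp = 2)))

oracleAcmgClass <- function(codes) {
  counts <- c(vs = sum(grepl("^PVS", codes)),
              s = sum(grepl("^PS", codes)),
              m = sum(grepl("^PM", codes)),
              pp = sum(grepl("^PP", codes)),
              ba = sum(grepl("^BA", codes)),
              bs = sum(grepl("^BS", codes)),
              bp = sum(grepl("^BP", codes)))
  hits <- function(tier) any(vapply(.oracleRules[[tier]], function(req)
    all(counts[names(req)] >= req), logical(1)))
  pathogenicSide <- hits("P") || hits("LP")
  benignSide <- hits("B") || hits("LB")
  if (pathogenicSide && benignSide) return("VUS")
  if (hits("P")) return("P")
  if (hits("LP")) return("LP")
  if (hits("B")) return("B")
  if (hits("LB")) return("LB")
  "VUS"
}

# enumerate evidence sets with up to `maxPerTier` codes per strength tier
enumerateEvidenceSets <- function(maxPerTier = 3L) {
  pools <- list(vs = "PVS1", s = paste0("PS", 1:4), m = paste0("PM", 1:6),
                pp = paste0("PP", 1:5), ba = "BA1", bs = paste0("BS", 1:4),
                bp = paste0("BP", 1:7))
  caps <- vapply(pools, function(p) min(length(p), maxPerTier), integer(1))
  grid <- expand.grid(lapply(caps, function(k) 0:k))
  lapply(seq_len(nrow(grid)), function(i)
    unlist(lapply(names(pools), function(t)
      pools[[t]][seq_len(grid[i, t])]), use.names = FALSE))
}
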