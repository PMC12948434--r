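#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' all printed cohort percentages, instead of base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(1.55, 1.649, 9.843), 1)
#' @export
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, printed-table convention
#'
#' @param n count, @param total denominator.
#' @return 100 * n / total rounded half-up to one decimal; 0 for empty total.
#' @keywords internal
.pct1 <- function(n, total) {
  if (total == 0) return(numeric(length(n)))
  roundHalfUp(100 * n / total, 1L)
}

# stop() with a consistent prefix, no call echo
.err <- function(...) stop(sprintf(...), call. = FALSE)

.checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .err("%s is missing required column(s): %s", what,
         paste(miss, collapse = ", "))
  invisible(df)
}

# site key shared by all site-level filters; variant identity across
# individuals is (chrom, pos, ref, alt)
.siteKey <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
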