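#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' The group-comparison test used for categorical cohort contrasts (e.g.
#' LP/P carrier vs non-carrier by stone-former status). The continuity
#' correction is deliberately off: the uncorrected statistic reproduces the
#' printed cohort p-value (chi-square = 5.11, p = 0.0238 on the
#' 107/594 vs 18/182 carrier table), whereas the Yates-corrected one does
#' not (p = 0.032).
#'
#' @param a,b first-row counts; @param c,d second-row counts.
#' @return list \code{statistic}, \code{p_value}, \code{df},
#'   \code{method}.
#' @examples
#' chiSquare2x2(107, 594, 18, 182)$p_value  # ~ 0.0238
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) .err("counts must be nonnegative")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .err("chi-square test undefined with a zero margin")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), method = "pearson_chisq_uncorrected")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration for small tie-free samples (both n < 50), otherwise
#' the tie-corrected normal approximation without continuity correction.
#' Fully tied samples (zero rank variance) return p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @return list \code{statistic} (U for the first sample), \code{p_value},
#'   \code{n}, \code{method}.
#' @export
mannWhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) .err("both samples must be non-empty")
  r <- rank(c(x, y))
  if (max(r) == min(r))  # all observations identical
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                n = c(length(x), length(y)), method = "mann_whitney_ties"))
  exact <- length(x) < 50 && length(y) < 50 && !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       n = c(length(x), length(y)),
       method = if (exact) "mann_whitney_exact" else "mann_whitney_normal")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom, used for multi-group biochemistry comparisons across variant
#' classes. Groups of identical constants (zero rank variance) return
#' H = 0, p = 1.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return list \code{statistic}, \code{p_value}, \code{df},
#'   \code{method}.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    .err("kruskalWallis needs a list of >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(!lengths(groups))) .err("all groups must be non-empty")
  values <- unlist(groups)
  if (max(values) == min(values))
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1,
                method = "kruskal_wallis"))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(values, g)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), method = "kruskal_wallis")
}

#' Normality-gated descriptive summary
#'
#' Implements the cohort reporting convention: a Shapiro-Wilk test gates
#' the descriptive summary, median (IQR) when normality is rejected at
#' p < 0.05, mean (SD) otherwise.
#'
#' @param sample numeric vector, n >= 3.
#' @param alpha Shapiro-Wilk rejection level (default 0.05).
#' @return list \code{type} (\code{parametric_summary} /
#'   \code{nonparametric_summary}), \code{center}, \code{spread},
#'   \code{shapiro_p}.
#' @export
shapiroGate <- function(sample, alpha = 0.05) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 3) .err("shapiroGate needs n >= 3")
  p <- tryCatch(stats::shapiro.test(sample)$p.value,
                error = function(e) 0)  # degenerate samples: nonparametric
  if (p < alpha) {
    q <- stats::quantile(sample, c(0.25, 0.5, 0.75), names = FALSE)
    list(type = "nonparametric_summary", center = q[2],
         spread = c(q1 = q[1], q3 = q[3]), shapiro_p = p)
  } else {
    list(type = "parametric_summary", center = mean(sample),
         spread = c(sd = stats::sd(sample)), shapiro_p = p)
  }
}

.survivalCheck <- function(records) {
  .checkCols(records, c("individual_id", "time_days", "event",
                        "strong_risk_factor"), "survival records")
  if (any(records$time_days < 0)) .err("time_days must be >= 0")
  if (any(records$event & records$time_days <= 0))
    .err("events must have time_days > 0")
  records
}

#' Kaplan-Meier product-limit estimate per risk group
#'
#' @param records data.frame with \code{individual_id}, \code{time_days},
#'   \code{event} (logical), and the grouping column.
#' @param groupBy name of the grouping column (default
#'   \code{strong_risk_factor}).
#' @return list with \code{fit} (a \code{survival::survfit} object) and
#'   \code{table} (long data.frame: group, time, n_risk, n_event,
#'   n_censor, survival) for plotting and risk tables.
#' @export
kmEstimate <- function(records, groupBy = "strong_risk_factor") {
  .survivalCheck(records)
  f <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~", groupBy))
  fit <- survival::survfit(f, data = records)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time))
         else as.character(s$strata)
  tab <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, n_censor = s$n.censor,
                    survival = s$surv, stringsAsFactors = FALSE)
  list(fit = fit, table = tab)
}

#' Two-group log-rank test
#'
#' @inheritParams kmEstimate
#' @return list \code{statistic} (chi-square, df = 1), \code{p_value},
#'   \code{method}.
#' @export
logrankTest <- function(records, groupBy = "strong_risk_factor") {
  .survivalCheck(records)
  if (length(unique(records[[groupBy]])) != 2)
    .err("logrankTest requires exactly 2 groups")
  if (!any(records$event)) .err("logrankTest requires >= 1 event")
  f <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~", groupBy))
  sd <- survival::survdiff(f, data = records)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       method = "logrank")
}

#' Cox proportional hazards regression for stone recurrence
#'
#' Partial-likelihood fit with Efron tie handling, the recurrence model of
#' the cohort analysis: time to first recurrence on the strong-risk flag
#' adjusted for age and sex. Wald confidence intervals and p-values per
#' covariate; HR = exp(coefficient).
#'
#' @param records data.frame with \code{time_days}, \code{event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names (default
#'   \code{c("strong_risk_factor", "age", "sex")}).
#' @return data.frame, one row per model term: \code{term}, \code{coef},
#'   \code{HR}, \code{ci_low}, \code{ci_high}, \code{p_value}.
#' @export
coxPh <- function(records,
                  covariates = c("strong_risk_factor", "age", "sex")) {
  .checkCols(records, c(c("time_days", "event"), covariates),
             "survival records")
  if (sum(records$event) < 2) .err("coxPh requires >= 2 events")
  f <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        .err("coxPh failed: %s", conditionMessage(w))
      suppressWarnings(survival::coxph(f, data = records, ties = "efron"))
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(term = rownames(co), coef = co[, "coef"],
             HR = co[, "exp(coef)"],
             ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
             p_value = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-recurrence summary by risk group
#'
#' Percentage of individuals with more than one stone recurrence during
#' follow-up, per strong-risk group, printed-table rounding (half-up, one
#' decimal).
#'
#' @param records survival data.frame with \code{n_recurrences} and
#'   \code{strong_risk_factor}.
#' @return data.frame \code{group}, \code{n}, \code{n_multi}, \code{pct}.
#' @examples
#' rec <- data.frame(strong_risk_factor = rep(c(TRUE, FALSE), c(48, 302)),
#'                   n_recurrences = c(rep(2, 5), rep(0, 43),
#'                                     rep(2, 7), rep(0, 295)))
#' multiRecurrenceSummary(rec)
#' @export
multiRecurrenceSummary <- function(records) {
  .checkCols(records, c("strong_risk_factor", "n_recurrences"),
             "recurrence records")
  groups <- list(strong_risk = records$strong_risk_factor,
                 no_strong_risk = !records$strong_risk_factor)
  out <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    data.frame(group = g, n = sum(sel),
               n_multi = sum(records$n_recurrences[sel] > 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$pct <- mapply(function(nm, n) if (n > 0) .pct1(nm, n) else 0,
                    out$n_multi, out$n)
  out
}
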