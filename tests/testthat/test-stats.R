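test_that("uncorrected chi-square reproduces textbook values and guards
          degenerate margins", {
  r <- chiSquare2x2(107, 594, 18, 182)
  expect_equal(r$p_value, 0.0238, tolerance = 0.02)
  expect_equal(r$df, 1)
  expect_equal(chiSquare2x2(10, 90, 10, 90)$statistic, 0)
  expect_equal(chiSquare2x2(10, 90, 10, 90)$p_value, 1)
  expect_equal(chiSquare2x2(5, 5, 5, 5)$statistic, 0)
  expect_error(chiSquare2x2(0, 0, 5, 5), "margin")
  expect_error(chiSquare2x2(-1, 5, 5, 5), "nonnegative")
})

test_that("Mann-Whitney: exact separation oracle, tie degeneracy, rank
          invariance", {
  # 3 vs 3 complete separation: U = 0, exact two-sided p = 2/C(6,3) = 0.1
  r <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  # identical samples
  x <- rnorm(20)
  expect_equal(mannWhitney(x, x)$p_value, 1, tolerance = 1e-6)
  # fully tied samples are defined, not NaN
  expect_equal(mannWhitney(rep(5, 6), rep(5, 4))$p_value, 1)
  # invariance under a monotone transform of both samples
  set.seed(1)
  a <- rnorm(25); b <- rnorm(30, 0.5)
  expect_equal(mannWhitney(exp(a), exp(b))$p_value,
               mannWhitney(a, b)$p_value, tolerance = 1e-12)
  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("Kruskal-Wallis handles constants, agrees with two-sample rank
          test, and detects a planted shift", {
  r <- kruskalWallis(list(rep(3, 5), rep(3, 7)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # with 2 groups the tie-corrected H test matches the normal-approximation
  # Mann-Whitney asymptotically
  set.seed(2)
  x <- rnorm(120); y <- rnorm(150, 0.2)
  pKW <- kruskalWallis(list(x, y))$p_value
  pMW <- mannWhitney(x, y)$p_value
  expect_equal(pKW, pMW, tolerance = 0.02)
  # power against a one-group location shift at n = 50/group
  set.seed(3)
  rejections <- replicate(40, {
    g <- c(lapply(1:3, function(i) rnorm(50)), list(rnorm(50, 0.8)))
    kruskalWallis(g)$p_value < 0.05
  })
  nullRej <- replicate(40, {
    g <- lapply(1:4, function(i) rnorm(50))
    kruskalWallis(g)$p_value < 0.05
  })
  expect_gt(mean(rejections), mean(nullRej))
  expect_gt(mean(rejections), 0.5)
})

test_that("Shapiro gate selects the reporting convention", {
  set.seed(4)
  nonNormal <- shapiroGate(runif(500))
  expect_equal(nonNormal$type, "nonparametric_summary")
  expect_named(nonNormal$spread, c("q1", "q3"))
  expect_silent(shapiroGate(c(1, 1.0000001, 1.0000002)))
  # type-I control: Gaussian samples mostly summarized parametrically
  set.seed(5)
  types <- replicate(30, shapiroGate(rnorm(200))$type)
  expect_gte(mean(types == "parametric_summary"), 0.9)
  expect_error(shapiroGate(c(1, 2)), "n >= 3")
})

test_that("Kaplan-Meier estimates match the hand product-limit oracle", {
  # no events: survival identically 1
  rec <- data.frame(individual_id = c("a", "b"), time_days = c(100, 200),
                    event = FALSE, strong_risk_factor = FALSE)
  km <- kmEstimate(rec)
  expect_true(all(km$table$survival == 1))
  # single event at t=10 among n=2
  rec <- data.frame(individual_id = c("a", "b"), time_days = c(10, 50),
                    event = c(TRUE, FALSE), strong_risk_factor = FALSE)
  km <- kmEstimate(rec)
  expect_equal(km$table$survival[km$table$time == 10], 0.5)
  # 10-record fixture against a brute-force product over event times
  set.seed(6)
  rec <- data.frame(individual_id = letters[1:10],
                    time_days = sample(10:400, 10),
                    event = rep(c(TRUE, FALSE), 5),
                    strong_risk_factor = FALSE)
  km <- kmEstimate(rec)$table
  bruteS <- function(t) {
    eventTimes <- sort(rec$time_days[rec$event & rec$time_days <= t])
    prod(vapply(eventTimes, function(u) {
      atRisk <- sum(rec$time_days >= u)
      d <- sum(rec$event & rec$time_days == u)
      1 - d / atRisk
    }, numeric(1)))
  }
  for (t in km$time)
    expect_equal(km$survival[km$time == t], bruteS(t), tolerance = 1e-12)
  # conservation at each time: risk set accounts for events + censorings
  expect_true(all(diff(km$survival) <= 1e-12))
})

test_that("log-rank: null invariance and equivalence with the Cox score
          test", {
  base <- data.frame(individual_id = sprintf("i%d", 1:40),
                     time_days = rep(c(50, 120, 300, 700), 10),
                     event = rep(c(TRUE, FALSE), 20),
                     age = 50, sex = "M",
                     strong_risk_factor = rep(c(TRUE, FALSE), each = 20))
  # mirrored groups: identical survival experience, statistic 0
  mirror <- base
  mirror$strong_risk_factor <- !mirror$strong_risk_factor
  mirror$individual_id <- paste0("m", mirror$individual_id)
  both <- rbind(base, mirror)
  expect_equal(logrankTest(both)$statistic, 0, tolerance = 1e-12)
  # log-rank equals the score test of the unadjusted Cox fit
  set.seed(7)
  rec <- data.frame(individual_id = sprintf("i%d", 1:120),
                    time_days = rexp(120, 1 / 400),
                    event = runif(120) < 0.7,
                    strong_risk_factor = rep(c(TRUE, FALSE), 60))
  rec$event[1:2] <- TRUE  # guarantee events
  lr <- logrankTest(rec)
  fit <- survival::coxph(
    survival::Surv(time_days, event) ~ strong_risk_factor, data = rec,
    ties = "efron")
  expect_equal(lr$statistic, unname(summary(fit)$sctest["test"]),
               tolerance = 1e-6)
  expect_error(logrankTest(base[!base$event, ]), "event")
})

test_that("Cox coefficient matches a brute-force partial-likelihood grid
          on a hand-checkable dataset", {
  # 6 records, single binary covariate, no ties
  rec <- data.frame(individual_id = sprintf("i%d", 1:6),
                    time_days = c(10, 25, 40, 70, 100, 130),
                    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                    x = c(1, 0, 1, 1, 0, 0))
  # independent oracle: Breslow/Efron coincide without ties; maximize the
  # partial likelihood by golden-section search
  logPL <- function(beta) {
    s <- 0
    for (i in which(rec$event)) {
      riskSet <- rec$time_days >= rec$time_days[i]
      s <- s + beta * rec$x[i] - log(sum(exp(beta * rec$x[riskSet])))
    }
    s
  }
  oracle <- stats::optimize(logPL, c(-5, 5), maximum = TRUE)$maximum
  rec$strong_risk_factor <- rec$x == 1
  fit <- coxPh(rec, covariates = "strong_risk_factor")
  expect_equal(fit$coef, oracle, tolerance = 1e-4)
  expect_equal(fit$HR, exp(oracle), tolerance = 1e-4)
  expect_error(coxPh(rec[!rec$event, ], covariates = "strong_risk_factor"),
               "events")
})

test_that("Cox on permuted labels is null-calibrated", {
  set.seed(8)
  hrs <- replicate(30, {
    n <- 200
    rec <- data.frame(time_days = rexp(n, 1 / 500),
                      event = runif(n) < 0.6,
                      age = rnorm(n, 50, 10),
                      sex = sample(c("M", "F"), n, TRUE),
                      strong_risk_factor = sample(rep(c(TRUE, FALSE),
                                                      each = n / 2)))
    coxPh(rec)$HR[1]
  })
  expect_equal(mean(log(hrs)), 0, tolerance = 0.12)
})

test_that("multi-recurrence summary prints group percentages with half-up
          rounding", {
  rec <- data.frame(strong_risk_factor = rep(c(TRUE, FALSE), c(48, 302)),
                    n_recurrences = c(rep(2, 5), rep(1, 10), rep(0, 33),
                                      rep(2, 7), rep(1, 50), rep(0, 245)))
  ms <- multiRecurrenceSummary(rec)
  expect_equal(ms$pct[ms$group == "strong_risk"], 10.4)
  expect_equal(ms$pct[ms$group == "no_strong_risk"], 2.3)
  expect_equal(ms$n, c(48, 302))
})
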