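# small cohort with boosted hazards so validation metrics have events to
# work with at modest n; no unknown-ER relabelling so that risks computed
# from the generating model itself are calibrated against the recorded
# ER-specific events
boosted_truth <- function() {
  base <- cbind(ERpos = c(1.1, 1.5, 1.9, 2.2, 2.5, 2.7, 2.8, 2.9) * 4e-3,
                ERneg = c(1.1, 1.5, 1.9, 2.2, 2.5, 2.7, 2.8, 2.9) * 1.2e-3)
  default_true_model(baselines = base, p_unknown = 0)
}

test_that("C-statistic hits the closed-form extremes", {
  n <- 60
  co <- data.frame(id = 1:n, entry_age = 50,
                   exit_age = 50 + c(rep(2, 10), rep(8, 50)),
                   event = c(rep("ERpos", 10), rep("censored", 50)))
  risks <- c(rep(0.9, 10), rep(0.1, 50))
  expect_equal(cstatistic_5yr(risks, co, "ERpos", ci = FALSE)$C, 1.0)
  expect_equal(cstatistic_5yr(rep(0.5, n), co, "ERpos", ci = FALSE)$C, 0.5)
})

test_that("C-statistic equals exhaustive pair enumeration on a hand fixture", {
  # 8 subjects: ER+ cases at 1 and 3 years, a competing event at 2 years,
  # one early censored subject, an ER+ case beyond the window
  co <- data.frame(
    id = 1:8,
    entry_age = rep(50, 8),
    exit_age = 50 + c(1, 3, 2, 1.5, 6, 4.8, 7, 9),
    event = c("ERpos", "ERpos", "competing", "censored", "ERpos",
              "censored", "censored", "ERneg")
  )
  risks <- c(0.08, 0.02, 0.05, 0.02, 0.06, 0.01, 0.03, 0.04)
  tt <- erisk:::truncated_times(co, "ERpos", 5)
  expect_equal(cstatistic_5yr(risks, co, "ERpos", ci = FALSE)$C,
               cstat_brute(risks, tt$time, tt$status))
  # and on random data with ties
  set.seed(80)
  for (rep in 1:5) {
    n <- 40
    co2 <- data.frame(
      id = 1:n, entry_age = 50,
      exit_age = 50 + sample(seq(0.5, 8, by = 0.5), n, TRUE),
      event = sample(c("ERpos", "ERneg", "competing", "censored"), n,
                     TRUE, c(0.3, 0.1, 0.2, 0.4))
    )
    r2 <- round(runif(n), 1)
    tt2 <- erisk:::truncated_times(co2, "ERpos", 5)
    if (sum(tt2$status) %in% c(0, length(tt2$status))) next
    expect_equal(cstatistic_5yr(r2, co2, "ERpos", ci = FALSE)$C,
                 cstat_brute(r2, tt2$time, tt2$status))
  }
})

test_that("C-statistic is invariant under strictly monotone transforms", {
  tm <- boosted_truth()
  co <- simulate_cohort(4000, tm, seed = 81)
  pr <- cumulative_incidence(tm, co, horizon = 5)
  c0 <- cstatistic_5yr(pr$risk_ERpos, co, "ERpos", ci = FALSE)$C
  for (f in list(function(x) x^2, function(x) log(x + 1e-12),
                 function(x) 100 * x - 3, stats::qlogis)) {
    expect_equal(cstatistic_5yr(f(pr$risk_ERpos), co, "ERpos",
                                ci = FALSE)$C, c0)
  }
})

test_that("E/O follows the stated arithmetic and CI rule", {
  # construct a cohort with O = 100 observed 5-year ER+ events
  n <- 1000
  co <- data.frame(id = 1:n, entry_age = 50, exit_age = 50 + 6,
                   event = "censored")
  co$exit_age[1:100] <- 50 + 2.5
  co$event[1:100] <- "ERpos"
  risks <- rep(110 / n, n)          # E = 110
  eo <- expected_observed(risks, co, "ERpos", 5)
  expect_equal(eo$E, 110)
  expect_equal(eo$O, 100)
  expect_equal(eo$EO, 1.10)
  expect_equal(eo$ci, c(1.10 * exp(-0.196), 1.10 * exp(0.196)),
               tolerance = 1e-3)
  # doubling predicted risks doubles E/O
  eo2 <- expected_observed(2 * risks, co, "ERpos", 5)
  expect_equal(eo2$EO, 2 * eo$EO)
  # no observed events is undefined
  expect_error(expected_observed(risks, co, "ERneg", 5), "undefined")
})

test_that("the Aalen-Johansen switch corrects censoring undercount", {
  tm <- boosted_truth()
  co <- simulate_cohort(20000, tm, seed = 82)
  # censor half the cohort at 3 years to force undercount
  cut <- seq_len(10000)
  trunc <- co$entry_age[cut] + 3 < co$exit_age[cut]
  co$exit_age[cut][trunc] <- co$entry_age[cut][trunc] + 3
  co$event[cut][trunc] <- "censored"
  pr <- cumulative_incidence(tm, co, horizon = 5)
  raw <- expected_observed(pr$risk_ERpos, co, "ERpos", 5)
  adj <- expected_observed(pr$risk_ERpos, co, "ERpos", 5,
                           adjust = "aalen-johansen")
  expect_gt(adj$O, raw$O)     # the adjustment recovers masked events
  expect_lt(abs(adj$EO - 1), abs(raw$EO - 1) + 0.02)
})

test_that("decile calibration partitions subjects and flags inflation", {
  set.seed(83)
  risks <- runif(100)
  co <- data.frame(id = 1:100, entry_age = 50, exit_age = 56,
                   event = "censored")
  tab <- calibration_deciles(risks, co, "ERpos", 5)
  expect_equal(tab$n, rep(10, 10))
  expect_equal(sum(tab$n), 100)
  # self-calibrated synthetic cohort: per-decile agreement within 3 SEs
  tm <- boosted_truth()
  co2 <- simulate_cohort(30000, tm, seed = 84)
  pr <- cumulative_incidence(tm, co2, horizon = 5)
  tab2 <- calibration_deciles(pr$risk_ERpos, co2, "ERpos", 5)
  # per-decile agreement within 3 binomial SEs, allowing the one
  # excursion that ten simultaneous 3-SE checks are expected to produce
  dev_se <- abs(tab2$mean_predicted - tab2$observed) /
    pmax(tab2$se_observed, 1e-8)
  expect_gte(sum(dev_se <= 3), 9)
  expect_true(all(dev_se <= 4))
  # systematic 10% inflation shows predicted > observed in (nearly) all
  # deciles
  tab3 <- calibration_deciles(1.1 * pr$risk_ERpos, co2, "ERpos", 5)
  expect_gte(sum(tab3$mean_predicted > tab3$observed), 9)
})

test_that("fivefold cross-validation covers every subject once and is stable", {
  tm <- boosted_truth()
  co <- simulate_cohort(12000, tm, seed = 85)
  cv <- crossvalidate_5fold(co, seed = 2)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_true(all(table(cv$folds) %in% c(2400)))
  expect_false(anyNA(cv$risks))          # one out-of-fold prediction each
  # in a well-specified large cohort, CV C is close to the apparent C
  fit <- erisk_fit(co)
  pr <- cumulative_incidence(fit, co, horizon = 5)
  c_app <- cstatistic_5yr(pr$risk_ERpos, co, "ERpos", ci = FALSE)$C
  expect_lt(abs(cv$ERpos$C - c_app), 0.02)
  # E/O near 1 when fitting and evaluating on the same population
  expect_lt(abs(cv$ERpos$EO - 1), 3 / sqrt(cv$ERpos$O) + 0.05)
})

test_that("eliminating real stratum effects reduces discrimination", {
  # amplify the country contrasts so strata carry strong baseline
  # differences
  sp <- default_model_spec()
  beta <- truth_coefficients(sp)
  beta[c("country:B", "country:C", "country:D"), 1] <- c(0.9, -0.9, 1.3)
  base <- cbind(ERpos = c(1.1, 1.5, 1.9, 2.2, 2.5, 2.7, 2.8, 2.9) * 4e-3,
                ERneg = c(1.1, 1.5, 1.9, 2.2, 2.5, 2.7, 2.8, 2.9) * 1.2e-3)
  tm <- true_model(sp, baselines = base, coefficients = beta)
  co <- simulate_cohort(8000, tm, seed = 86)
  cv_with <- crossvalidate_5fold(co, seed = 3)
  cv_without <- crossvalidate_5fold(co, seed = 3, eliminate_stratum = TRUE)
  expect_lt(cv_without$ERpos$C, cv_with$ERpos$C)
})
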