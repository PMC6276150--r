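test_that("covariate generation matches configured marginals and is reproducible", {
  co <- generate_covariates(10000, seed = 7)
  # binomial 3-SE bound around P(postmenopausal) = 0.51
  expect_lt(abs(mean(co$meno == "post") - 0.51), 0.015)
  expect_true(all(co$entry_age >= 40 & co$entry_age < 70))
  # dependency rules: no age at menopause on premenopausal rows, no
  # parity variables on nulliparous rows
  expect_true(all(is.na(co$age_menopause[co$meno == "pre"])))
  expect_true(all(!is.na(co$age_menopause[co$meno == "post"])))
  expect_true(all(is.na(co$n_ftp[co$ftp == "no"])))
  expect_true(all(is.na(co$breastfeeding[co$ftp == "no"])))
  # derived interaction coding
  expect_true(all(co$bmi_meno[co$meno == "pre"] == "0"))
  post_ob <- co$meno == "post" & co$bmi == "30to35"
  expect_true(all(co$bmi_meno[post_ob] == "2"))
  # determinism under a fixed seed
  expect_identical(generate_covariates(5, seed = 3),
                   generate_covariates(5, seed = 3))
})

test_that("invalid probability vectors are rejected by name", {
  cfg <- default_covariate_config()
  cfg$hrt <- cfg$hrt * 2
  expect_error(generate_covariates(10, cfg), "hrt")
})

test_that("zero hazards produce only administrative censoring", {
  tm <- tiny_truth(0, 0, gompertz = list(alpha = -Inf, gamma = 0))
  co <- simulate_outcomes(tiny_cohort(500, 1), tm, seed = 2)
  expect_true(all(co$event == "censored"))
  expect_true(all(co$exit_age <= 80 + 1e-12))
  expect_true(all(co$exit_age - co$entry_age >= 10 - 1e-12 |
                    abs(co$exit_age - 80) < 1e-12))
})

test_that("event fraction matches the exponential closed form", {
  # constant total hazard 0.01/yr over a 10-year window
  tm <- tiny_truth(0.006, 0.004, gompertz = list(alpha = -Inf, gamma = 0),
                   p_unknown = 0,
                   censoring = default_censoring(fu_min = 10, fu_max = 10,
                                                 age_cap = 200))
  n <- 40000
  co <- simulate_outcomes(tiny_cohort(n, 4, p_post = 0), tm, seed = 5)
  p_true <- 1 - exp(-0.1)
  frac <- mean(co$event != "censored")
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("cause split follows the competing-risks hazard ratio", {
  # two constant causes 0.01 and 0.03: cause-1 share of events = 0.25
  tm <- tiny_truth(0.01, 0.03, gompertz = list(alpha = -Inf, gamma = 0),
                   p_unknown = 0)
  co <- simulate_outcomes(tiny_cohort(100000, 8, p_post = 0), tm, seed = 9)
  ev <- co$event[co$event %in% tumour_causes()]
  share <- mean(ev == "ERpos")
  expect_lt(abs(share - 0.25), 3 * sqrt(0.25 * 0.75 / length(ev)))
})

test_that("unknown-ER relabelling thins tumours at the configured rate", {
  tm <- tiny_truth(0.004, 0.002, gompertz = list(alpha = -Inf, gamma = 0),
                   p_unknown = 0.25)
  co <- simulate_outcomes(tiny_cohort(50000, 10, p_post = 0), tm, seed = 11)
  tum <- co$event %in% c(tumour_causes(), "unknownER")
  pu <- mean(co$event[tum] == "unknownER")
  expect_lt(abs(pu - 0.25), 3 * sqrt(0.25 * 0.75 / sum(tum)))
})

test_that("empirical crude incidence matches the analytic cumulative incidence", {
  tm <- tiny_truth(2e-3, 5e-4, hr = c(1, 1),
                   censoring = default_censoring(fu_min = 12, fu_max = 12,
                                                 age_cap = 90),
                   p_unknown = 0)
  n <- 50000
  co <- simulate_outcomes(tiny_cohort(n, 12, p_post = 0), tm, seed = 13)
  # analytic 12-year ER+ cumulative incidence per subject, averaged
  pr <- cumulative_incidence(tm, co, start_age = co$entry_age, horizon = 12)
  p_true <- mean(pr$risk_ERpos)
  tau <- co$exit_age - co$entry_age
  p_emp <- mean(co$event == "ERpos" & tau <= 12)
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("simulation respects proportional hazards between covariate groups", {
  tm <- tiny_truth(1.5e-3, 4e-4, hr = c(0.66, 0.66),
                   gompertz = list(alpha = -Inf, gamma = 0), p_unknown = 0)
  co <- simulate_outcomes(tiny_cohort(150000, 14), tm, seed = 15)
  py <- function(ix) sum(co$exit_age[ix] - co$entry_age[ix])
  rate <- function(ix) sum(co$event[ix] == "ERpos") / py(ix)
  hr_emp <- rate(co$meno == "post") / rate(co$meno == "pre")
  d <- sum(co$event == "ERpos")
  expect_lt(abs(log(hr_emp) - log(0.66)), 3 * 2 / sqrt(d))
})

test_that("missingness injection hits the requested rates and mechanisms", {
  co <- generate_covariates(10000, seed = 20)
  co$exit_age <- co$entry_age + 1
  co$event <- "censored"
  # identity at rate 0
  expect_identical(inject_missingness(co, c(hrt = 0), seed = 1), co)
  # MCAR 3-SE bound
  co2 <- inject_missingness(co, c(hrt = 0.3), seed = 2)
  expect_lt(abs(mean(is.na(co2$hrt)) - 0.3), 0.014)
  expect_false(anyNA(co2$event))
  # MAR-on-age: oldest decile misses more than youngest
  co3 <- inject_missingness(co, c(bmi = 0.3), mechanism = "MAR-age",
                            seed = 3)
  q <- quantile(co$entry_age, c(0.1, 0.9))
  expect_gt(mean(is.na(co3$bmi[co$entry_age >= q[2]])),
            mean(is.na(co3$bmi[co$entry_age <= q[1]])))
  expect_lt(abs(mean(is.na(co3$bmi)) - 0.3), 0.02)
  # out-of-range rates rejected
  expect_error(inject_missingness(co, c(hrt = 1.2)), "\\[0, 1\\]")
})

test_that("cohort schema violations are caught", {
  co <- hand_cohort()
  expect_silent(validate_cohort(co))
  bad <- co; bad$exit_age[1] <- bad$entry_age[1]
  expect_error(validate_cohort(bad), "exceed")
  bad <- co; bad$event[1] <- "lost"
  expect_error(validate_cohort(bad), "vocabulary")
  bad <- co; bad$age_menopause <- factor(c("le45", NA, NA, "le45"))
  expect_error(validate_cohort(bad), "premenopausal")
})

test_that("cohort tables round-trip through CSV", {
  tm <- default_true_model()
  co <- simulate_cohort(50, tm, seed = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$event, co$event)
  expect_equal(levels(back$hrt), levels(co$hrt))
  expect_equal(back$height, co$height, tolerance = 1e-12)
})
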