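# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; nothing is read from disk.

# A minimal spec: one binary covariate over a single age band. Used where
# the shape of the model, not the epidemiology, is under test.
tiny_spec <- function(cutoffs = numeric(0), shared = TRUE) {
  sp <- default_model_spec(cutoffs = cutoffs, covariates = "meno",
                           shared = c(meno = shared))
  sp
}

tiny_truth <- function(lambda1 = 4e-4, lambda2 = 2e-4,
                       hr = c(1.3, 1.3), cutoffs = numeric(0),
                       gompertz = list(alpha = -10.4, gamma = 0.09),
                       shared = TRUE, ...) {
  sp <- tiny_spec(cutoffs, shared = shared)
  nb <- length(cutoffs) + 1L
  true_model(sp,
             baselines = cbind(rep(lambda1, nb), rep(lambda2, nb)),
             coefficients = matrix(log(hr), 1, 2,
                                   dimnames = list("meno:post", NULL)),
             gompertz = gompertz, ...)
}

tiny_cohort <- function(n, seed, p_post = 0.5, ...) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             entry_age = runif(n, 40, 70),
             meno = factor(sample(c("pre", "post"), n, TRUE,
                                  prob = c(1 - p_post, p_post)),
                           levels = c("pre", "post")))
}

# Deterministic hand-built cohort for person-time and fitting fixtures.
hand_cohort <- function() {
  data.frame(
    id = 1:4,
    entry_age = c(48, 46, 52, 41),
    exit_age = c(53, 47, 60, 44.5),
    event = c("censored", "ERpos", "ERneg", "competing"),
    meno = factor(c("pre", "post", "post", "pre"),
                  levels = c("pre", "post"))
  )
}

# Independent C-statistic oracle: exhaustive enumeration over all pairs.
# A case at time t is compared with every subject event-free for the
# cause and under observation beyond t.
cstat_brute <- function(risks, time, status) {
  num <- 0; den <- 0
  for (i in which(status == 1)) {
    for (j in seq_along(risks)) {
      if (j == i) next
      comparable <- time[j] > time[i] ||
        (time[j] == time[i] && status[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  num / den
}

# Quadrature oracle for the cumulative incidence of one tumour cause:
# adaptive integration of h_k(t) S(t) dt with S built from the exact
# cumulative hazards; completely independent of the package's series
# evaluation.
cif_quadrature <- function(model, newdata, cause = 1L, a, h) {
  lp <- erisk:::linear_predictor(model, newdata)
  base <- exp(model$piecewise$baselines)
  cuts <- model$spec$cutoffs
  alpha <- model$gompertz$alpha; gamma <- model$gompertz$gamma
  haz_k <- function(t, k) base[findInterval(t, cuts) + 1L, k] * exp(lp[1, k])
  cumhaz <- function(t) {
    # total cumulative hazard over [a, t], exact
    brk <- sort(unique(c(a, t, cuts[cuts > a & cuts < t])))
    tot <- 0
    for (s in seq_len(length(brk) - 1L)) {
      t1 <- brk[s]; t2 <- brk[s + 1L]
      mid <- (t1 + t2) / 2
      tot <- tot + (haz_k(mid, 1L) + haz_k(mid, 2L)) * (t2 - t1)
      if (is.finite(alpha))
        tot <- tot + exp(alpha + gamma * t1) * expm1(gamma * (t2 - t1)) /
          gamma
    }
    tot
  }
  integrand <- Vectorize(function(t) haz_k(t, cause) * exp(-cumhaz(t)))
  stats::integrate(integrand, a, a + h, rel.tol = 1e-10,
                   subdivisions = 400L)$value
}

# Poisson-GLM oracle for the piecewise fitter: stacked episode-by-cause
# rows, cause-by-band baseline factor, log-exposure offset.
poisson_glm_oracle <- function(cohort, spec) {
  pt <- split_person_time(cohort, spec$cutoffs)
  Z <- erisk:::build_design(pt, spec)
  blocks <- erisk:::design_blocks(spec)
  causes <- spec$causes
  stk <- do.call(rbind, lapply(1:2, function(k) {
    df <- data.frame(d = as.numeric(pt$event == causes[k]),
                     Texp = pt$exposure,
                     cell = paste0(causes[k], ":band", pt$band))
    for (cn in blocks$shared) df[[make.names(cn)]] <- Z[, cn]
    for (cn in blocks$specific)
      for (kk in 1:2)
        df[[make.names(paste0(causes[kk], "_", cn))]] <-
          if (k == kk) Z[, cn] else 0
    df
  }))
  covar_terms <- setdiff(names(stk), c("d", "Texp", "cell"))
  fml <- stats::reformulate(c("0", "cell", covar_terms), response = "d")
  stats::glm(fml, family = stats::poisson(), data = stk,
             offset = log(stk$Texp),
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
}

# Large shared recovery fixture, computed once per test run.
recovery_cache <- new.env(parent = emptyenv())
recovery_fixture <- function() {
  if (is.null(recovery_cache$fit)) {
    tm <- default_true_model()
    co <- simulate_cohort(200000, tm, seed = 101)
    recovery_cache$truth <- tm
    recovery_cache$cohort <- co
    recovery_cache$fit <- erisk_fit(co)
  }
  recovery_cache
}
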