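#' C-statistic for 5-year risk predictions
#'
#' Harrell-type concordance over comparable pairs within the projection
#' window: a case of the target cause at time `t` (measured from the
#' projection start) is paired with every subject still event-free for
#' that cause and under observation beyond `t`; competing events censor a
#' subject's observation at their occurrence. Follow-up is truncated at
#' the horizon. Ties in the risk score count 0.5. The confidence interval
#' is a subject-level bootstrap percentile interval.
#'
#' @param risks Predicted risks, one per cohort row.
#' @param cohort Cohort table with `entry_age`, `exit_age`, `event`.
#' @param cause Target cause, `"ERpos"` or `"ERneg"`.
#' @param horizon Window in years (default 5).
#' @param ci Logical: compute the bootstrap CI (default `TRUE`).
#' @param boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @return A list with `C`, `ci` (length-2 vector or `NULL`), `n_cases`.
#' @export
cstatistic_5yr <- function(risks, cohort, cause = "ERpos", horizon = 5,
                           ci = TRUE, boot = 200L, seed = 1L) {
  stopifnot(length(risks) == nrow(cohort))
  tt <- truncated_times(cohort, cause, horizon)
  if (sum(tt$status) == 0 || sum(tt$status) == length(tt$status))
    stop("no comparable pairs: need both cases and non-cases in the window")
  cval <- concordance_value(tt$time, tt$status, risks)
  out <- list(C = cval, ci = NULL, n_cases = sum(tt$status))
  if (ci) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(cohort)
    cb <- vapply(seq_len(boot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      if (sum(tt$status[ix]) == 0) return(NA_real_)
      concordance_value(tt$time[ix], tt$status[ix], risks[ix])
    }, 0)
    out$ci <- unname(stats::quantile(cb, c(0.025, 0.975), na.rm = TRUE))
  }
  out
}

# time since projection start, truncated at the horizon; competing events
# and the other tumour cause censor observation at their occurrence
truncated_times <- function(cohort, cause, horizon) {
  tau <- cohort$exit_age - cohort$entry_age
  status <- as.numeric(cohort$event == cause & tau <= horizon)
  list(time = pmin(tau, horizon), status = status)
}

concordance_value <- function(time, status, risks) {
  fit <- survival::concordance(survival::Surv(time, status) ~ risks,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Expected/observed calibration ratio
#'
#' `E` is the sum of the predicted risks over the horizon; `O` counts
#' events of the target cause occurring within the horizon from the
#' projection start. The confidence interval uses the log-scale Poisson
#' approximation `(E/O) * exp(-+1.96 / sqrt(O))`. Optionally `O` can be
#' replaced by `n` times the Aalen-Johansen cause-specific cumulative
#' incidence at the horizon, which corrects the raw count for
#' censoring-induced undercount.
#'
#' @inheritParams cstatistic_5yr
#' @param adjust `"none"` (raw count, default) or `"aalen-johansen"`.
#' @return A list with `EO`, `ci`, `E`, `O`.
#' @export
expected_observed <- function(risks, cohort, cause = "ERpos", horizon = 5,
                              adjust = c("none", "aalen-johansen")) {
  stopifnot(length(risks) == nrow(cohort))
  adjust <- match.arg(adjust)
  E <- sum(risks)
  tau <- cohort$exit_age - cohort$entry_age
  O_raw <- sum(cohort$event == cause & tau <= horizon)
  if (adjust == "none") {
    O <- O_raw
  } else {
    state <- ifelse(tau > horizon, "censored", as.character(cohort$event))
    state <- factor(ifelse(state == "censored", "censored",
                           ifelse(state == cause, cause, "other")),
                    levels = c("censored", cause, "other"))
    fit <- survival::survfit(survival::Surv(pmin(tau, horizon), state) ~ 1)
    col <- match(cause, fit$states)
    O <- nrow(cohort) *
      utils::tail(fit$pstate[fit$time <= horizon, col], 1L)
  }
  if (O <= 0) stop("no observed events of cause ", cause,
                   " within the horizon; E/O undefined")
  eo <- E / O
  half <- 1.96 / sqrt(O)
  list(EO = eo, ci = c(eo * exp(-half), eo * exp(half)), E = E, O = O)
}

#' Calibration by deciles of predicted risk
#'
#' Splits subjects into deciles of predicted risk (ties broken by stable
#' subject order) and tabulates the mean predicted risk against the
#' observed proportion with a target-cause event inside the horizon.
#'
#' @inheritParams cstatistic_5yr
#' @return A data.frame with one row per decile: `decile`, `n`,
#'   `risk_lo`, `risk_hi`, `mean_predicted`, `observed`, `se_observed`.
#' @export
calibration_deciles <- function(risks, cohort, cause = "ERpos", horizon = 5) {
  stopifnot(length(risks) == nrow(cohort), nrow(cohort) >= 10)
  tau <- cohort$exit_age - cohort$entry_age
  obs <- as.numeric(cohort$event == cause & tau <= horizon)
  ord <- order(risks, seq_along(risks))
  n <- length(risks)
  dec <- integer(n)
  dec[ord] <- ceiling(seq_len(n) / n * 10)
  out <- do.call(rbind, lapply(1:10, function(dd) {
    ix <- dec == dd
    p_obs <- mean(obs[ix])
    data.frame(decile = dd, n = sum(ix),
               risk_lo = min(risks[ix]), risk_hi = max(risks[ix]),
               mean_predicted = mean(risks[ix]), observed = p_obs,
               se_observed = sqrt(p_obs * (1 - p_obs) / sum(ix)))
  }))
  out
}

#' Fivefold cross-validated model assessment
#'
#' Partitions subjects into five seeded folds of near-equal size, fits
#' the full model ([erisk_fit()]) on four folds, projects absolute risks
#' for the held-out fold at each subject's entry age, and evaluates
#' discrimination and calibration on the pooled out-of-fold predictions.
#' With `eliminate_stratum = TRUE` the risk scores used for ranking are
#' recomputed with the stratum (country) coefficients zeroed, isolating
#' the discrimination attributable to individual-level risk factors from
#' between-stratum incidence differences.
#'
#' @param cohort Cohort table.
#' @param spec Model specification.
#' @param seed Seed for the fold assignment.
#' @param horizon Projection horizon in years (default 5).
#' @param k Number of folds (default 5).
#' @param eliminate_stratum Zero stratum coefficients before ranking
#'   (default `FALSE`).
#' @param ci Compute bootstrap CIs for the C-statistics (default `FALSE`;
#'   the E/O interval is analytic and always reported).
#' @return An object of class `erisk_cv`: per-cause C-statistic, E/O with
#'   CI, decile calibration tables, subgroup C by menopausal status, the
#'   fold assignment and the pooled out-of-fold risk matrix.
#' @export
crossvalidate_5fold <- function(cohort, spec = default_model_spec(),
                                seed = 1L, horizon = 5, k = 5L,
                                eliminate_stratum = FALSE, ci = FALSE) {
  n <- nrow(cohort)
  assign_folds <- function(s) {
    set.seed(s)
    sample(rep_len(seq_len(k), n))
  }
  folds <- assign_folds(seed)
  ok <- function(f) all(vapply(seq_len(k), function(j)
    all(table(factor(cohort$event[f != j],
                     levels = tumour_causes())) > 0), TRUE))
  if (!ok(folds)) {
    folds <- assign_folds(seed + 1L)   # re-randomise once
    if (!ok(folds))
      stop("a training fold has no events of some cause; cohort too small")
  }
  risks <- matrix(NA_real_, n, 2L,
                  dimnames = list(NULL, tumour_causes()))
  for (j in seq_len(k)) {
    train <- cohort[folds != j, , drop = FALSE]
    test <- cohort[folds == j, , drop = FALSE]
    fit <- erisk_fit(train, spec)
    pr <- cumulative_incidence(fit, test, horizon = horizon,
                               drop_stratum = eliminate_stratum)
    risks[folds == j, 1L] <- pr$risk_ERpos
    risks[folds == j, 2L] <- pr$risk_ERneg
  }
  res <- list(folds = folds, risks = risks, horizon = horizon,
              eliminate_stratum = eliminate_stratum)
  for (cause in tumour_causes()) {
    r <- risks[, cause]
    cs <- cstatistic_5yr(r, cohort, cause, horizon, ci = ci)
    eo <- expected_observed(r, cohort, cause, horizon)
    pre <- !is.na(cohort$meno) & cohort$meno == "pre"
    sub <- lapply(list(pre = pre, post = !pre), function(ix) {
      if (sum(cohort$event[ix] == cause &
              (cohort$exit_age - cohort$entry_age)[ix] <= horizon) < 5)
        return(NA_real_)
      cstatistic_5yr(r[ix], cohort[ix, ], cause, horizon, ci = FALSE)$C
    })
    res[[cause]] <- list(C = cs$C, C_ci = cs$ci, EO = eo$EO, EO_ci = eo$ci,
                         E = eo$E, O = eo$O,
                         C_premenopausal = sub$pre,
                         C_postmenopausal = sub$post,
                         deciles = calibration_deciles(r, cohort, cause,
                                                       horizon))
  }
  class(res) <- "erisk_cv"
  res
}

#' @export
print.erisk_cv <- function(x, ...) {
  cat("Fivefold cross-validated assessment (horizon ", x$horizon,
      " years", if (x$eliminate_stratum) ", stratum effect eliminated",
      ")\n", sep = "")
  for (cause in tumour_causes()) {
    r <- x[[cause]]
    cat(sprintf("  %s: C = %.3f, E/O = %.3f (%.3f-%.3f), E = %.1f, O = %d\n",
                cause, r$C, r$EO, r$EO_ci[1], r$EO_ci[2], r$E, r$O))
  }
  invisible(x)
}
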