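#' Simulate event histories under a generating model
#'
#' Draws, for each subject, a latent first-event time from the total
#' cause-specific hazard (two piecewise-constant tumour hazards plus the
#' Gompertz competing hazard) by inverse-CDF sampling: a unit exponential
#' deviate is compared segment by segment against the exact cumulative
#' hazard, where segments are the age-band cutoffs intersected with the
#' subject's at-risk window. Within the segment containing the event the
#' crossing time is solved on the exact cumulative hazard (bisection to
#' near machine precision; the piecewise part is linear and the Gompertz
#' part analytic, so the bracket is exact). The cause is then drawn with
#' probability proportional to the cause-specific hazards at the event
#' age, tumours are relabelled `"unknownER"` with the configured
#' probability, and exit is the earlier of the event age and the
#' administrative censoring age.
#'
#' @param cohort Cohort table with covariates and `entry_age` (e.g. from
#'   [generate_covariates()]).
#' @param truth Generating `erisk_model`; see [true_model()].
#' @param seed Integer seed.
#' @return The cohort with `exit_age` and `event` columns filled in.
#' @export
simulate_outcomes <- function(cohort, truth, seed = NULL) {
  stopifnot(inherits(truth, "erisk_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  spec <- truth$spec
  pw <- truth$piecewise
  alpha <- truth$gompertz$alpha
  gamma <- truth$gompertz$gamma
  cens <- truth$censoring

  lp <- linear_predictor(truth, cohort)
  r1 <- exp(lp[, 1L]); r2 <- exp(lp[, 2L])
  base <- exp(pw$baselines)            # n_bands x 2, hazards per year

  # all random draws up front so the stream is independent of outcomes
  fu <- stats::runif(n, cens$fu_min, cens$fu_max)
  E <- stats::rexp(n)
  u_cause <- stats::runif(n)
  u_unknown <- stats::runif(n)

  entry <- cohort$entry_age
  cens_age <- pmin(entry + fu, cens$age_cap)
  grid <- sort(unique(c(spec$cutoffs, min(entry), max(cens_age))))
  grid <- grid[grid >= min(entry) & grid <= max(cens_age)]
  if (grid[1L] > min(entry)) grid <- c(min(entry), grid)
  if (grid[length(grid)] < max(cens_age)) grid <- c(grid, max(cens_age))

  event_age <- rep(NA_real_, n)
  for (j in seq_len(length(grid) - 1L)) {
    g1 <- grid[j]; g2 <- grid[j + 1L]
    s1 <- pmax(entry, g1); s2 <- pmin(cens_age, g2)
    active <- is.na(event_age) & s2 > s1
    if (!any(active)) next
    i <- which(active)
    band <- age_band(0.5 * (g1 + g2), spec$cutoffs)
    lam <- base[band, 1L] * r1[i] + base[band, 2L] * r2[i]
    Hg <- gomp_cumhaz(alpha, gamma, s1[i], s2[i])
    Hseg <- lam * (s2[i] - s1[i]) + Hg
    hit <- E[i] <= Hseg
    if (any(hit)) {
      ih <- i[hit]
      event_age[ih] <- s1[ih] + solve_crossing(
        E[ih], lam[hit], alpha, gamma, s1[ih], s2[ih] - s1[ih])
    }
    E[i[!hit]] <- E[i[!hit]] - Hseg[!hit]
  }

  evented <- !is.na(event_age)
  exit <- ifelse(evented, event_age, cens_age)
  event <- rep("censored", n)
  if (any(evented)) {
    idx <- which(evented)
    band <- age_band(event_age[idx], spec$cutoffs)
    h1 <- base[band, 1L] * r1[idx]
    h2 <- base[band, 2L] * r2[idx]
    hg <- if (is.finite(alpha)) exp(alpha + gamma * event_age[idx]) else 0
    tot <- h1 + h2 + hg
    u <- u_cause[idx] * tot
    cause <- ifelse(u < h1, "ERpos", ifelse(u < h1 + h2, "ERneg",
                                            "competing"))
    tumour <- cause %in% tumour_causes()
    cause[tumour & u_unknown[idx] < truth$p_unknown] <- "unknownER"
    event[idx] <- cause
  }
  cohort$exit_age <- exit
  cohort$event <- event
  validate_cohort(cohort)
  cohort
}

#' @rdname simulate_outcomes
#' @param object Generating `erisk_model`.
#' @param nsim Number of cohorts to simulate (default 1).
#' @param ... Must contain `cohort`; extra arguments are ignored.
#' @return For `simulate.erisk_model`: a cohort (or list of `nsim`
#'   cohorts).
#' @export
simulate.erisk_model <- function(object, nsim = 1, seed = NULL, ...) {
  dots <- list(...)
  cohort <- dots$cohort
  if (is.null(cohort)) stop("supply a covariate cohort via cohort =")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i) simulate_outcomes(cohort, object))
  if (nsim == 1) out[[1L]] else out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: draws covariates with [generate_covariates()] and
#' event histories with [simulate_outcomes()] in one call.
#'
#' @param n Number of subjects.
#' @param truth Generating model (default [default_true_model()]).
#' @param config Covariate configuration (default
#'   [default_covariate_config()]).
#' @param seed Integer seed covering both stages.
#' @return A complete cohort table.
#' @export
simulate_cohort <- function(n, truth = default_true_model(),
                            config = default_covariate_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_outcomes(generate_covariates(n, config), truth)
}

# band index of an age under half-open, open-ended cutoffs
age_band <- function(age, cutoffs) findInterval(age, cutoffs) + 1L

# exact Gompertz cumulative hazard over [t1, t2]
gomp_cumhaz <- function(alpha, gamma, t1, t2) {
  if (!is.finite(alpha)) return(rep(0, length(t1)))
  if (abs(gamma) < 1e-12) return(exp(alpha) * (t2 - t1))
  exp(alpha + gamma * t1) * expm1(gamma * (t2 - t1)) / gamma
}

# Solve lam * s + Hg(t1, t1 + s) = target for s in (0, delta], vectorised
# bisection on a monotone increasing function with an exact bracket.
solve_crossing <- function(target, lam, alpha, gamma, t1, delta) {
  if (!is.finite(alpha)) return(target / lam)   # purely piecewise: linear
  lo <- rep(0, length(target)); hi <- delta
  for (it in 1:60) {
    mid <- 0.5 * (lo + hi)
    f <- lam * mid + gomp_cumhaz(alpha, gamma, t1, t1 + mid)
    below <- f < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  0.5 * (lo + hi)
}
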