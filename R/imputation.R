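#' Multiple imputation by chained equations
#'
#' Imputes missing covariate values by cycling variable-by-variable
#' conditional draws: multinomial-logistic models for categorical
#' variables and normal-linear models for continuous ones, each
#' conditioning on the other covariates, a tumour-event indicator and log
#' follow-up time. Imputations start from a random hot-deck fill and are
#' cycled `sweeps` times; the whole procedure is repeated `m` times with
#' seed offsets `seed + 1, ..., seed + m` to produce `m` completed
#' tables.
#'
#' Structural non-applicability is respected, not imputed: age at
#' menopause exists only for postmenopausal women and the parity block
#' only for parous women. When a parent variable (menopausal status,
#' parity) is itself imputed, the applicability of its dependents is
#' re-evaluated each sweep — rows that become applicable receive draws,
#' rows that become inapplicable revert to the structural `NA`. The
#' derived BMI-by-menopause code is recomputed, never imputed.
#' Continuous draws are truncated to the observed data range.
#'
#' @param cohort Cohort table with missing covariate values (`NA`).
#' @param m Number of imputations (default 5).
#' @param sweeps Chained-equation cycles per imputation (default 10).
#' @param seed Integer seed.
#' @return An object of class `erisk_mids`: list with `imputations` (m
#'   completed cohorts), `m`, `sweeps`, `seed`, `imputed_vars`.
#' @export
impute_chained <- function(cohort, m = 5L, sweeps = 10L, seed = 1L) {
  stopifnot(m >= 1, sweeps >= 1)
  if (!all(c("event", "exit_age") %in% names(cohort)) ||
      anyNA(cohort$event) || anyNA(cohort$exit_age))
    stop("event and follow-up columns must be present and complete")
  reg <- covariate_registry()
  names(reg) <- vapply(reg, `[[`, "", "name")
  reg <- reg[names(reg) %in% names(cohort)]
  reg <- reg[!vapply(reg, function(cv) isTRUE(cv$derived), TRUE)]
  # parents (applicability drivers) first, then the rest, fixed order
  ord <- unique(c(intersect(c("meno", "ftp"), names(reg)), names(reg)))
  reg <- reg[ord]

  applicable <- function(cv, data) {
    if (is.null(cv$applies_when)) rep(TRUE, nrow(data))
    else {
      p <- as.character(data[[cv$applies_when$var]])
      !is.na(p) & p == cv$applies_when$level
    }
  }
  # a cell is imputable if it is NA in the input *and* applicable given
  # the current (possibly imputed) parents; recomputed every sweep
  orig_na <- lapply(reg, function(cv) is.na(cohort[[cv$name]]))
  # a variable is an imputation target if any originally-missing cell is
  # applicable, or *might* become applicable once its (missing) parent is
  # imputed
  maybe_applicable <- function(cv, data) {
    if (is.null(cv$applies_when)) rep(TRUE, nrow(data))
    else {
      p <- as.character(data[[cv$applies_when$var]])
      is.na(p) | p == cv$applies_when$level
    }
  }
  target_vars <- names(reg)[vapply(names(reg), function(nm) {
    any(orig_na[[nm]] & maybe_applicable(reg[[nm]], cohort))
  }, TRUE)]
  fully_missing <- names(reg)[vapply(names(reg), function(nm) {
    app <- applicable(reg[[nm]], cohort)
    any(app) && all(is.na(cohort[[nm]][app]))
  }, TRUE)]
  if (length(fully_missing))
    stop("variable(s) 100% missing, unimputable: ",
         paste(fully_missing, collapse = ", "))

  aux <- data.frame(
    .tumour = as.numeric(cohort$event %in%
                           c(tumour_causes(), "unknownER")),
    .logfu = log(cohort$exit_age - cohort$entry_age)
  )
  predictors_for <- function(target) {
    setdiff(names(reg), target)
  }

  one_imputation <- function(s) {
    set.seed(s)
    data <- cohort
    # random hot-deck initialisation among observed applicable values
    for (nm in target_vars) {
      cv <- reg[[nm]]
      app <- applicable(cv, data)
      need <- orig_na[[nm]] & app
      pool <- data[[nm]][!is.na(cohort[[nm]])]
      data[[nm]][need] <- sample(pool, sum(need), replace = TRUE)
    }
    for (sw in seq_len(sweeps)) {
      for (nm in target_vars) {
        cv <- reg[[nm]]
        app <- applicable(cv, data)
        # structural consistency under the current parents: blank
        # inapplicable rows, reinstate observed values on applicable ones
        data[[nm]][!app] <- NA
        keep <- app & !orig_na[[nm]]
        data[[nm]][keep] <- cohort[[nm]][keep]
        need <- orig_na[[nm]] & app          # redrawn every sweep
        if (!any(need)) next
        obs <- !orig_na[[nm]] & app
        pred <- predictors_for(nm)
        Xfull <- cbind(impute_design(data, reg, pred), aux)
        df_obs <- cbind(Xfull[obs, , drop = FALSE],
                        .y = data[[nm]][obs])
        df_mis <- Xfull[need, , drop = FALSE]
        drawn <- impute_draw(cv, df_obs, df_mis, data[[nm]][obs])
        data[[nm]][need] <- drawn
      }
      if (all(c("meno", "bmi") %in% names(data)))
        data$bmi_meno <- derive_bmi_meno(data$meno, data$bmi)
    }
    data
  }

  imps <- lapply(seq_len(m), function(i) one_imputation(seed + i))
  structure(list(imputations = imps, m = m, sweeps = sweeps, seed = seed,
                 imputed_vars = target_vars),
            class = "erisk_mids")
}

# numeric predictor design for the conditional models; structural NAs and
# still-missing entries enter as the reference level (zero) so every row
# is usable
impute_design <- function(data, reg, vars) {
  cols <- list()
  for (nm in vars) {
    cv <- reg[[nm]]
    v <- data[[nm]]
    if (cv$type == "continuous") {
      x <- (as.numeric(v) - cv$center) / cv$scale
      x[is.na(x)] <- 0
      cols[[nm]] <- x
    } else {
      v <- as.character(v)
      for (lv in setdiff(cv$levels, cv$ref))
        cols[[paste0(nm, ".", lv)]] <- as.numeric(!is.na(v) & v == lv)
    }
  }
  as.data.frame(cols)
}

impute_draw <- function(cv, df_obs, df_mis, y_obs) {
  n_mis <- nrow(df_mis)
  if (cv$type == "continuous") {
    fit <- tryCatch(stats::lm(.y ~ ., data = df_obs),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("linear imputation model failed for '", cv$name,
              "'; falling back to marginal draws")
      return(sample(y_obs, n_mis, replace = TRUE))
    }
    mu <- stats::predict(fit, newdata = df_mis)
    sig <- stats::sigma(fit)
    out <- stats::rnorm(n_mis, mu, sig)
    pmin(pmax(out, min(y_obs)), max(y_obs))
  } else {
    y <- factor(as.character(y_obs), levels = cv$levels)
    y <- droplevels(y)
    if (nlevels(y) < 2)
      return(factor(sample(as.character(y), n_mis, replace = TRUE),
                    levels = cv$levels))
    fit <- tryCatch(
      suppressWarnings(nnet::multinom(.y ~ ., data = cbind(df_obs[
        setdiff(names(df_obs), ".y")], .y = y),
        trace = FALSE, maxit = 200, MaxNWts = 5000)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$convergence == 0)) {
      warning("multinomial imputation model did not converge for '",
              cv$name, "'; falling back to marginal draws")
      return(factor(sample(as.character(y), n_mis, replace = TRUE),
                    levels = cv$levels))
    }
    pr <- stats::predict(fit, newdata = df_mis, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr,
                                      deparse.level = 0)
    lev <- levels(y)
    idx <- apply(pr, 1L, function(p) sample.int(length(lev), 1L, prob = p))
    factor(lev[idx], levels = cv$levels)
  }
}

#' @export
print.erisk_mids <- function(x, ...) {
  cat("Chained-equations multiple imputation: m =", x$m,
      ", sweeps =", x$sweeps, "\n")
  cat("  imputed variables:", paste(x$imputed_vars, collapse = ", "), "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the arithmetic mean of the per-imputation
#' estimates; the total variance is the within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance; degrees of freedom
#' follow Barnard-Rubin (reducing to the classic
#' `(m - 1)(1 + W / ((1 + 1/m) B))^2` when the complete-data degrees of
#' freedom are infinite). With `m = 1` the between-variance is zero by
#' convention.
#'
#' @param estimates List of numeric coefficient vectors (congruent
#'   dimensions), or a matrix with one row per imputation.
#' @param variances List of variance vectors or covariance matrices
#'   (diagonals are used), congruent with `estimates`.
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @return An object of class `pooled_estimate` with `estimate`,
#'   `within`, `between`, `total`, `se`, `df`, `m`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  if (is.matrix(estimates)) estimates <- asplit(estimates, 1L)
  m <- length(estimates)
  if (m < 1) stop("need at least one estimate")
  p <- length(estimates[[1L]])
  if (!all(vapply(estimates, length, 0L) == p))
    stop("estimate dimensions are not congruent")
  vdiag <- lapply(variances, function(v) if (is.matrix(v)) diag(v) else v)
  if (length(vdiag) != m || !all(vapply(vdiag, length, 0L) == p))
    stop("variance dimensions are not congruent with the estimates")
  Q <- do.call(rbind, estimates)
  qbar <- colMeans(Q)
  W <- colMeans(do.call(rbind, vdiag))
  B <- if (m > 1) apply(Q, 2L, stats::var) else rep(0, p)
  total <- W + (1 + 1 / m) * B
  # Barnard-Rubin degrees of freedom
  df <- rep(Inf, p)
  if (m > 1) {
    r <- (1 + 1 / m) * B / W
    lam <- (1 + 1 / m) * B / total
    nu_old <- (m - 1) / pmax(lam, 1e-300)^2
    if (is.finite(dfcom)) {
      nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lam)
      df <- 1 / (1 / nu_old + 1 / nu_obs)
    } else df <- nu_old
    df[B == 0] <- Inf
  }
  structure(list(estimate = qbar, within = W, between = B, total = total,
                 se = sqrt(total), df = df, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat("Rubin-pooled estimate over m =", x$m, "imputations\n")
  print(data.frame(estimate = x$estimate, se = x$se, df = x$df))
  invisible(x)
}
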