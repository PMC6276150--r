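#' Fit the cause-specific piecewise-constant hazard model
#'
#' Maximum-likelihood estimation of the two-cause (ER+/ER-) model with
#' piecewise-constant baseline hazards over the spec's age bands and
#' covariate effects that are either shared across the two causes or
#' cause-specific, per the spec's sharing flags. The log-likelihood is the
#' piecewise-exponential (Poisson-equivalent) form
#' \deqn{\sum_k \sum_i d_{ik} (\log\lambda_{k,b(i)} + \beta_k' x_i)
#'       - T_i \lambda_{k,b(i)} e^{\beta_k' x_i},}
#' maximised jointly over both causes by Newton-Raphson. A shared
#' covariate is a single free parameter entering both causes' linear
#' predictors (aliasing, not post-hoc averaging — this is what makes
#' nested likelihood-ratio tests valid). Tumours with unknown ER status
#' count as competing events and contribute no ER-specific events.
#'
#' @param cohort Cohort table, or a pre-split episode table from
#'   [split_person_time()] (recognised by its `exposure` column; its bands
#'   must then match `spec$cutoffs`).
#' @param spec An `erisk_spec`; see [default_model_spec()].
#' @param tol Convergence tolerance on the gradient sup-norm (default
#'   1e-8).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return An object of class `piecewise_hazard` with the per-band
#'   per-cause log baseline hazards, the coefficient matrix (shared rows
#'   identical across causes), the free-parameter covariance from the
#'   observed information, and the maximised log-likelihood.
#' @seealso [fit_gompertz()], [erisk_fit()], [lrt_heterogeneity()]
#' @export
fit_piecewise <- function(cohort, spec = default_model_spec(),
                          tol = 1e-8, max_iter = 200L) {
  validate_model_spec(spec)
  pt <- if ("exposure" %in% names(cohort)) cohort
        else split_person_time(cohort, spec$cutoffs)
  causes <- spec$causes
  nb <- n_bands(spec)
  if (any(pt$band > nb)) stop("episode bands exceed the spec's cutoffs")

  Z <- build_design(pt, spec)
  if (anyNA(Z))
    stop("missing covariate values in the fitting data; impute first")
  blocks <- design_blocks(spec)
  ne <- nrow(pt)
  band <- pt$band
  Texp <- pt$exposure
  d1 <- as.numeric(pt$event == causes[1L])
  d2 <- as.numeric(pt$event == causes[2L])
  events_by_cause <- c(sum(d1), sum(d2))
  if (any(events_by_cause == 0))
    stop("at least one event per cause is required (",
         paste(causes, events_by_cause, sep = ": ", collapse = ", "), ")")

  # drop design columns never observed (empty categories)
  keep_col <- colSums(abs(Z)) > 0
  if (!all(keep_col))
    warning("dropping empty design column(s): ",
            paste(colnames(Z)[!keep_col], collapse = ", "))
  sh_cols <- intersect(blocks$shared, colnames(Z)[keep_col])
  sp_cols <- intersect(blocks$specific, colnames(Z)[keep_col])
  Zs <- Z[, sh_cols, drop = FALSE]
  Zc <- Z[, sp_cols, drop = FALSE]
  p_s <- length(sh_cols); p_c <- length(sp_cols)

  # baseline cells (cause x band); cells without events or exposure are
  # pinned to log-hazard -30 and excluded from the free parameters
  bf <- factor(band, levels = seq_len(nb))
  cell_d <- c(as.vector(tapply(d1, bf, sum, default = 0)),
              as.vector(tapply(d2, bf, sum, default = 0)))
  cell_T <- rep(as.vector(tapply(Texp, bf, sum, default = 0)), 2L)
  pinned <- cell_d == 0 | cell_T == 0
  if (any(pinned & cell_T > 0))
    warning(sum(pinned & cell_T > 0),
            " baseline cell(s) without events pinned to log-hazard -30")
  cell_names <- paste0(rep(causes, each = nb), ":band",
                       rep(seq_len(nb), 2L))
  free_cells <- which(!pinned)
  nf <- length(free_cells)

  par_names <- c(cell_names[free_cells], sh_cols,
                 if (p_c) paste0(causes[1L], ":", sp_cols),
                 if (p_c) paste0(causes[2L], ":", sp_cols))
  np <- length(par_names)
  # index maps into the parameter vector
  ix_base <- seq_len(nf)
  ix_s <- nf + seq_len(p_s)
  ix_c1 <- nf + p_s + seq_len(p_c)
  ix_c2 <- nf + p_s + p_c + seq_len(p_c)

  # deterministic start: per-cause crude log rates, zero coefficients
  theta <- numeric(np)
  names(theta) <- par_names
  py <- sum(Texp)
  theta[ix_base] <- log(events_by_cause / py)[(free_cells - 1L) %/% nb + 1L]

  basevec <- function(th) {
    bv <- matrix(-30, nb, 2L)
    bv[free_cells] <- th[ix_base]
    bv
  }
  etas <- function(th) {
    bv <- basevec(th)
    lp_s <- if (p_s) drop(Zs %*% th[ix_s]) else 0
    eta1 <- bv[band, 1L] + lp_s +
      (if (p_c) drop(Zc %*% th[ix_c1]) else 0)
    eta2 <- bv[band, 2L] + lp_s +
      (if (p_c) drop(Zc %*% th[ix_c2]) else 0)
    cbind(eta1, eta2)
  }
  ll_fun <- function(th) {
    eta <- etas(th)
    sum(d1 * eta[, 1L] + d2 * eta[, 2L]) -
      sum(Texp * (exp(eta[, 1L]) + exp(eta[, 2L])))
  }

  ll <- ll_fun(theta)
  converged <- FALSE
  info <- function(th) {
    eta <- etas(th)
    mu1 <- Texp * exp(eta[, 1L]); mu2 <- Texp * exp(eta[, 2L])
    # gradient
    g_b1 <- as.vector(tapply(d1 - mu1, bf, sum, default = 0))
    g_b2 <- as.vector(tapply(d2 - mu2, bf, sum, default = 0))
    grad <- numeric(np)
    grad[ix_base] <- c(g_b1, g_b2)[free_cells]
    r12 <- (d1 - mu1) + (d2 - mu2)
    if (p_s) grad[ix_s] <- drop(crossprod(Zs, r12))
    if (p_c) {
      grad[ix_c1] <- drop(crossprod(Zc, d1 - mu1))
      grad[ix_c2] <- drop(crossprod(Zc, d2 - mu2))
    }
    # observed information
    H <- matrix(0, np, np)
    s_b1 <- as.vector(tapply(mu1, bf, sum, default = 0))
    s_b2 <- as.vector(tapply(mu2, bf, sum, default = 0))
    diag(H)[ix_base] <- c(s_b1, s_b2)[free_cells]
    Ms1 <- if (p_s) rowsum(Zs * mu1, band) else NULL
    Ms2 <- if (p_s) rowsum(Zs * mu2, band) else NULL
    Mc1 <- if (p_c) rowsum(Zc * mu1, band) else NULL
    Mc2 <- if (p_c) rowsum(Zc * mu2, band) else NULL
    band_of <- function(M) {
      # rowsum indexes by sorted unique band; expand to nb rows
      out <- matrix(0, nb, ncol(M))
      out[as.integer(rownames(M)), ] <- M
      out
    }
    for (j in seq_len(nf)) {
      k <- (free_cells[j] - 1L) %/% nb + 1L
      b <- free_cells[j] - (k - 1L) * nb
      if (p_s) {
        M <- if (k == 1L) band_of(Ms1) else band_of(Ms2)
        H[j, ix_s] <- H[ix_s, j] <- M[b, ]
      }
      if (p_c) {
        M <- if (k == 1L) band_of(Mc1) else band_of(Mc2)
        ixk <- if (k == 1L) ix_c1 else ix_c2
        H[j, ixk] <- H[ixk, j] <- M[b, ]
      }
    }
    if (p_s)
      H[ix_s, ix_s] <- crossprod(Zs, Zs * (mu1 + mu2))
    if (p_c) {
      H[ix_c1, ix_c1] <- crossprod(Zc, Zc * mu1)
      H[ix_c2, ix_c2] <- crossprod(Zc, Zc * mu2)
      if (p_s) {
        H[ix_s, ix_c1] <- crossprod(Zs, Zc * mu1)
        H[ix_c1, ix_s] <- t(H[ix_s, ix_c1])
        H[ix_s, ix_c2] <- crossprod(Zs, Zc * mu2)
        H[ix_c2, ix_s] <- t(H[ix_s, ix_c2])
      }
    }
    list(grad = grad, H = H)
  }

  for (iter in seq_len(max_iter)) {
    gi <- info(theta)
    if (max(abs(gi$grad)) <= tol) { converged <- TRUE; break }
    step <- tryCatch(solve(gi$H, gi$grad), error = function(e)
      stop("singular information matrix; check the design for aliasing"))
    # trust region: cap the step length so that a parameter running to
    # -Inf (zero-event category) walks there in a few bounded moves
    # instead of triggering endless step-halving
    smax <- max(abs(step))
    if (smax > 5) step <- step * (5 / smax)
    if (max(abs(gi$grad)) <= 1e-3) {
      # quadratic regime: the true per-step gain can fall below the
      # floating-point resolution of the log-likelihood, so take the
      # pure Newton step instead of insisting on a certified ascent
      cand <- theta + step
      ll_new <- ll_fun(cand)
      ok <- is.finite(ll_new)
    } else {
      ok <- FALSE
      for (h in 0:25) {                     # step-halving ascent guard
        cand <- theta + step / 2^h
        ll_new <- ll_fun(cand)
        if (is.finite(ll_new) && ll_new >= ll - 1e-12) { ok <- TRUE; break }
      }
    }
    if (!ok) break
    moved <- sqrt(sum((cand - theta)^2))
    theta <- cand; ll <- ll_new
    if (moved < 1e-13 && max(abs(gi$grad)) <= 1e-6) {
      converged <- TRUE; break
    }
  }
  gi <- info(theta)
  if (!converged) {
    if (max(abs(gi$grad)) <= 1e-6) converged <- TRUE
    else stop("Newton-Raphson did not converge after ", max_iter,
              " iterations (gradient sup-norm ",
              format(max(abs(gi$grad))), ")")
  }
  vc <- solve(gi$H)
  dimnames(vc) <- list(par_names, par_names)

  # unpack into per-cause baseline and coefficient matrices
  baselines <- basevec(theta)
  dimnames(baselines) <- list(paste0("band", seq_len(nb)), causes)
  all_cols <- c(blocks$shared, blocks$specific)
  beta <- matrix(NA_real_, length(all_cols), 2L,
                 dimnames = list(all_cols, causes))
  beta_se <- beta
  se_all <- sqrt(pmax(diag(vc), 0))
  names(se_all) <- par_names
  for (cn in sh_cols) {
    beta[cn, ] <- theta[cn]
    beta_se[cn, ] <- se_all[cn]
  }
  for (k in 1:2) for (cn in sp_cols) {
    pn <- paste0(causes[k], ":", cn)
    beta[cn, k] <- theta[pn]
    beta_se[cn, k] <- se_all[pn]
  }
  dropped <- setdiff(all_cols, c(sh_cols, sp_cols))
  beta[dropped, ] <- 0

  structure(list(
    spec = spec, cutoffs = spec$cutoffs, causes = causes,
    baselines = baselines, coefficients = beta, coefficient_se = beta_se,
    par = theta, vcov = vc, loglik = ll,
    n_free = np, iterations = iter, converged = converged,
    events = stats::setNames(events_by_cause, causes),
    person_years = py,
    pinned_cells = cell_names[pinned]
  ), class = "piecewise_hazard")
}

#' @export
print.piecewise_hazard <- function(x, ...) {
  cat("Cause-specific piecewise-constant hazard model\n")
  cat("  events:      ", paste(names(x$events), x$events, sep = " = ",
                               collapse = ", "), "\n")
  cat("  person-years:", format(round(x$person_years)), "\n")
  cat("  bands:       ", nrow(x$baselines),
      " (cutoffs ", paste(x$cutoffs, collapse = ", "), ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik), " (", x$n_free,
      " free parameters)\n", sep = "")
  cat("\nHazard ratios:\n")
  print(round(exp(x$coefficients), 3))
  invisible(x)
}

#' @export
coef.piecewise_hazard <- function(object, ...) object$coefficients

#' @export
vcov.piecewise_hazard <- function(object, ...) object$vcov

#' @export
logLik.piecewise_hazard <- function(object, ...) {
  structure(object$loglik, df = object$n_free, class = "logLik")
}

#' @export
summary.piecewise_hazard <- function(object, ...) {
  hr <- exp(object$coefficients)
  se <- object$coefficient_se
  lo <- exp(object$coefficients - 1.96 * se)
  hi <- exp(object$coefficients + 1.96 * se)
  out <- data.frame(
    term = rownames(hr),
    HR_ERpos = hr[, 1], lo_ERpos = lo[, 1], hi_ERpos = hi[, 1],
    HR_ERneg = hr[, 2], lo_ERneg = lo[, 2], hi_ERneg = hi[, 2],
    shared = rownames(hr) %in% design_blocks(object$spec)$shared,
    row.names = NULL
  )
  class(out) <- c("summary.piecewise_hazard", "data.frame")
  out
}

#' Likelihood-ratio test for heterogeneity by ER status
#'
#' Compares a model in which one or more covariates carry cause-specific
#' coefficients (the free model) with a nested model in which they are
#' shared across ER+/ER- (the constrained model), both fitted to the same
#' data. The statistic is `2 * (logLik_free - logLik_constrained)` with
#' degrees of freedom equal to the difference in free parameter count,
#' referred to the upper tail of the chi-square distribution.
#'
#' @param free Fitted `piecewise_hazard` with the covariate(s) of interest
#'   cause-specific.
#' @param constrained Fitted `piecewise_hazard` with them shared; must be
#'   nested in `free`.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
lrt_heterogeneity <- function(free, constrained) {
  stopifnot(inherits(free, "piecewise_hazard"),
            inherits(constrained, "piecewise_hazard"))
  df <- free$n_free - constrained$n_free
  if (df < 1)
    stop("models are not nested: the free model must have more parameters")
  if (!setequal(rownames(free$coefficients),
                rownames(constrained$coefficients)) ||
      !identical(free$cutoffs, constrained$cutoffs))
    stop("models are not nested: specs differ beyond the sharing flags")
  stat <- 2 * (free$loglik - constrained$loglik)
  if (stat < -1e-6)
    stop("negative likelihood-ratio statistic (", format(stat),
         "): optimisation failure")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
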