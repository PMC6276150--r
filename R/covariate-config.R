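#' Default covariate configuration for synthetic cohorts
#'
#' Marginal category probabilities, the continuous height distribution, the
#' stratum (country) weights and the entry-age window used by
#' [generate_covariates()]. The categorical codings mirror the model
#' specification; dependent variables (age at menopause, breastfeeding and
#' the parity block) are generated only for the subjects to whom they
#' apply. Probabilities were chosen to resemble a large European
#' recruitment wave of women aged 40-70 (about half postmenopausal, 85%
#' parous, 40% ever-users of hormone replacement therapy); they are
#' plausible rather than cohort-faithful, and every entry can be
#' overridden.
#'
#' @param postmenopausal Marginal probability of being postmenopausal at
#'   recruitment (default 0.51).
#' @return An object of class `erisk_covariate_config`: a list with one
#'   element per generated variable. Categorical entries are named
#'   probability vectors; `height` has `mean` and `sd` in cm;
#'   `entry_age` has `min` and `max` in years.
#' @export
default_covariate_config <- function(postmenopausal = 0.51) {
  cfg <- list(
    entry_age = list(min = 40, max = 70),
    meno = c(pre = 1 - postmenopausal, post = postmenopausal),
    age_menopause = c(le45 = 0.30, "45to50" = 0.35, "50to55" = 0.28,
                      gt55 = 0.07),
    menarche = c(le11 = 0.18, "12" = 0.24, "13" = 0.26, "14" = 0.17,
                 ge15 = 0.15),
    hrt = c("0" = 0.60, "0.1to1" = 0.10, "1.1to2" = 0.08, "2.1to3" = 0.06,
            gt3 = 0.16),
    bmi = c(lt25 = 0.54, "25to30" = 0.31, "30to35" = 0.10, ge35 = 0.05),
    alcohol = c("0" = 0.30, lt1 = 0.45, "1to2" = 0.15, ge2 = 0.10),
    ftp = c(no = 0.15, yes = 0.85),
    n_ftp = c("1" = 0.25, "2" = 0.45, ge3 = 0.30),
    age_ftp = c(le20 = 0.25, "20to25" = 0.45, "25to30" = 0.22,
                "30to35" = 0.06, gt35 = 0.02),
    breastfeeding = c("0" = 0.30, "0.1to6" = 0.35, "6.1to12" = 0.20,
                      gt12 = 0.15),
    height = list(mean = 163, sd = 6.5),
    country = c(A = 0.35, B = 0.30, C = 0.20, D = 0.15)
  )
  structure(cfg, class = "erisk_covariate_config")
}

#' Validate a covariate configuration
#'
#' Each categorical probability vector must be non-negative and sum to 1
#' within 1e-12; the error message names the offending variable.
#'
#' @param config An `erisk_covariate_config` (or plain list of the same
#'   shape).
#' @return `config`, invisibly; errors otherwise.
#' @export
validate_covariate_config <- function(config) {
  for (nm in names(config)) {
    p <- config[[nm]]
    if (!is.numeric(p) || nm %in% c("entry_age", "height")) next
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("invalid probability vector for variable '", nm,
           "': entries must be non-negative and sum to 1")
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop("probability vector for variable '", nm, "' must be named")
  }
  if (!is.null(config$entry_age) &&
      config$entry_age$min >= config$entry_age$max)
    stop("invalid probability vector for variable 'entry_age': min >= max")
  if (!is.null(config$height) && config$height$sd <= 0)
    stop("height standard deviation must be positive")
  invisible(config)
}

draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Generate cohort covariates
#'
#' Draws `n` subjects with entry ages uniform on the configured window and
#' covariates from the configured marginals, honouring the structural
#' dependencies: age at menopause exists only for postmenopausal women;
#' the parity block (number of full-term pregnancies, age at first FTP,
#' breastfeeding) exists only for parous women; the BMI-by-menopause
#' interaction (coded 0-3) is derived from menopausal status and the BMI
#' category. Structural non-applicability is encoded as `NA` and is
#' distinct from missingness injected later.
#'
#' @param n Number of subjects (>= 1).
#' @param config Covariate configuration; see
#'   [default_covariate_config()].
#' @param seed Integer seed; fixed seed gives an identical table.
#' @return A `data.frame` cohort table without event columns: `id`,
#'   `entry_age`, the covariates, and `country`.
#' @examples
#' head(generate_covariates(5, seed = 1))
#' @export
generate_covariates <- function(n, config = default_covariate_config(),
                                seed = NULL) {
  stopifnot(n >= 1)
  validate_covariate_config(config)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(
    id = seq_len(n),
    entry_age = stats::runif(n, config$entry_age$min, config$entry_age$max)
  )
  out$meno <- draw_cat(n, config$meno)
  out$age_menopause <- draw_cat(n, config$age_menopause)
  out$age_menopause[out$meno != "post"] <- NA
  out$menarche <- draw_cat(n, config$menarche)
  out$hrt <- draw_cat(n, config$hrt)
  out$bmi <- draw_cat(n, config$bmi)
  out$alcohol <- draw_cat(n, config$alcohol)
  out$ftp <- draw_cat(n, config$ftp)
  parous <- out$ftp == "yes"
  out$n_ftp <- draw_cat(n, config$n_ftp)
  out$n_ftp[!parous] <- NA
  out$age_ftp <- draw_cat(n, config$age_ftp)
  out$age_ftp[!parous] <- NA
  out$breastfeeding <- draw_cat(n, config$breastfeeding)
  out$breastfeeding[!parous] <- NA
  out$height <- stats::rnorm(n, config$height$mean, config$height$sd)
  out$country <- draw_cat(n, config$country)
  out$bmi_meno <- derive_bmi_meno(out$meno, out$bmi)
  out
}

#' Derive the BMI-by-menopause interaction code
#'
#' Code 0: premenopausal, or postmenopausal with BMI < 25; codes 1-3:
#' postmenopausal with BMI 25-30, 30-35, >= 35.
#'
#' @param meno Factor/character of menopausal status (`"pre"`/`"post"`).
#' @param bmi Factor/character BMI category
#'   (`"lt25"`, `"25to30"`, `"30to35"`, `"ge35"`).
#' @return Factor with levels `"0"`-`"3"`; `NA` where either input is
#'   missing.
#' @export
derive_bmi_meno <- function(meno, bmi) {
  meno <- as.character(meno); bmi <- as.character(bmi)
  code <- ifelse(meno == "pre", "0",
                 c(lt25 = "0", "25to30" = "1", "30to35" = "2",
                   ge35 = "3")[bmi])
  code[is.na(meno) | is.na(bmi)] <- NA
  factor(code, levels = c("0", "1", "2", "3"))
}

#' Inject missing values into covariates
#'
#' Masks covariate values at the requested per-variable rates, either
#' completely at random (MCAR) or with probability increasing in entry age
#' (MAR-on-age, logistic in standardised age with slope 1 and intercept
#' calibrated so the marginal rate equals the requested rate). Event and
#' follow-up columns are never masked, and structurally non-applicable
#' entries are left untouched (they are already `NA` and are not
#' "missing"). The derived `bmi_meno` column is re-derived after masking
#' so that it is missing exactly when one of its parents is.
#'
#' @param cohort Cohort table.
#' @param rates Named numeric vector of per-variable missingness
#'   probabilities in `[0, 1]`, e.g. `c(hrt = 0.3, bmi = 0.1)`.
#' @param mechanism `"MCAR"` or `"MAR-age"`.
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rates, mechanism = c("MCAR", "MAR-age"),
                               seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]")
  protected <- c("id", "entry_age", "exit_age", "event", "bmi_meno")
  bad <- intersect(names(rates), protected)
  if (length(bad))
    stop("cannot mask protected column(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r == 0) next
    if (!nm %in% names(cohort)) stop("no such column: ", nm)
    if (mechanism == "MCAR") {
      p <- rep(r, n)
    } else {
      z <- as.numeric(scale(cohort$entry_age))
      # calibrate the intercept so mean(plogis(a + z)) == r
      a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - r,
                          c(-30, 30))$root
      p <- stats::plogis(a + z)
    }
    mask <- stats::runif(n) < p
    cohort[[nm]][mask] <- NA
  }
  if (all(c("meno", "bmi") %in% names(cohort)))
    cohort$bmi_meno <- derive_bmi_meno(cohort$meno, cohort$bmi)
  cohort
}

#' Validate a cohort table
#'
#' Checks the core schema: positive follow-up (`exit_age > entry_age`),
#' event codes from the closed vocabulary, and the structural rule that
#' premenopausal rows carry no age at menopause.
#'
#' @param cohort Cohort table (data.frame).
#' @param require_events If `TRUE` (default) `exit_age` and `event` must be
#'   present; covariate-only tables pass with `FALSE`.
#' @return `cohort`, invisibly; errors otherwise.
#' @export
validate_cohort <- function(cohort, require_events = TRUE) {
  stopifnot(is.data.frame(cohort), "entry_age" %in% names(cohort))
  if (require_events) {
    if (!all(c("exit_age", "event") %in% names(cohort)))
      stop("cohort lacks exit_age/event columns")
    if (any(cohort$exit_age <= cohort$entry_age))
      stop("exit_age must exceed entry_age for every subject")
    if (!all(cohort$event %in% event_codes()))
      stop("event codes outside the fixed vocabulary")
  }
  if (all(c("meno", "age_menopause") %in% names(cohort))) {
    bad <- !is.na(cohort$age_menopause) & !is.na(cohort$meno) &
      cohort$meno == "pre"
    if (any(bad))
      stop("premenopausal rows must not carry an age at menopause")
  }
  invisible(cohort)
}

#' Read / write cohort CSV files
#'
#' Cohort tables are exchanged as plain CSV with a header row; categorical
#' covariates are re-levelled against the built-in coding on read.
#'
#' @param path File path.
#' @param cohort Cohort table.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reg <- covariate_registry()
  for (cv in reg) {
    if (cv$type == "categorical" && cv$name %in% names(df))
      df[[cv$name]] <- factor(as.character(df[[cv$name]]),
                              levels = cv$levels)
  }
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
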