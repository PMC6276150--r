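#' Event codes used in cohort tables
#'
#' The closed vocabulary for the `event` column of a cohort table:
#' `"ERpos"` and `"ERneg"` are first primary breast tumours of known
#' estrogen-receptor status, `"unknownER"` is a breast tumour whose ER
#' status was not recorded, `"competing"` pools primary cancers at other
#' sites and deaths from non-cancer causes, and `"censored"` marks
#' administrative end of follow-up. Tumours with unknown ER status are
#' treated as competing events throughout: they never contribute
#' ER-specific events.
#'
#' @return Character vector of the five event codes.
#' @export
event_codes <- function() {
  c("ERpos", "ERneg", "unknownER", "competing", "censored")
}

#' Tumour causes modelled cause-specifically
#' @return Character vector `c("ERpos", "ERneg")`.
#' @export
tumour_causes <- function() c("ERpos", "ERneg")

# Internal registry of the model covariates: coding, reference level,
# whether the coefficient is shared across ER strata by default, structural
# applicability rule, and the ground-truth log hazard ratios used by the
# default generating model (EPIC-style estimates; cause order ERpos, ERneg).
covariate_registry <- function() {
  list(
    list(name = "meno", type = "categorical",
         levels = c("pre", "post"), ref = "pre", shared = TRUE,
         truth = list(post = c(log(0.66), log(0.66)))),
    list(name = "age_menopause", type = "categorical",
         levels = c("le45", "45to50", "50to55", "gt55"), ref = "le45",
         shared = TRUE, applies_when = list(var = "meno", level = "post"),
         truth = list("45to50" = rep(log(1.16), 2),
                      "50to55" = rep(log(1.25), 2),
                      "gt55"   = rep(log(1.41), 2))),
    list(name = "menarche", type = "categorical",
         levels = c("le11", "12", "13", "14", "ge15"), ref = "le11",
         shared = TRUE,
         truth = list("12" = rep(log(1.06), 2), "13" = rep(log(1.00), 2),
                      "14" = rep(log(0.97), 2), "ge15" = rep(log(0.85), 2))),
    list(name = "hrt", type = "categorical",
         levels = c("0", "0.1to1", "1.1to2", "2.1to3", "gt3"), ref = "0",
         shared = TRUE,
         truth = list("0.1to1" = rep(log(1.17), 2),
                      "1.1to2" = rep(log(1.27), 2),
                      "2.1to3" = rep(log(1.39), 2),
                      "gt3"    = rep(log(1.55), 2))),
    list(name = "breastfeeding", type = "categorical",
         levels = c("0", "0.1to6", "6.1to12", "gt12"), ref = "0",
         shared = TRUE, applies_when = list(var = "ftp", level = "yes"),
         truth = list("0.1to6" = rep(log(1.01), 2),
                      "6.1to12" = rep(log(0.96), 2),
                      "gt12"   = rep(log(1.01), 2))),
    list(name = "bmi", type = "categorical",
         levels = c("lt25", "25to30", "30to35", "ge35"), ref = "lt25",
         shared = TRUE,
         truth = list("25to30" = rep(log(0.99), 2),
                      "30to35" = rep(log(0.97), 2),
                      "ge35"   = rep(log(1.12), 2))),
    # BMI x menopause interaction, coded 0-3: 0 premenopausal or
    # postmenopausal with BMI < 25; 1/2/3 postmenopausal with BMI
    # 25-30 / 30-35 / >= 35. Derived from meno and bmi, never generated
    # or imputed directly.
    list(name = "bmi_meno", type = "categorical",
         levels = c("0", "1", "2", "3"), ref = "0",
         shared = TRUE, derived = TRUE,
         truth = list("1" = rep(log(1.11), 2),
                      "2" = rep(log(1.26), 2),
                      "3" = rep(log(1.17), 2))),
    list(name = "alcohol", type = "categorical",
         levels = c("0", "lt1", "1to2", "ge2"), ref = "0",
         shared = TRUE,
         truth = list("lt1" = rep(log(1.00), 2),
                      "1to2" = rep(log(1.14), 2),
                      "ge2"  = rep(log(1.22), 2))),
    # Parity block: heterogeneous by ER status. The parous reference
    # profile is a single full-term pregnancy at age <= 20.
    list(name = "ftp", type = "categorical",
         levels = c("no", "yes"), ref = "no", shared = FALSE,
         truth = list(yes = c(log(0.81), log(0.97)))),
    list(name = "n_ftp", type = "categorical",
         levels = c("1", "2", "ge3"), ref = "1", shared = FALSE,
         applies_when = list(var = "ftp", level = "yes"),
         truth = list("2" = c(log(0.99), log(1.05)),
                      "ge3" = c(log(0.87), log(0.95)))),
    list(name = "age_ftp", type = "categorical",
         levels = c("le20", "20to25", "25to30", "30to35", "gt35"),
         ref = "le20", shared = FALSE,
         applies_when = list(var = "ftp", level = "yes"),
         truth = list("20to25" = c(log(1.05), log(1.04)),
                      "25to30" = c(log(1.20), log(0.93)),
                      "30to35" = c(log(1.32), log(0.96)),
                      "gt35"   = c(log(1.46), log(0.91)))),
    # Height enters the linear predictor per 10-cm increment, centred
    # at 160 cm so that the baseline hazard refers to a 160-cm woman.
    list(name = "height", type = "continuous", shared = FALSE,
         center = 160, scale = 10,
         truth = list(height = c(log(1.19), log(1.06)))),
    # Country of recruitment: the stratum variable, always cause-specific.
    list(name = "country", type = "categorical",
         levels = c("A", "B", "C", "D"), ref = "A", shared = FALSE,
         stratum = TRUE,
         truth = list(B = c(0.15, -0.05), C = c(-0.10, 0.10),
                      D = c(0.25, 0.20)))
  )
}

#' Model specification for the cause-specific piecewise hazard model
#'
#' A model specification lists the covariates with their category codings
#' and reference levels, flags each covariate as shared across the ER+/ER-
#' causes or cause-specific, and fixes the age-band cutoffs of the
#' piecewise-constant baseline hazard.
#'
#' @param cutoffs Increasing numeric vector of age cutoffs delimiting the
#'   baseline-hazard bands. The first band is open below and the last open
#'   above. Default `c(45, 50, 55, 60, 65, 70, 75)`.
#' @param covariates Character vector naming the covariates to include,
#'   from the built-in registry. Defaults to all of them.
#' @param shared Optional named logical vector overriding the per-covariate
#'   sharing flag (`TRUE` = one coefficient for both causes). The stratum
#'   variable (`country`) is always cause-specific and cannot be shared.
#' @return An object of class `erisk_spec`.
#' @examples
#' sp <- default_model_spec()
#' sp$cutoffs
#' @export
default_model_spec <- function(cutoffs = c(45, 50, 55, 60, 65, 70, 75),
                               covariates = NULL,
                               shared = NULL) {
  reg <- covariate_registry()
  names(reg) <- vapply(reg, `[[`, "", "name")
  if (is.null(covariates)) covariates <- names(reg)
  missing_cov <- setdiff(covariates, names(reg))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  reg <- reg[covariates]
  if (!is.null(shared)) {
    for (nm in names(shared)) {
      if (!nm %in% names(reg)) next
      if (isTRUE(reg[[nm]]$stratum) && isTRUE(shared[[nm]]))
        stop("the stratum variable '", nm, "' is always cause-specific")
      reg[[nm]]$shared <- isTRUE(shared[[nm]])
    }
  }
  new_model_spec(cutoffs, reg)
}

new_model_spec <- function(cutoffs, covariates) {
  spec <- structure(list(cutoffs = as.numeric(cutoffs),
                         causes = tumour_causes(),
                         covariates = covariates),
                    class = "erisk_spec")
  validate_model_spec(spec)
  spec
}

#' Validate a model specification
#'
#' Checks that cutoffs are strictly increasing, that every categorical
#' covariate's reference level is among its levels, and that sharing flags
#' are well formed.
#'
#' @param spec An `erisk_spec`.
#' @return `spec`, invisibly; errors otherwise.
#' @export
validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "erisk_spec"))
  co <- spec$cutoffs
  if (length(co) && any(diff(co) <= 0))
    stop("age-band cutoffs must be strictly increasing")
  for (cv in spec$covariates) {
    if (cv$type == "categorical") {
      if (!cv$ref %in% cv$levels)
        stop("reference level '", cv$ref, "' not among the levels of '",
             cv$name, "'")
      if (length(cv$levels) < 2)
        stop("covariate '", cv$name, "' needs at least two levels")
    }
    if (!is.logical(cv$shared))
      stop("sharing flag for '", cv$name, "' must be logical")
  }
  invisible(spec)
}

#' @export
print.erisk_spec <- function(x, ...) {
  cat("Cause-specific piecewise hazard model specification\n")
  cat("  causes:  ", paste(x$causes, collapse = ", "), "\n")
  cat("  cutoffs: ", paste(x$cutoffs, collapse = ", "), "\n")
  sh <- vapply(x$covariates, function(cv) cv$shared, TRUE)
  nm <- vapply(x$covariates, function(cv) cv$name, "")
  cat("  shared coefficients:        ",
      paste(nm[sh], collapse = ", "), "\n")
  cat("  cause-specific coefficients:",
      paste(nm[!sh], collapse = ", "), "\n")
  invisible(x)
}

# Number of baseline-hazard age bands implied by the cutoffs.
n_bands <- function(spec) length(spec$cutoffs) + 1L

# Names of the non-reference design columns of one covariate.
design_cols <- function(cv) {
  if (cv$type == "continuous") return(cv$name)
  paste0(cv$name, ":", setdiff(cv$levels, cv$ref))
}

# Build the covariate design matrix (one row per data row, reference-level
# coding). Structurally non-applicable rows (e.g. age at menopause for
# premenopausal women) contribute the reference level, i.e. all zeros.
# Missing values propagate NA so that fitting can refuse incomplete data.
build_design <- function(data, spec) {
  cols <- list()
  for (cv in spec$covariates) {
    v <- data[[cv$name]]
    if (is.null(v)) stop("cohort lacks covariate column '", cv$name, "'")
    if (cv$type == "continuous") {
      x <- (as.numeric(v) - cv$center) / cv$scale
      cols[[cv$name]] <- x
    } else {
      v <- as.character(v)
      bad <- !is.na(v) & !v %in% cv$levels
      if (any(bad))
        stop("covariate '", cv$name, "' has categories outside its coding: ",
             paste(utils::head(unique(v[bad])), collapse = ", "))
      applicable <- rep(TRUE, length(v))
      if (!is.null(cv$applies_when)) {
        parent <- as.character(data[[cv$applies_when$var]])
        applicable <- !is.na(parent) & parent == cv$applies_when$level
      }
      for (lv in setdiff(cv$levels, cv$ref)) {
        x <- as.numeric(!is.na(v) & v == lv)
        x[applicable & is.na(v)] <- NA_real_
        x[!applicable] <- 0
        cols[[paste0(cv$name, ":", lv)]] <- x
      }
    }
  }
  do.call(cbind, cols)
}

# Split design-column names into the shared block and the cause-specific
# block, per the spec's sharing flags.
design_blocks <- function(spec) {
  shared <- character(0); specific <- character(0)
  for (cv in spec$covariates) {
    nm <- design_cols(cv)
    if (cv$shared) shared <- c(shared, nm) else specific <- c(specific, nm)
  }
  list(shared = shared, specific = specific)
}

#' Ground-truth coefficient matrix of the built-in registry
#'
#' Returns the log hazard ratios (design columns x causes) that the
#' default generating model uses as simulation ground truth: EPIC-style
#' estimates with shared effects for the homogeneous risk factors and
#' cause-specific effects for the parity block, height and country.
#'
#' @param spec An `erisk_spec`.
#' @return Numeric matrix with one row per design column and one column
#'   per cause.
#' @export
truth_coefficients <- function(spec) {
  blocks <- design_blocks(spec)
  all_cols <- c(blocks$shared, blocks$specific)
  beta <- matrix(0, nrow = length(all_cols), ncol = length(spec$causes),
                 dimnames = list(all_cols, spec$causes))
  for (cv in spec$covariates) {
    if (is.null(cv$truth)) next
    if (cv$type == "continuous") {
      beta[cv$name, ] <- cv$truth[[1L]]
    } else {
      for (lv in names(cv$truth)) {
        cn <- paste0(cv$name, ":", lv)
        if (cn %in% all_cols) beta[cn, ] <- cv$truth[[lv]]
      }
    }
  }
  beta
}
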