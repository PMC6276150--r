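#' Serialize / restore models as JSON
#'
#' A fitted or generating `erisk_model` round-trips through a plain JSON
#' document holding the cutoffs, per-cause log baseline hazards,
#' coefficient matrix, sharing flags, Gompertz parameters, and (for
#' generating models) the unknown-ER probability and censoring rule.
#' Covariance matrices are included when present.
#'
#' @param model An `erisk_model`.
#' @param path Output/input file path.
#' @return `write_model_json` returns `path` invisibly;
#'   `read_model_json` returns the restored `erisk_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "erisk_model"))
  pw <- model$piecewise
  spec <- model$spec
  obj <- list(
    cutoffs = spec$cutoffs,
    causes = spec$causes,
    covariates = lapply(spec$covariates, function(cv)
      cv[setdiff(names(cv), "truth")]),
    baselines = as.data.frame(pw$baselines),
    coefficients = cbind(term = rownames(pw$coefficients),
                         as.data.frame(pw$coefficients)),
    loglik = pw$loglik,
    gompertz = list(alpha = model$gompertz$alpha,
                    gamma = model$gompertz$gamma,
                    loglik = model$gompertz$loglik),
    p_unknown = model$p_unknown,
    censoring = model$censoring,
    fitted = isTRUE(model$fitted)
  )
  if (!is.null(pw$vcov))
    obj$vcov <- list(names = colnames(pw$vcov), matrix = unname(pw$vcov))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- lapply(seq_len(nrow_safe(obj$covariates)), function(i) NULL)
  # covariates come back as a list of lists under jsonlite
  covs <- obj$covariates
  if (is.data.frame(covs)) covs <- split(covs, seq_len(nrow(covs)))
  covs <- lapply(covs, function(cv) {
    cv <- as.list(cv)
    cv$levels <- unlist(cv$levels)
    if (!is.null(cv$applies_when))
      cv$applies_when <- as.list(cv$applies_when)
    cv
  })
  spec <- new_model_spec(obj$cutoffs, covs)
  base <- as.matrix(obj$baselines)
  rownames(base) <- paste0("band", seq_len(nrow(base)))
  beta <- as.matrix(obj$coefficients[spec$causes[1:2]])
  beta <- matrix(as.numeric(beta), ncol = 2,
                 dimnames = list(obj$coefficients$term, spec$causes))
  pw <- structure(list(spec = spec, cutoffs = spec$cutoffs,
                       causes = spec$causes, baselines = base,
                       coefficients = beta, coefficient_se = NULL,
                       vcov = NULL, loglik = null2na(obj$loglik),
                       n_free = NA_integer_, converged = NA),
                  class = "piecewise_hazard")
  if (!is.null(obj$vcov)) {
    vc <- matrix(unlist(obj$vcov$matrix), nrow = length(obj$vcov$names),
                 dimnames = list(obj$vcov$names, obj$vcov$names))
    pw$vcov <- vc
  }
  gz <- structure(list(alpha = obj$gompertz$alpha,
                       gamma = obj$gompertz$gamma, vcov = NULL,
                       loglik = null2na(obj$gompertz$loglik)),
                  class = "gompertz_hazard")
  new_erisk_model(pw, gz, p_unknown = null2na(obj$p_unknown),
                  censoring = obj$censoring, fitted = isTRUE(obj$fitted))
}

null2na <- function(x) if (is.null(x)) NA_real_ else x
nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read a covariate configuration from YAML or JSON
#'
#' The file holds named probability maps per categorical variable plus
#' `height: {mean, sd}` and `entry_age: {min, max}`; see
#' [default_covariate_config()] for the expected shape.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return An `erisk_covariate_config`.
#' @export
read_covariate_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  for (nm in names(obj))
    if (!nm %in% c("entry_age", "height")) obj[[nm]] <- unlist(obj[[nm]])
  cfg <- structure(obj, class = "erisk_covariate_config")
  validate_covariate_config(cfg)
  cfg
}

#' @rdname read_covariate_config
#' @param config A covariate configuration.
#' @export
write_covariate_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}
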