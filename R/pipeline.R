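#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> impute -> fit -> project -> validate -> dca as
#' a reproducible, configured run. Each enabled stage writes its outputs
#' (CSV for tables, JSON for models and reports) into the output
#' directory and appends an entry to a manifest recording inputs,
#' outputs, seeds and wall time. Given the same configuration and seeds,
#' the data artifacts are byte-identical across runs.
#'
#' @param config A named list, or the path of a YAML/JSON file holding
#'   one. Recognised fields: `n` (subjects to simulate), `seed`,
#'   `outdir`, `horizon` (default 5), `cohort` (path of an existing
#'   cohort CSV, bypassing simulation), `missingness` (named rates
#'   passed to [inject_missingness()]), `m` and `sweeps` for imputation,
#'   `grid_step` for the decision curve, and `stages`, a named logical
#'   list enabling `simulate`, `impute`, `fit`, `project`, `validate`,
#'   `dca` (all but `impute` default to `TRUE`).
#' @param quiet Suppress stage-tagged progress lines on stderr.
#' @return Invisibly, the manifest (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- list(n = 10000L, seed = 1L, horizon = 5, grid_step = 5e-4,
                   m = 5L, sweeps = 10L,
                   stages = list(simulate = TRUE, impute = FALSE,
                                 fit = TRUE, project = TRUE,
                                 validate = TRUE, dca = TRUE))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$stages))
    if (is.null(config$stages[[nm]]))
      config$stages[[nm]] <- defaults$stages[[nm]]
  if (is.null(config$outdir)) stop("config must name an output directory")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list()
  say <- function(stage, msg) {
    if (!quiet) message("[", stage, "] ", msg)
  }
  record <- function(stage, inputs, outputs, t0) {
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, seed = config$seed, inputs = inputs,
      outputs = outputs,
      elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
      package_version = as.character(utils::packageVersion("erisk")))
  }
  out_path <- function(f) file.path(config$outdir, f)
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    say(stage, "start")
    tryCatch(fn(t0), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(stage, "done")
  }

  cohort <- NULL
  truth <- default_true_model()
  spec <- default_model_spec()

  if (isTRUE(config$stages$simulate)) {
    run_stage("simulate", function(t0) {
      cohort <<- simulate_cohort(config$n, truth, seed = config$seed)
      if (!is.null(config$missingness))
        cohort <<- inject_missingness(cohort, unlist(config$missingness),
                                      seed = config$seed + 1000L)
      write_cohort(cohort, out_path("cohort.csv"))
      record("simulate", list(n = config$n), "cohort.csv", t0)
    })
  } else if (!is.null(config$cohort)) {
    cohort <- read_cohort(config$cohort)
  }
  if (is.null(cohort)) stop("no cohort: enable the simulate stage or ",
                            "provide config$cohort")

  cohorts <- list(cohort)
  if (isTRUE(config$stages$impute)) {
    run_stage("impute", function(t0) {
      ims <- impute_chained(cohort, m = config$m, sweeps = config$sweeps,
                            seed = config$seed + 2000L)
      cohorts <<- ims$imputations
      record("impute", list(m = config$m, sweeps = config$sweeps),
             character(0), t0)
    })
  }

  fits <- NULL
  if (isTRUE(config$stages$fit)) {
    run_stage("fit", function(t0) {
      fits <<- lapply(cohorts, erisk_fit, spec = spec)
      write_model_json(fits[[1L]], out_path("model.json"))
      if (length(fits) > 1L) {
        est <- lapply(fits, function(f) f$piecewise$par)
        vcv <- lapply(fits, function(f) f$piecewise$vcov)
        pooled <- pool_rubin(est, vcv)
        jsonlite::write_json(
          list(term = names(fits[[1L]]$piecewise$par),
               estimate = pooled$estimate, se = pooled$se, df = pooled$df),
          out_path("pooled_coefficients.json"), digits = NA)
        record("fit", list(m = length(fits)),
               c("model.json", "pooled_coefficients.json"), t0)
      } else record("fit", list(m = 1L), "model.json", t0)
    })
  }

  risks <- NULL
  if (isTRUE(config$stages$project)) {
    if (is.null(fits)) stop("project stage needs the fit stage")
    run_stage("project", function(t0) {
      per_fit <- lapply(seq_along(fits), function(i)
        cumulative_incidence(fits[[i]], cohorts[[i]],
                             horizon = config$horizon))
      risks <<- per_fit[[1L]]
      if (length(per_fit) > 1L) {
        for (cl in c("risk_ERpos", "risk_ERneg", "risk_competing",
                     "risk_any", "surv"))
          risks[[cl]] <<- rowMeans(vapply(per_fit, `[[`,
                                          numeric(nrow(risks)), cl))
      }
      utils::write.csv(risks, out_path("risks.csv"), row.names = FALSE)
      record("project", list(horizon = config$horizon), "risks.csv", t0)
    })
  }

  if (isTRUE(config$stages$validate)) {
    if (is.null(risks)) stop("validate stage needs the project stage")
    run_stage("validate", function(t0) {
      rep <- list()
      for (cause in tumour_causes()) {
        r <- risks[[paste0("risk_", cause)]]
        cs <- cstatistic_5yr(r, cohort, cause, config$horizon, ci = FALSE)
        eo <- expected_observed(r, cohort, cause, config$horizon)
        rep[[cause]] <- list(C = cs$C, EO = eo$EO, EO_ci = eo$ci,
                             E = eo$E, O = eo$O)
        utils::write.csv(
          calibration_deciles(r, cohort, cause, config$horizon),
          out_path(paste0("calibration_", cause, ".csv")),
          row.names = FALSE)
      }
      jsonlite::write_json(rep, out_path("validation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("validate", list(horizon = config$horizon),
             c("validation.json", "calibration_ERpos.csv",
               "calibration_ERneg.csv"), t0)
    })
  }

  if (isTRUE(config$stages$dca)) {
    if (is.null(risks)) stop("dca stage needs the project stage")
    run_stage("dca", function(t0) {
      tau <- cohort$exit_age - cohort$entry_age
      y_pos <- as.numeric(cohort$event == "ERpos" & tau <= config$horizon)
      y_all <- as.numeric(cohort$event %in%
                            c(tumour_causes(), "unknownER") &
                            tau <= config$horizon)
      curve <- net_benefit_curve(risks$risk_ERpos, y_pos,
                                 step = config$grid_step,
                                 outcomes_all = y_all)
      utils::write.csv(as.data.frame(curve), out_path("dca_curve.csv"),
                       row.names = FALSE)
      ar <- applicability_area(curve)
      jsonlite::write_json(ar, out_path("dca_areas.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("dca", list(grid_step = config$grid_step),
             c("dca_curve.csv", "dca_areas.json"), t0)
    })
  }

  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
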