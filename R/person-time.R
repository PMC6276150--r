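#' Split follow-up into age-band episodes
#'
#' Expands each subject's follow-up interval `[entry_age, exit_age)` into
#' one row per age band intersected with it. Bands are half-open
#' `[c_j, c_{j+1})`; the first band is open below and the last open above,
#' so every attainable age is covered. The event code is carried on the
#' terminal episode (the band in which follow-up ends); all earlier
#' episodes are marked `"censored"`. Per-subject exposures sum exactly to
#' `exit_age - entry_age`.
#'
#' @param cohort Cohort table with `id`, `entry_age`, `exit_age`, `event`
#'   and covariate columns.
#' @param cutoffs Strictly increasing age cutoffs
#'   (default `c(45, 50, 55, 60, 65, 70, 75)`).
#' @return A data.frame with columns `id`, `band` (1-based), `tstart`,
#'   `tstop`, `exposure`, `event`, plus the cohort's covariate columns.
#' @examples
#' co <- data.frame(id = 1, entry_age = 48, exit_age = 53,
#'                  event = "censored")
#' split_person_time(co, c(45, 50, 55))
#' @export
split_person_time <- function(cohort, cutoffs = c(45, 50, 55, 60, 65, 70, 75)) {
  validate_cohort(cohort)
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) && any(diff(cutoffs) <= 0))
    stop("cutoffs must be strictly increasing")
  lower <- c(-Inf, cutoffs)
  upper <- c(cutoffs, Inf)
  nb <- length(lower)
  n <- nrow(cohort)

  # n x nb overlap matrix, then long format keeping positive exposures
  ov_lo <- outer(cohort$entry_age, lower, pmax)
  ov_hi <- outer(cohort$exit_age, upper, pmin)
  expo <- pmax(ov_hi - ov_lo, 0)
  keep <- which(expo > 0, arr.ind = TRUE)
  keep <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
  ri <- keep[, 1L]; bi <- keep[, 2L]

  out <- data.frame(
    id = cohort$id[ri],
    band = bi,
    tstart = ov_lo[keep],
    tstop = ov_hi[keep],
    exposure = expo[keep]
  )
  # terminal episode = last row of each subject block
  last <- c(ri[-1L] != ri[-length(ri)], TRUE)
  out$event <- ifelse(last, as.character(cohort$event[ri]), "censored")
  covars <- setdiff(names(cohort), c("id", "entry_age", "exit_age", "event"))
  if (length(covars))
    out <- cbind(out, cohort[ri, covars, drop = FALSE], row.names = NULL)
  out
}
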