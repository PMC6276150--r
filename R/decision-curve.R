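#' Net-benefit decision curve
#'
#' For each risk threshold \eqn{p_t} on the grid, the net benefit of
#' treating subjects with predicted risk at or above the threshold is
#' \deqn{NB(p_t) = TP/n - (FP/n)\, p_t / (1 - p_t),}
#' where TP and FP count events and non-events with risk >= \eqn{p_t}.
#' The treat-all comparator is \eqn{\pi - (1 - \pi) p_t/(1 - p_t)} with
#' event proportion \eqn{\pi}; treat-none is identically zero. The
#' default grid runs in steps of 0.0005 from 0.0005 up to the maximal
#' risk estimate. An optional second outcome vector gives a second
#' treat-all line (e.g. all breast cancer when the model outcome is ER+
#' tumours only).
#'
#' @param risks Predicted risks in `[0, 1]`.
#' @param outcomes Binary outcome indicators over the horizon.
#' @param grid Threshold grid; defaults to
#'   `seq(step, max(risks), by = step)`.
#' @param step Grid step when `grid` is `NULL` (default 0.0005).
#' @param outcomes_all Optional second binary outcome for an additional
#'   treat-all line (`nb_all_alt` in the result).
#' @return An object of class `decision_curve`: a data.frame with columns
#'   `threshold`, `nb_model`, `nb_all` (and `nb_all_alt` when requested),
#'   plus attributes `prevalence` and `n`.
#' @export
net_benefit_curve <- function(risks, outcomes, grid = NULL, step = 5e-4,
                              outcomes_all = NULL) {
  stopifnot(length(risks) == length(outcomes),
            all(risks >= 0 & risks <= 1), all(outcomes %in% 0:1))
  if (is.null(grid)) grid <- seq(step, max(risks), by = step)
  if (any(grid >= 1) || any(grid <= 0))
    stop("thresholds must lie strictly inside (0, 1)")
  if (any(diff(grid) <= 0)) stop("threshold grid must be strictly increasing")
  n <- length(risks)
  odds <- grid / (1 - grid)
  nb_model <- vapply(grid, function(pt) {
    treat <- risks >= pt
    (sum(outcomes[treat]) - sum(!outcomes[treat]) * pt / (1 - pt)) / n
  }, 0)
  pi_hat <- mean(outcomes)
  out <- data.frame(threshold = grid, nb_model = nb_model,
                    nb_all = pi_hat - (1 - pi_hat) * odds)
  if (!is.null(outcomes_all)) {
    pa <- mean(outcomes_all)
    out$nb_all_alt <- pa - (1 - pa) * odds
  }
  structure(out, class = c("decision_curve", "data.frame"),
            prevalence = pi_hat, n = n)
}

#' Benefit-to-harm threshold algebra
#'
#' At the indifference threshold the expected benefit and harm of
#' treatment balance: \eqn{p_t B = (1 - p_t) H}, so the implied
#' benefit-to-harm ratio is \eqn{B/H = (1 - p_t)/p_t} and conversely
#' \eqn{p_t = 1/(1 + B/H)}. `threshold_bh` optionally rounds the ratio to
#' the nearest multiple of a given number (clinical summaries usually
#' round to the nearest 5).
#'
#' @param p_t Risk threshold(s), strictly inside (0, 1).
#' @param nearest Optional rounding unit for the ratio (e.g. 5);
#'   `NULL` (default) returns the exact ratio.
#' @return `threshold_bh`: the benefit-to-harm ratio(s); `bh_threshold`:
#'   the threshold(s).
#' @examples
#' threshold_bh(0.04, nearest = 5)   # 25
#' bh_threshold(24)                  # 0.04
#' @export
threshold_bh <- function(p_t, nearest = NULL) {
  if (any(p_t <= 0 | p_t >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  r <- (1 - p_t) / p_t
  if (!is.null(nearest)) r <- round(r / nearest) * nearest
  r
}

#' @rdname threshold_bh
#' @param r Benefit-to-harm ratio(s), positive.
#' @export
bh_threshold <- function(r) {
  if (any(r <= 0)) stop("benefit-to-harm ratios must be positive")
  1 / (1 + r)
}

#' Applicability area of a decision curve
#'
#' Integrates how much the model's net-benefit curve lies above the
#' envelope of the two extreme strategies,
#' `envelope(p_t) = max(nb_all(p_t), 0)`, by the trapezoidal rule over
#' the threshold grid. The signed negative part (`area_below`, where the
#' model falls under the envelope) and positive part (`area_above`) are
#' reported separately along with their sum; a model everywhere above the
#' envelope yields a single positive total.
#'
#' @param curve A `decision_curve`.
#' @param use_alt Integrate against the alternative treat-all line
#'   (`nb_all_alt`) instead of the primary one (default `FALSE`).
#' @return A list with `area_below`, `area_above`, `total`.
#' @export
applicability_area <- function(curve, use_alt = FALSE) {
  stopifnot(inherits(curve, "decision_curve"))
  x <- curve$threshold
  steps <- diff(x)
  if (length(steps) < 1) stop("need at least two grid points")
  if (diff(range(steps)) > 1e-9 * mean(steps)) {
    warning("non-uniform threshold grid; re-interpolating")
    xs <- seq(min(x), max(x), length.out = max(length(x), 200L))
    nbm <- stats::approx(x, curve$nb_model, xs)$y
    nba <- stats::approx(x, if (use_alt) curve$nb_all_alt else curve$nb_all,
                         xs)$y
    x <- xs
  } else {
    nbm <- curve$nb_model
    nba <- if (use_alt) curve$nb_all_alt else curve$nb_all
  }
  g <- nbm - pmax(nba, 0)
  trap <- function(y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
  list(area_below = trap(pmin(g, 0)),
       area_above = trap(pmax(g, 0)),
       total = trap(g))
}

#' @export
plot.decision_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$nb_model, type = "l", lwd = 2,
                 xlab = "risk threshold", ylab = "net benefit", ...)
  graphics::lines(x$threshold, x$nb_all, col = "grey50")
  if (!is.null(x$nb_all_alt))
    graphics::lines(x$threshold, x$nb_all_alt, col = "grey50", lty = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
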