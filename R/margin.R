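#' QALY gap between alternative and standard arm
#'
#' Evaluates the decision model in both arms and returns the difference in
#' total QALYs per 1000 patients (alternative minus standard). The standard
#' arm is evaluated at the scenario's fixed `p_S`; pass `standard_outcomes`
#' to reuse a cached evaluation.
#'
#' @param p_A Cumulative event rate in the alternative arm over the trial
#'   horizon; may be a vector, evaluated efficiently on a shared cached grid.
#' @param scenario An [ni_scenario()].
#' @param standard_outcomes Optional cached `arm_outcomes` for the standard
#'   arm.
#' @return QALY difference per 1000 patients, one value per element of
#'   `p_A`; positive when the alternative arm is preferred.
#' @export
qaly_gap <- function(p_A, scenario, standard_outcomes = NULL) {
  stopifnot(inherits(scenario, "ni_scenario"))
  if (is.null(standard_outcomes)) {
    standard_outcomes <- scenario_arm_outcomes(scenario, "standard",
                                               scenario$p_S)
  }
  ev <- scenario_evaluator(scenario, "alternative")
  vapply(p_A, function(p) qaly_difference(ev(p), standard_outcomes),
         numeric(1))
}

#' Net-monetary-benefit gap between alternative and standard arm
#'
#' `NMB = wtp * QALYs - costs`, per 1000 patients; the gap is alternative
#' minus standard.
#'
#' @inheritParams qaly_gap
#' @param wtp Willingness-to-pay per QALY; defaults to the scenario's
#'   economic parameters.
#' @return NMB difference (currency units per 1000 patients).
#' @export
nmb_gap <- function(p_A, scenario, wtp = scenario$econ$wtp,
                    standard_outcomes = NULL) {
  stopifnot(inherits(scenario, "ni_scenario"))
  if (is.null(standard_outcomes)) {
    standard_outcomes <- scenario_arm_outcomes(scenario, "standard",
                                               scenario$p_S)
  }
  nmb_std <- wtp * standard_outcomes$qaly_total - standard_outcomes$cost_total
  ev <- scenario_evaluator(scenario, "alternative")
  vapply(p_A, function(p) {
    alt <- ev(p)
    (wtp * alt$qaly_total - alt$cost_total) - nmb_std
  }, numeric(1))
}

#' Solve for the equipoise event rate of a monotone gap function
#'
#' The workhorse behind the margin solvers, exposed so that closed-form gap
#' functions can be solved directly. Requires `gap(p_S) >= 0` and a sign
#' change within `[p_S, p_max]`; the bracket is grown by doubling its width
#' starting from `bracket_width`. The root is refined (Brent, then bisection)
#' until `|gap| < tol` -- the tolerance is on the gap, not on the rate,
#' because the gap's slope varies by scenario.
#'
#' @param gap A function of the event rate returning the (strictly
#'   decreasing) gap.
#' @param p_S Standard-arm event rate (lower end of the bracket).
#' @param tol Absolute tolerance on the gap at the solution.
#' @param bracket_width Initial bracket width above `p_S`.
#' @param p_max Largest event rate considered before declaring failure.
#' @return A list with `p_A_star`, `gap_at_solution`, `iterations` (gap
#'   evaluations) and `bracket`.
#' @export
solve_equipoise <- function(gap, p_S, tol = 1e-4, bracket_width = 0.01,
                            p_max = 0.2) {
  n_eval <- 0L
  g <- function(p) {
    n_eval <<- n_eval + 1L
    gap(p)
  }
  g_low <- g(p_S)
  if (abs(g_low) <= tol) {
    return(list(p_A_star = p_S, gap_at_solution = g_low,
                iterations = n_eval, bracket = c(p_S, p_S)))
  }
  if (g_low < 0) {
    stop("alternative never non-inferior: the gap is already negative at ",
         "p_A = p_S = ", p_S, call. = FALSE)
  }
  width <- bracket_width
  hi <- min(p_S + width, p_max)
  g_hi <- g(hi)
  while (g_hi > 0 && hi < p_max) {
    width <- width * 2
    hi <- min(p_S + width, p_max)
    g_hi <- g(hi)
  }
  if (g_hi > 0) {
    stop("alternative dominates at all plausible rates: no QALY/NMB ",
         "equipoise below p_A = ", p_max, call. = FALSE)
  }
  lo <- p_S
  root <- uniroot(g, c(lo, hi), f.lower = g_low, f.upper = g_hi,
                  tol = .Machine$double.eps^0.5)
  p_star <- root$root
  g_star <- g(p_star)
  # bisect further if the gap tolerance is not yet met
  blo <- lo; bhi <- hi
  for (i in 1:100) {
    if (abs(g_star) <= tol) break
    if (g_star > 0) blo <- p_star else bhi <- p_star
    p_star <- (blo + bhi) / 2
    g_star <- g(p_star)
  }
  if (abs(g_star) > tol) {
    stop("equipoise search did not reach the requested gap tolerance",
         call. = FALSE)
  }
  list(p_A_star = p_star, gap_at_solution = g_star, iterations = n_eval,
       bracket = c(lo, hi))
}

new_margin_result <- function(scenario, sol, criterion, wtp, trial) {
  res <- structure(list(p_S = scenario$p_S,
                        p_A_star = sol$p_A_star,
                        delta = sol$p_A_star - scenario$p_S,
                        criterion = criterion,
                        wtp = wtp,
                        gap_at_solution = sol$gap_at_solution,
                        solver_iterations = sol$iterations,
                        bracket = sol$bracket,
                        scenario_hash = scenario_hash(scenario),
                        sample_size = NULL),
                   class = "margin_result")
  if (!is.null(trial) && res$delta > 0) {
    res$sample_size <- required_sample_size(trial, res$delta)
  }
  res
}

#' Non-inferiority margin at QALY equipoise
#'
#' Finds the alternative-arm event rate `p_A*` at which total QALYs are equal
#' between arms (the tipping point) and reports the margin
#' `delta = p_A* - p_S`. If a trial design is available, the corresponding
#' non-inferiority sample size is attached.
#'
#' @param scenario An [ni_scenario()].
#' @param trial A [trial_design()] for the attached sample size; defaults to
#'   the scenario's. Use `NULL` to skip.
#' @param tol Tolerance on the QALY gap (QALYs per 1000 patients).
#' @param bracket_width,p_max Bracket controls, see [solve_equipoise()].
#' @return A `margin_result`.
#' @export
solve_margin_qaly <- function(scenario, trial = scenario$trial, tol = 1e-4,
                              bracket_width = 0.01, p_max = 0.2) {
  stopifnot(inherits(scenario, "ni_scenario"))
  std <- scenario_arm_outcomes(scenario, "standard", scenario$p_S)
  ev <- scenario_evaluator(scenario, "alternative")
  sol <- solve_equipoise(function(p) qaly_difference(ev(p), std),
                         scenario$p_S, tol = tol,
                         bracket_width = bracket_width, p_max = p_max)
  new_margin_result(scenario, sol, "qaly", NA_real_, trial)
}

#' Non-inferiority margin at net-monetary-benefit equipoise
#'
#' As [solve_margin_qaly()], but equipoise is defined on net monetary
#' benefit `wtp * QALYs - costs`. When the alternative arm is cheaper, the
#' cost saving buys additional tolerance for lost effectiveness, so this
#' margin is at least as large as the QALY margin.
#'
#' @inheritParams solve_margin_qaly
#' @param wtp Willingness-to-pay per QALY; defaults to the scenario's
#'   economic parameters.
#' @param tol Tolerance on the NMB gap, expressed in QALYs per 1000 (it is
#'   multiplied by `wtp` internally so that the two solvers use comparable
#'   stopping rules).
#' @return A `margin_result`.
#' @export
solve_margin_nmb <- function(scenario, wtp = scenario$econ$wtp,
                             trial = scenario$trial, tol = 1e-4,
                             bracket_width = 0.01, p_max = 0.2) {
  stopifnot(inherits(scenario, "ni_scenario"))
  std <- scenario_arm_outcomes(scenario, "standard", scenario$p_S)
  nmb_std <- wtp * std$qaly_total - std$cost_total
  ev <- scenario_evaluator(scenario, "alternative")
  sol <- solve_equipoise(function(p) {
    alt <- ev(p)
    (wtp * alt$qaly_total - alt$cost_total) - nmb_std
  }, scenario$p_S, tol = tol * wtp,
    bracket_width = bracket_width, p_max = p_max)
  new_margin_result(scenario, sol, "nmb", wtp, trial)
}

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("Non-inferiority margin (%s equipoise)\n",
              toupper(x$criterion)))
  cat(sprintf("  p_S = %.4f%%, tipping point p_A* = %.4f%%\n",
              100 * x$p_S, 100 * x$p_A_star))
  cat(sprintf("  margin delta = %.4f%%\n", 100 * x$delta))
  if (x$criterion == "nmb") {
    cat(sprintf("  willingness-to-pay = %g per QALY\n", x$wtp))
  }
  cat(sprintf("  gap at solution %.3g after %d evaluations\n",
              x$gap_at_solution, x$solver_iterations))
  if (!is.null(x$sample_size)) {
    cat(sprintf("  required sample size: %d per arm, %d total\n",
                x$sample_size$n_per_arm, x$sample_size$n_total))
  }
  invisible(x)
}

#' Serialize a margin result to JSON
#'
#' Writes the result fields (including the scenario hash for provenance) as
#' a JSON object.
#'
#' @param result A `margin_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_margin_json <- function(result, path) {
  stopifnot(inherits(result, "margin_result"))
  out <- unclass(result)
  if (!is.null(out$sample_size)) out$sample_size <- unclass(out$sample_size)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
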