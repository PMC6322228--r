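#' Reduced-form natural-history parameters
#'
#' A deliberately simple stand-in for a full microsimulation natural
#' history: the event of interest (cancer diagnosis) arises from an
#' age-increasing baseline hazard; each surveillance exam multiplies that
#' hazard by `1 - per_exam_protection * sensitivity_multiplier` until the
#' next scheduled exam (or for `protection window = interval` years after
#' the last one); diagnosed persons carry an excess mortality rate for
#' `cure_horizon` years and are then subject to background mortality only.
#' The absolute level of the baseline hazard is irrelevant: a calibration
#' multiplier (see [calibrate_hazard_multiplier()]) rescales it to hit any
#' requested cumulative incidence over the trial horizon.
#'
#' @param baseline_rate Baseline event hazard (per year) at `baseline_ref_age`.
#' @param baseline_ref_age Age anchoring `baseline_rate`.
#' @param doubling_time Years over which the baseline hazard doubles with age.
#' @param per_exam_protection Fraction in `[0, 1]` by which one exam reduces
#'   the event hazard during its protection window (rho).
#' @param sensitivity_multiplier Unitless scaling of the protection,
#'   representing test-sensitivity perturbations (epsilon); `rho * epsilon`
#'   must not exceed 1.
#' @param excess_mortality_rate Extra mortality hazard (per year) among
#'   diagnosed persons during the first `cure_horizon` years.
#' @param cure_horizon Years of excess mortality after diagnosis; survivors
#'   are then considered cured.
#' @param cycle_length Model cycle in years; must divide one year and all
#'   exam-age offsets. Default one month.
#' @param horizon_age Age at which the lifetime follow-up is truncated.
#' @param discount_rate Annual discount rate applied to person-time and
#'   losses; default 0 (undiscounted totals).
#' @return An object of class `natural_history_params`.
#' @export
natural_history_params <- function(baseline_rate = 0.001,
                                   baseline_ref_age = 50,
                                   doubling_time = 12,
                                   per_exam_protection = 0.5,
                                   sensitivity_multiplier = 1.0,
                                   excess_mortality_rate = 0.10,
                                   cure_horizon = 5,
                                   cycle_length = 1 / 12,
                                   horizon_age = 100,
                                   discount_rate = 0) {
  check_scalar(baseline_rate, "baseline_rate", lower = 0)
  check_scalar(baseline_ref_age, "baseline_ref_age", lower = 0)
  check_scalar(doubling_time, "doubling_time")
  if (doubling_time <= 0) stop("`doubling_time` must be positive", call. = FALSE)
  check_scalar(per_exam_protection, "per_exam_protection", lower = 0, upper = 1)
  check_scalar(sensitivity_multiplier, "sensitivity_multiplier", lower = 0)
  if (per_exam_protection * sensitivity_multiplier > 1 + 1e-12) {
    stop("per_exam_protection * sensitivity_multiplier must be <= 1",
         call. = FALSE)
  }
  check_scalar(excess_mortality_rate, "excess_mortality_rate", lower = 0)
  check_scalar(cure_horizon, "cure_horizon", lower = 0)
  check_scalar(cycle_length, "cycle_length")
  if (cycle_length <= 0) stop("`cycle_length` must be positive", call. = FALSE)
  cpy <- 1 / cycle_length
  if (abs(cpy - round(cpy)) > 1e-9) {
    stop("`cycle_length` must divide one year", call. = FALSE)
  }
  check_scalar(horizon_age, "horizon_age", lower = 0)
  check_scalar(discount_rate, "discount_rate", lower = 0)
  structure(list(baseline_rate = baseline_rate,
                 baseline_ref_age = baseline_ref_age,
                 doubling_time = doubling_time,
                 per_exam_protection = per_exam_protection,
                 sensitivity_multiplier = sensitivity_multiplier,
                 excess_mortality_rate = excess_mortality_rate,
                 cure_horizon = cure_horizon,
                 cycle_length = cycle_length,
                 horizon_age = horizon_age,
                 discount_rate = discount_rate),
            class = "natural_history_params")
}

# baseline (pre-calibration, pre-protection) event hazard at age
nh_baseline_hazard <- function(nh, age) {
  nh$baseline_rate * 2^((age - nh$baseline_ref_age) / nh$doubling_time)
}
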