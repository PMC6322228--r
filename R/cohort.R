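#' @name cohort_model
#' @title Deterministic cohort model of surveillance, diagnosis and death
#'
#' @description
#' The cohort enters event-free at the strategy's `start_age` and is followed
#' in cycles of `cycle_length` years until `horizon_age`. Each cycle applies
#' competing exponential hazards of other-cause death and of diagnosis; exams
#' occur instantaneously at their scheduled ages among alive, not-yet
#' diagnosed persons, carry a per-exam fatal complication risk, and suppress
#' the diagnosis hazard by `rho * epsilon` until the next scheduled exam.
#' Diagnosed persons carry excess mortality for `cure_horizon` years, then
#' revert to background mortality.
NULL

# Precompute the per-cycle hazard grids for one arm.
cohort_grid <- function(strategy, nh, life) {
  dt <- nh$cycle_length
  n_cycles <- round((nh$horizon_age - strategy$start_age) / dt)
  if (n_cycles < 1) stop("horizon_age must exceed start_age", call. = FALSE)
  age0 <- strategy$start_age
  age_start <- age0 + (seq_len(n_cycles) - 1) * dt
  age_mid <- age_start + dt / 2

  exam_ages <- strategy$exam_ages
  exam_cycle <- integer(0)
  if (length(exam_ages)) {
    off <- (exam_ages - age0) / dt
    if (any(abs(off - round(off)) > 1e-9)) {
      stop("exam ages are not aligned with the model cycle length ",
           "(cycle_length must divide all exam-age offsets)", call. = FALSE)
    }
    exam_cycle <- as.integer(round(off))
    exam_cycle <- exam_cycle[exam_cycle >= 0 & exam_cycle < n_cycles]
  }

  # protection windows: from each exam to the next, capped at one interval
  protected <- rep(FALSE, n_cycles)
  if (length(exam_ages)) {
    nxt <- c(exam_ages[-1], Inf)
    win_end <- pmin(nxt, exam_ages + strategy$interval)
    for (i in seq_along(exam_ages)) {
      protected <- protected |
        (age_mid > exam_ages[i] & age_mid <= win_end[i])
    }
  }
  prot_factor <- ifelse(protected,
                        1 - nh$per_exam_protection * nh$sensitivity_multiplier,
                        1)

  mu <- lt_hazard(life, age_mid)
  base_event <- nh_baseline_hazard(nh, age_mid) * prot_factor

  list(dt = dt, n_cycles = n_cycles, age_start = age_start,
       age_mid = age_mid, mu = mu, base_event = base_event,
       exam_cycle = exam_cycle,
       cure_cycles = as.integer(round(nh$cure_horizon / dt)),
       cycles_per_year = as.integer(round(1 / dt)))
}

# Fast path: cumulative incidence over the first `horizon_cycles` cycles,
# from the healthy-state recursion only (identical formulas to the full
# model; diagnosed-state dynamics do not affect incidence).
cum_incidence_fast <- function(grid, psi, fatal_exam_risk) {
  lam <- psi * grid$base_event
  tot <- lam + grid$mu
  ps <- exp(-tot * grid$dt)
  examfac <- rep(1, grid$n_cycles)
  examfac[grid$exam_cycle + 1L] <- 1 - fatal_exam_risk
  g <- examfac * ps
  H_pre <- c(1, cumprod(g)[-grid$n_cycles]) # start of cycle, pre-exam
  frac <- ifelse(tot > 0, lam / tot, 0)
  H_pre * examfac * (1 - ps) * frac # new diagnoses per cycle
}

#' Calibrate the hazard multiplier to a target cumulative incidence
#'
#' Finds the multiplier `psi >= 0` such that running the cohort with event
#' hazard `psi * baseline` (protection effects included) yields the requested
#' cumulative incidence of diagnosis over `horizon_years`, in the presence of
#' competing other-cause mortality. The cumulative incidence is monotone
#' increasing in `psi`, so a bracketed root search (Brent) applies; the
#' multiplier keeps acting for the remaining lifetime beyond the horizon.
#'
#' @param nh A [natural_history_params()].
#' @param life A [life_table_params()].
#' @param strategy A [surveillance_strategy()].
#' @param target_p Target cumulative incidence over the horizon, in `[0, 1)`.
#' @param horizon_years Calibration horizon (years after entry); default 10.
#' @param fatal_exam_risk Per-exam fatal complication probability applied in
#'   the cohort (polypectomy fraction times fatal complication probability).
#' @param tol Absolute tolerance on the achieved cumulative incidence.
#' @return The multiplier `psi` (a single number).
#' @export
calibrate_hazard_multiplier <- function(nh, life, strategy, target_p,
                                        horizon_years = 10,
                                        fatal_exam_risk = 0.3 / 30000,
                                        tol = 1e-12) {
  grid <- cohort_grid(strategy, nh, life)
  hc <- as.integer(round(horizon_years / grid$dt))
  hc <- min(hc, grid$n_cycles)
  calibrate_psi(grid, target_p, fatal_exam_risk, hc, tol = tol)
}

# robust bracketed calibration on a precomputed grid; `init` warm-starts a
# proportional fixed-point iteration (cumulative incidence is near-linear in
# psi at the rates of interest)
calibrate_psi <- function(grid, target_p, fatal_exam_risk, hc, tol = 1e-12,
                          init = NULL) {
  check_scalar(target_p, "target_p", lower = 0, upper = 1 - 1e-12)
  if (target_p == 0) return(0)
  cum <- function(psi) {
    sum(cum_incidence_fast(grid, psi, fatal_exam_risk)[seq_len(hc)])
  }
  if (all(grid$base_event[seq_len(hc)] == 0)) {
    stop("target cumulative incidence ", target_p, " is unreachable: the ",
         "baseline event hazard is zero over the horizon (achievable range ",
         "is [0, 0])", call. = FALSE)
  }
  if (!is.null(init) && init > 0) {
    psi <- init
    for (i in 1:50) {
      ci <- cum(psi)
      if (abs(ci - target_p) <= tol) return(psi)
      if (ci <= 0) break
      psi <- psi * (target_p / ci)
    }
  }
  f <- function(psi) cum(psi) - target_p
  hi <- 1
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) < 0) {
    stop(sprintf(paste0("target cumulative incidence %g is unreachable with ",
                        "psi >= 0 (achievable range is [0, %.6g])"),
                 target_p, f(hi) + target_p), call. = FALSE)
  }
  root <- uniroot(f, c(0, hi), tol = .Machine$double.eps^0.75)
  psi <- root$root
  # polish with bisection until the achieved incidence is within tol
  lo <- 0; up <- hi
  for (i in 1:200) {
    if (abs(f(psi)) <= tol) break
    if (f(psi) > 0) up <- psi else lo <- psi
    psi <- (lo + up) / 2
  }
  psi
}

#' Run one arm of the trial through the cohort model
#'
#' Calibrates the hazard multiplier to `target_p` (unless `psi` is supplied)
#' and runs the full lifetime cohort recursion, returning a `cohort_trace`.
#'
#' @inheritParams calibrate_hazard_multiplier
#' @param psi Optional pre-calibrated hazard multiplier; skips calibration.
#' @return A `cohort_trace`: per-cycle state occupancy (start of cycle),
#'   flows (exams, new diagnoses, deaths) and person-years by phase, plus the
#'   calibrated multiplier and discount weights. Convert with
#'   [as.data.frame.cohort_trace()] for a tidy per-cycle/per-compartment view.
#' @export
run_arm <- function(strategy, nh, life, target_p,
                    horizon_years = 10, fatal_exam_risk = 0.3 / 30000,
                    psi = NULL) {
  grid <- cohort_grid(strategy, nh, life)
  hc <- min(as.integer(round(horizon_years / grid$dt)), grid$n_cycles)
  if (is.null(psi)) {
    psi <- calibrate_psi(grid, target_p, fatal_exam_risk, hc)
  }
  run_arm_on_grid(grid, nh, strategy$label, target_p, fatal_exam_risk, hc,
                  psi)
}

# trace assembly on a precomputed grid (shared by run_arm and the cached
# per-arm evaluators used by the margin solvers)
run_arm_on_grid <- function(grid, nh, label, target_p, fatal_exam_risk, hc,
                            psi) {
  raw <- .cohort_run_cpp(grid$mu, psi * grid$base_event, grid$dt,
                         grid$exam_cycle, fatal_exam_risk,
                         nh$excess_mortality_rate, grid$cure_cycles,
                         grid$cycles_per_year)
  r <- nh$discount_rate
  t_start <- (seq_len(grid$n_cycles) - 1) * grid$dt
  trace <- c(raw, list(
    age = grid$age_start,
    dt = grid$dt,
    n_cycles = grid$n_cycles,
    horizon_cycles = hc,
    psi = psi,
    target_p = target_p,
    fatal_exam_risk = fatal_exam_risk,
    strategy_label = label,
    discount_mid = exp(-r * (t_start + grid$dt / 2)),
    discount_start = exp(-r * t_start)
  ))
  structure(trace, class = "cohort_trace")
}

#' Achieved cumulative incidence of diagnosis over the trial horizon
#'
#' @param trace A `cohort_trace` from [run_arm()].
#' @param horizon_years Horizon (years after entry); defaults to the horizon
#'   used when the trace was built.
#' @return Cumulative incidence (proportion of the entering cohort diagnosed
#'   within the horizon, competing mortality included).
#' @export
cumulative_incidence <- function(trace, horizon_years = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  hc <- if (is.null(horizon_years)) trace$horizon_cycles
        else min(as.integer(round(horizon_years / trace$dt)), trace$n_cycles)
  sum(trace$new_dx[seq_len(hc)])
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", x$strategy_label, "\n")
  cat(sprintf("  %d cycles of %.4g y, ages %.4g-%.4g\n",
              x$n_cycles, x$dt, x$age[1], x$age[x$n_cycles] + x$dt))
  cat(sprintf("  calibrated multiplier psi = %.6g (target p = %g, achieved %.6g)\n",
              x$psi, x$target_p, cumulative_incidence(x)))
  cat(sprintf("  exams/person %.4f, lifetime diagnoses/person %.6f\n",
              sum(x$exams), sum(x$new_dx)))
  cat(sprintf("  life-years/person %.4f\n",
              sum(x$py_healthy + x$py_initial + x$py_continuing + x$py_cured)))
  invisible(x)
}

#' Tidy per-cycle view of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Ignored; present for method compatibility.
#' @return A long data frame with one row per cycle per quantity: columns
#'   `cycle`, `age`, `quantity`, `value`. State quantities (`s_*`) are
#'   start-of-cycle occupancy fractions; flow and person-year quantities are
#'   within-cycle totals.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  fields <- c("s_healthy", "s_dx_initial", "s_dx_continuing", "s_cured",
              "s_dead_other", "s_dead_event", "s_dead_compl",
              "exams", "compl_deaths", "new_dx", "event_deaths",
              "py_healthy", "py_initial", "py_continuing", "py_cured",
              "py_terminal")
  n <- x$n_cycles
  do.call(rbind, lapply(fields, function(f) {
    data.frame(cycle = seq_len(n), age = x$age, quantity = f,
               value = x[[f]])
  }))
}

#' Write a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
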