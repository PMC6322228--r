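# Shared scenario fixtures, built in code.

# quarterly cycles keep the many-evaluation property tests fast while the
# headline scenario stays at the monthly default
quarterly_nh <- function(...) {
  natural_history_params(cycle_length = 0.25, ...)
}

# degenerate scenario: exams carry no burden, no complications and no
# protective effect, so the two arms are identical up to exam counts
zero_burden_scenario <- function(zero_costs = TRUE) {
  econ <- if (zero_costs) {
    econ_params(cost_per_colonoscopy = 0, cost_per_complication = 0,
                cost_initial = 0, cost_continuing = 0, cost_terminal = 0)
  } else {
    econ_params()
  }
  ni_scenario(
    nh = quarterly_nh(per_exam_protection = 0),
    burden = colonoscopy_burden(anxiety_duration = 0, procedure_duration = 0,
                                complication_qaly_loss = 0,
                                fatal_complication_probability = 0,
                                polypectomy_fraction = 0, scaling = 1),
    econ = econ
  )
}

# random scenario draws for property tests: burden parameters jittered by
# +-20%, protection and excess mortality varied over plausible ranges
random_scenario <- function(i) {
  set.seed(1000 + i)
  j <- function(x) x * runif(1, 0.8, 1.2)
  ni_scenario(
    nh = quarterly_nh(per_exam_protection = runif(1, 0.3, 0.7),
                      excess_mortality_rate = j(0.10)),
    burden = colonoscopy_burden(anxiety_duration = j(21),
                                anxiety_disutility = j(0.1),
                                procedure_duration = j(2),
                                procedure_disutility = j(0.5),
                                complication_qaly_loss = j(14),
                                polypectomy_fraction = j(0.3),
                                scaling = j(1)),
    p_S = runif(1, 0.008, 0.012)
  )
}

# minimal trace stub for the accounting functions (per-person units)
toy_trace <- function(n = 4, exams = rep(0, n), age = rep(60, n),
                      py_initial = rep(0, n), py_continuing = rep(0, n),
                      py_terminal = rep(0, n), ded_initial = rep(0, n),
                      ded_continuing = rep(0, n)) {
  structure(list(exams = exams, age = age, py_initial = py_initial,
                 py_continuing = py_continuing, py_terminal = py_terminal,
                 ded_initial = ded_initial, ded_continuing = ded_continuing),
            class = "cohort_trace")
}

# start-of-cycle occupancy across all compartments, per cycle
state_sums <- function(trace) {
  trace$s_healthy + trace$s_dx_initial + trace$s_dx_continuing +
    trace$s_cured + trace$s_dead_other + trace$s_dead_event +
    trace$s_dead_compl
}
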