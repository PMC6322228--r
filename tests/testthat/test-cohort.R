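# Independent brute-force cohort recursion: a plain R loop computing the
# cumulative incidence of diagnosis from first principles (hazards written
# out directly, not via package internals).
oracle_cum_incidence <- function(psi, strategy, nh, life, horizon_years = 10,
                                 fatal_exam_risk = 0) {
  dt <- nh$cycle_length
  n <- round(horizon_years / dt)
  exam_ages <- strategy$exam_ages
  nxt <- c(exam_ages[-1], Inf)
  win_end <- pmin(nxt, exam_ages + strategy$interval)
  H <- 1
  cum <- 0
  for (t in seq_len(n)) {
    age <- strategy$start_age + (t - 1) * dt
    mid <- age + dt / 2
    if (any(abs(exam_ages - age) < 1e-9)) H <- H * (1 - fatal_exam_risk)
    prot <- any(mid > exam_ages & mid <= win_end)
    lam <- psi * nh$baseline_rate *
      2^((mid - nh$baseline_ref_age) / nh$doubling_time) *
      (if (prot) 1 - nh$per_exam_protection * nh$sensitivity_multiplier else 1)
    mu <- life$gompertz_a * exp(life$gompertz_b * (mid - life$reference_age))
    tot <- lam + mu
    pexit <- 1 - exp(-tot * dt)
    if (tot > 0) cum <- cum + H * pexit * lam / tot
    H <- H * exp(-tot * dt)
  }
  cum
}

test_that("hazard calibration is a fixed point at the model's own incidence", {
  nh <- natural_history_params()
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  own <- cumulative_incidence(run_arm(std, nh, life, target_p = 0, psi = 1))
  psi <- calibrate_hazard_multiplier(nh, life, std, own)
  expect_equal(psi, 1, tolerance = 1e-6)
  expect_identical(calibrate_hazard_multiplier(nh, life, std, 0), 0)
})

test_that("calibrated incidence matches an independent cohort recursion", {
  nh <- natural_history_params()
  life <- life_table_params()
  alt <- surveillance_strategy("10-yearly", 50, 10, 75)
  fatal <- 0.3 / 30000
  psi <- calibrate_hazard_multiplier(nh, life, alt, 0.015,
                                     fatal_exam_risk = fatal)
  oracle <- oracle_cum_incidence(psi, alt, nh, life,
                                 fatal_exam_risk = fatal)
  expect_equal(oracle, 0.015, tolerance = 1e-6)
})

test_that("calibration hits targets to 1e-6 with competing mortality", {
  nh <- natural_history_params()
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  for (target in c(0.005, 0.010, 0.015, 0.020)) {
    tr <- run_arm(std, nh, life, target)
    expect_lt(abs(cumulative_incidence(tr) - target), 1e-6)
  }
})

test_that("unreachable targets report the achievable range", {
  nh <- natural_history_params(baseline_rate = 0)
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  expect_error(calibrate_hazard_multiplier(nh, life, std, 0.01),
               "unreachable")
  expect_error(calibrate_hazard_multiplier(nh, life, std, 1.5), "target_p")
})

test_that("state occupancy is conserved at every cycle", {
  nh <- natural_history_params()
  life <- life_table_params()
  for (strat in list(surveillance_strategy("5-yearly", 50, 5, 75),
                     surveillance_strategy("10-yearly", 50, 10, 75))) {
    for (target in c(0.01, 0.03)) {
      tr <- run_arm(strat, nh, life, target)
      expect_lt(max(abs(state_sums(tr) - 1)), 1e-12)
      df <- as.data.frame(tr)
      expect_true(all(df$value >= 0)) # fractions and flows are non-negative
    }
  }
})

test_that("lifetime life-years are non-increasing in the target event rate", {
  nh <- natural_history_params()
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  ly <- vapply(c(0.005, 0.01, 0.02, 0.04), function(p) {
    tr <- run_arm(std, nh, life, p)
    sum(tr$py_healthy + tr$py_initial + tr$py_continuing + tr$py_cured)
  }, numeric(1))
  expect_true(all(diff(ly) < 0))
})

test_that("without protection, arms share the same event stream", {
  nh <- natural_history_params(per_exam_protection = 0)
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  alt <- surveillance_strategy("10-yearly", 50, 10, 75)
  tr_s <- run_arm(std, nh, life, 0.01, fatal_exam_risk = 0)
  tr_a <- run_arm(alt, nh, life, 0.01, fatal_exam_risk = 0)
  expect_equal(tr_s$new_dx, tr_a$new_dx, tolerance = 1e-12)
  expect_equal(tr_s$s_dead_event, tr_a$s_dead_event, tolerance = 1e-12)
  # with a fatal exam risk, life-years differ only via complication deaths
  tr_s2 <- run_arm(std, nh, life, 0.01, fatal_exam_risk = 1e-4)
  ly <- function(tr) sum(tr$py_healthy + tr$py_initial + tr$py_continuing +
                           tr$py_cured)
  expect_lt(ly(tr_s2), ly(tr_s))
  expect_equal(sum(tr_s$compl_deaths), 0)
  expect_gt(sum(tr_s2$compl_deaths), 0)
})

test_that("with no disease and no exams, life-years equal life expectancy", {
  nh <- natural_history_params()
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  tr <- run_arm(std, nh, life, target_p = 0, fatal_exam_risk = 0)
  ly <- sum(tr$py_healthy + tr$py_initial + tr$py_continuing + tr$py_cured)
  # quadrature oracle: survival to the model horizon at age 100
  a <- life$gompertz_a; b <- life$gompertz_b
  surv <- function(t) exp(-(a / b) * (exp(b * t) - 1))
  le <- stats::integrate(surv, 0, 50, rel.tol = 1e-10)$value
  expect_lt(abs(ly - le), 0.01)
})

test_that("exam ages misaligned with the cycle grid are rejected", {
  nh <- natural_history_params(cycle_length = 0.25)
  life <- life_table_params()
  odd <- surveillance_strategy("odd", 50, 2.7, 60)
  expect_error(run_arm(odd, nh, life, 0.01), "align")
})

test_that("traces export as tidy long CSV", {
  nh <- quarterly_nh()
  life <- life_table_params()
  std <- surveillance_strategy("5-yearly", 50, 5, 75)
  tr <- run_arm(std, nh, life, 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  df <- utils::read.csv(path)
  expect_named(df, c("cycle", "age", "quantity", "value"))
  expect_equal(nrow(df), tr$n_cycles * 16)
})
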