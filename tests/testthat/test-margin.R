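test_that("with no burden and no protection the margin is zero", {
  scen <- zero_burden_scenario()
  expect_equal(qaly_gap(scen$p_S, scen), 0, tolerance = 1e-9)
  m <- solve_margin_qaly(scen)
  expect_equal(m$p_A_star, scen$p_S)
  expect_equal(m$delta, 0)
  # with zero costs, the NMB margin coincides
  mn <- solve_margin_nmb(scen)
  expect_equal(mn$delta, 0)
})

test_that("at equal effectiveness the de-escalated arm gains QALYs", {
  scen <- ni_scenario(nh = quarterly_nh())
  expect_gt(qaly_gap(scen$p_S, scen), 0)
})

test_that("the QALY gap is strictly decreasing in the alternative event rate", {
  scen <- ni_scenario(nh = quarterly_nh())
  std <- nimargin:::scenario_arm_outcomes(scen, "standard", scen$p_S)
  grid <- seq(scen$p_S, scen$p_S + 0.03, length.out = 50)
  g <- qaly_gap(grid, scen, std)
  expect_true(all(diff(g) < 0))
})

test_that("the equipoise solver recovers closed-form linear tipping points", {
  # QALY toy: exam gain G per 1000, each extra unit of event rate losing L
  p_S <- 0.01
  G <- 8.3
  L <- 2000
  sol <- solve_equipoise(function(p) G - L * (p - p_S), p_S, tol = 1e-9)
  expect_equal(sol$p_A_star, p_S + G / L, tolerance = 1e-8)
  expect_lt(abs(sol$gap_at_solution), 1e-9)

  # NMB toy: additional per-cohort cost saving C at willingness-to-pay wtp
  wtp <- 20000
  C <- 40000
  sol_nmb <- solve_equipoise(function(p) wtp * (G - L * (p - p_S)) + C,
                             p_S, tol = 1e-9 * wtp)
  expect_equal(sol_nmb$p_A_star, p_S + (G + C / wtp) / L, tolerance = 1e-8)
})

test_that("solver failures are informative", {
  # alternative already worse at equal effectiveness: swap the arms
  scen <- ni_scenario(standard = surveillance_strategy("10-yearly", 50, 10, 75),
                      alternative = surveillance_strategy("5-yearly", 50, 5, 75),
                      nh = quarterly_nh())
  expect_error(solve_margin_qaly(scen), "never non-inferior")
  # alternative dominates everywhere: extra cases carry no penalty
  dom <- ni_scenario(nh = quarterly_nh(per_exam_protection = 0,
                                       excess_mortality_rate = 0),
                     treatment = treatment_disutility(0, 0, 0))
  expect_error(solve_margin_qaly(dom), "dominates")
})

test_that("margin results are internally consistent and reproducible", {
  scen <- ni_scenario(nh = quarterly_nh())
  m1 <- solve_margin_qaly(scen)
  m2 <- solve_margin_qaly(scen)
  expect_identical(m1$p_A_star, m2$p_A_star) # deterministic core
  expect_identical(m1$delta, m1$p_A_star - m1$p_S)
  expect_lt(abs(m1$gap_at_solution), 1e-4)
  # re-evaluating the gap from scratch reproduces it up to calibration noise
  expect_lt(abs(qaly_gap(m1$p_A_star, scen) - m1$gap_at_solution), 1e-7)
  expect_equal(m1$sample_size$n_total, 2L * m1$sample_size$n_per_arm)
  # JSON serialisation carries the scenario hash
  path <- withr::local_tempfile(fileext = ".json")
  write_margin_json(m1, path)
  rec <- jsonlite::read_json(path)
  expect_equal(rec$scenario_hash, scenario_hash(scen))
  expect_equal(rec$delta, m1$delta, tolerance = 1e-12)
})

test_that("the NMB margin reduces to the QALY margin as costs vanish", {
  # very large willingness-to-pay: the cost term becomes negligible
  scen <- ni_scenario(nh = quarterly_nh())
  mq <- solve_margin_qaly(scen, tol = 1e-6)
  mn <- solve_margin_nmb(scen, wtp = 1e12, tol = 1e-6)
  expect_lt(abs(mn$p_A_star - mq$p_A_star), 1e-6)
})

test_that("a cheaper alternative widens the NMB margin beyond the QALY margin", {
  scen <- ni_scenario(nh = quarterly_nh())
  mq <- solve_margin_qaly(scen)
  mn <- solve_margin_nmb(scen)
  expect_gte(mn$delta, mq$delta)
  # and the NMB sample size is accordingly smaller
  expect_lte(mn$sample_size$n_total, mq$sample_size$n_total)
})
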