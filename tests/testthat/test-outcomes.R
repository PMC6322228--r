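test_that("surveillance losses follow the closed-form arithmetic", {
  burden <- colonoscopy_burden()
  cm <- complication_model()
  # 1000 patients, one exam each at age 40
  tr <- toy_trace(n = 1, exams = 1, age = 40)
  sl <- surveillance_losses(tr, burden, cm)
  expect_equal(sl$qaly_lost_surveillance, 1000 * 3.1 / 365.25,
               tolerance = 1e-12)
  expect_equal(sl$qaly_lost_complications,
               1000 * 0.3 * 0.002 * 14 / 365.25, tolerance = 1e-12)
  expect_equal(sl$complication_deaths, 1000 * 0.3 / 30000, tolerance = 1e-12)

  # no exams, no losses
  sl0 <- surveillance_losses(toy_trace(), burden, cm)
  expect_equal(sl0$qaly_lost_surveillance, 0)
  expect_equal(sl0$qaly_lost_complications, 0)
  expect_equal(sl0$complication_deaths, 0)

  # doubling the polypectomy fraction doubles complication losses and deaths
  # but leaves the surveillance loss unchanged
  b2 <- colonoscopy_burden(polypectomy_fraction = 0.6)
  sl2 <- surveillance_losses(tr, b2, cm)
  expect_equal(sl2$qaly_lost_complications, 2 * sl$qaly_lost_complications)
  expect_equal(sl2$complication_deaths, 2 * sl$complication_deaths)
  expect_equal(sl2$qaly_lost_surveillance, sl$qaly_lost_surveillance)
})

test_that("treatment losses weight phase person-years by their decrements", {
  td <- treatment_disutility(initial = 0.3, continuing = 0.1, terminal = 0.45)
  expect_equal(treatment_losses(toy_trace(), td), 0)
  # 10 person-years per 1000 in the initial phase at decrement 0.3 -> 3.0
  tr <- toy_trace(n = 2, py_initial = c(0.004, 0.006))
  expect_equal(treatment_losses(tr, td), 3.0, tolerance = 1e-12)
  # all-phase decrement 1 recovers total diagnosed person-time
  td1 <- treatment_disutility(1, 1, 1)
  tr2 <- toy_trace(n = 2, py_initial = c(0.004, 0.006),
                   py_continuing = c(0.002, 0.003))
  expect_equal(treatment_losses(tr2, td1), 15, tolerance = 1e-12)
})

test_that("the QALY accounting identity holds on full model runs", {
  scen <- ni_scenario()
  for (arm in c("standard", "alternative")) {
    oc <- nimargin:::scenario_arm_outcomes(scen, arm, 0.012)
    expect_equal(oc$qaly_total + oc$qaly_lost_surveillance +
                   oc$qaly_lost_complications + oc$qaly_lost_treatment,
                 oc$life_years, tolerance = 1e-9)
    expect_true(oc$qaly_lost_surveillance >= 0)
    expect_true(oc$qaly_lost_complications >= 0)
    expect_true(oc$qaly_lost_treatment >= 0)
    expect_true(is.finite(oc$cost_total) && oc$cost_total > 0)
  }
})

test_that("losses are homogeneous of degree 1 in cohort size", {
  scen <- ni_scenario(nh = quarterly_nh())
  tr <- run_arm(scen$standard, scen$nh, scen$life, 0.01,
                fatal_exam_risk = nimargin:::scenario_fatal_risk(scen))
  oc1 <- assemble_outcomes(tr, scen$burden, scen$complications,
                           scen$treatment, scen$econ, cohort_size = 1000)
  oc5 <- assemble_outcomes(tr, scen$burden, scen$complications,
                           scen$treatment, scen$econ, cohort_size = 5000)
  for (f in c("life_years", "qaly_lost_surveillance",
              "qaly_lost_complications", "qaly_lost_treatment", "qaly_total",
              "cost_total", "n_colonoscopies")) {
    expect_equal(oc5[[f]], 5 * oc1[[f]], tolerance = 1e-12)
  }
})

test_that("outcome totals derive from the identity for any components", {
  oc <- arm_outcomes(life_years = 1000, qaly_lost_surveillance = 0,
                     qaly_lost_complications = 0, qaly_lost_treatment = 0)
  expect_equal(oc$qaly_total, oc$life_years)
  expect_error(arm_outcomes(1000, -1, 0, 0), "qaly_lost_surveillance")
  df <- as.data.frame(arm_outcomes(1000, 1, 2, 3, label = "arm"))
  expect_equal(df$qalys_per_1000, 994)
  expect_equal(df$strategy, "arm")
})
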