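test_that("a 1x1 sweep grid reproduces the direct margin solve", {
  scen <- ni_scenario(nh = quarterly_nh())
  g <- sweep_grid(disutility_scalings = 1, sensitivity_multipliers = 1)
  sw <- run_sweep(g, scen)
  m <- solve_margin_qaly(scen)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$p_A_star, m$p_A_star, tolerance = 1e-10)
  expect_equal(sw$n_total, m$sample_size$n_total)
  expect_equal(sw$per_exam_disutility_days, 3.1)
})

test_that("the default sweep completes with solved margins at every point", {
  scen <- ni_scenario(nh = quarterly_nh())
  sw <- run_sweep(sweep_grid(), scen)
  expect_equal(nrow(sw), 15L) # 5 scalings x 3 sensitivities
  expect_true(all(sw$status == "ok"))
  expect_false(is.unsorted(sw$scaling))
  # every returned tipping point satisfies the solver's gap tolerance
  for (i in seq_len(nrow(sw))) {
    scen_i <- nimargin:::apply_grid_point(scen, sw$scaling[i],
                                          sw$sensitivity[i])
    expect_lt(abs(qaly_gap(sw$p_A_star[i], scen_i)), 1e-4)
  }
  # higher disutility -> wider margin -> smaller trial, per sensitivity level
  for (se in unique(sw$sensitivity)) {
    rows <- sw[sw$sensitivity == se, ]
    rows <- rows[order(rows$scaling), ]
    expect_true(all(diff(rows$delta) > 0))
    expect_true(all(diff(rows$n_total) <= 0))
  }
  expect_equal(attr(sw, "max_n_total"), max(sw$n_total))
})

test_that("margin orderings hold across randomized scenario draws", {
  for (i in 1:10) {
    scen <- random_scenario(i)
    lo <- solve_margin_qaly(nimargin:::apply_grid_point(scen, 0.8, 1),
                            trial = NULL)
    hi <- solve_margin_qaly(nimargin:::apply_grid_point(scen, 1.2, 1),
                            trial = NULL)
    expect_gte(hi$delta, lo$delta)
    mq <- solve_margin_qaly(scen, trial = NULL)
    mn <- solve_margin_nmb(scen, trial = NULL)
    expect_gte(mn$delta, mq$delta) # alternative arm is weakly cheaper
  }
})

test_that("sweep output is a pure function of its inputs", {
  scen <- ni_scenario(nh = quarterly_nh())
  g <- sweep_grid(disutility_scalings = c(0.8, 1.2),
                  sensitivity_multipliers = 1)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(run_sweep(g, scen), p1)
  write_sweep_csv(run_sweep(g, scen), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("failed grid points are recorded, not dropped", {
  scen <- ni_scenario(nh = quarterly_nh()) # protection 0.5: x2.5 exceeds 1
  g <- sweep_grid(disutility_scalings = 1,
                  sensitivity_multipliers = c(1, 2.5))
  sw <- run_sweep(g, scen)
  expect_equal(nrow(sw), 2L)
  expect_true(any(grepl("solve_failed", sw$status)))
  expect_true(any(sw$status == "ok"))
})
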