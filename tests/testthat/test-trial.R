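test_that("the two-proportion non-inferiority formula reproduces known sizes", {
  td <- trial_design(p_S = 0.01)
  ss1 <- required_sample_size(td, 0.0042)
  expect_identical(ss1$n_per_arm, 9617L)
  expect_identical(ss1$n_total, 19234L)
  ss2 <- required_sample_size(td, 0.0062)
  expect_identical(ss2$n_per_arm, 4413L)
  expect_identical(ss2$n_total, 8826L)
  ss3 <- required_sample_size(td, 0.0045)
  expect_identical(ss3$n_total, 16754L)
  expect_error(required_sample_size(td, 0), "delta")
  expect_error(required_sample_size(td, -0.01), "delta")
})

test_that("sample size shrinks like one over the squared margin", {
  td <- trial_design(p_S = 0.01)
  deltas <- c(0.002, 0.003, 0.004, 0.006, 0.008)
  n <- vapply(deltas, function(d) required_sample_size(td, d)$n_per_arm,
              integer(1))
  expect_true(all(diff(n) < 0))
  for (d in deltas) {
    r <- required_sample_size(td, d)$n_per_arm /
      required_sample_size(td, 2 * d)$n_per_arm
    expect_equal(r, 4, tolerance = 0.01) # within ceiling effects
  }
})

test_that("full-precision z-quantiles shift the sizes by at most 5 per arm", {
  td3 <- trial_design(p_S = 0.01, z_rounding = 3)
  tdf <- trial_design(p_S = 0.01, z_rounding = Inf)
  for (d in c(0.0040, 0.0042, 0.0045, 0.0062)) {
    diff_n <- abs(required_sample_size(td3, d)$n_per_arm -
                    required_sample_size(tdf, d)$n_per_arm)
    expect_lte(diff_n, 5L)
  }
})

test_that("simulated power approaches 1 for huge trials", {
  td <- trial_design(p_S = 0.01)
  sim <- simulate_power(1e6, td, delta = 0.005, true_p_A = 0.01,
                        n_sim = 1e4, seed = 11)
  expect_gt(sim$power, 0.9999)
})

test_that("the test keeps its size on the null boundary", {
  td <- trial_design(p_S = 0.01)
  delta <- 0.005
  sim <- simulate_power(5e4, td, delta = delta, true_p_A = 0.01 + delta,
                        n_sim = 1e5, seed = 17)
  mc_se <- sqrt(0.05 * 0.95 / sim$n_sim)
  expect_lt(abs(sim$power - 0.05), 3 * mc_se)
})

test_that("analytic and simulated power agree at several design points", {
  td <- trial_design(p_S = 0.01)
  designs <- list(c(n = 6883, delta = 0.005),
                  c(n = 9617, delta = 0.0042),
                  c(n = 4413, delta = 0.0062),
                  c(n = 15000, delta = 0.004),
                  c(n = 3000, delta = 0.008))
  for (i in seq_along(designs)) {
    n <- designs[[i]]["n"]; d <- designs[[i]]["delta"]
    sim <- simulate_power(n, td, d, true_p_A = 0.01, n_sim = 1e5,
                          seed = 100 + i)
    ana <- analytic_power(n, td, d, true_p_A = 0.01)
    expect_lt(abs(sim$power - ana), 3 * sim$mc_se)
  }
})

test_that("power simulation is seed-deterministic and leaves the RNG alone", {
  td <- trial_design(p_S = 0.01)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  s1 <- simulate_power(6883, td, 0.005, n_sim = 1e4, seed = 5)
  s2 <- simulate_power(6883, td, 0.005, n_sim = 1e4, seed = 5)
  expect_identical(s1$power, s2$power)
  after <- runif(1)
  expect_identical(before, after) # global RNG state restored
})

test_that("trial design validation rejects out-of-range inputs", {
  expect_error(trial_design(p_S = 0), "p_S")
  expect_error(trial_design(alpha_one_sided = 0.6), "alpha")
  expect_error(trial_design(power = 0.4), "power")
  expect_error(simulate_power(100, trial_design(), 0.005, n_sim = 100),
               "n_sim")
})
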