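#' Non-inferiority trial design parameters
#'
#' The trial tests `H0: p_A - p_S > delta` against `Ha: p_A - p_S < delta`
#' (one-sided) for event probabilities `p_S`, `p_A` in the standard and
#' alternative arm. Normal quantiles are rounded to `z_rounding` decimals by
#' convention (3 decimals gives the familiar 1.645 and 1.282); set
#' `z_rounding = Inf` for full precision.
#'
#' @param p_S Event probability under the standard intervention.
#' @param alpha_one_sided One-sided type-I error rate; in `(0, 0.5)`.
#' @param power Target power under `assumed_true_p_A`; in `(0.5, 1)`.
#' @param assumed_true_p_A True alternative-arm event probability assumed for
#'   sizing; defaults to `p_S` (equal true efficacy).
#' @param z_rounding Decimal places for the normal quantiles (default 3).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(p_S = 0.01, alpha_one_sided = 0.05, power = 0.90,
                         assumed_true_p_A = p_S, z_rounding = 3) {
  check_scalar(p_S, "p_S")
  if (p_S <= 0 || p_S >= 1) stop("`p_S` must be in (0, 1)", call. = FALSE)
  check_scalar(alpha_one_sided, "alpha_one_sided")
  if (alpha_one_sided <= 0 || alpha_one_sided >= 0.5) {
    stop("`alpha_one_sided` must be in (0, 0.5)", call. = FALSE)
  }
  check_scalar(power, "power")
  if (power <= 0.5 || power >= 1) {
    stop("`power` must be in (0.5, 1)", call. = FALSE)
  }
  check_scalar(assumed_true_p_A, "assumed_true_p_A")
  if (assumed_true_p_A <= 0 || assumed_true_p_A >= 1) {
    stop("`assumed_true_p_A` must be in (0, 1)", call. = FALSE)
  }
  if (!(is.infinite(z_rounding) && z_rounding > 0)) {
    check_scalar(z_rounding, "z_rounding", lower = 0)
  }
  structure(list(p_S = p_S, alpha_one_sided = alpha_one_sided, power = power,
                 assumed_true_p_A = assumed_true_p_A,
                 z_rounding = z_rounding),
            class = "trial_design")
}

z_quantile <- function(p, z_rounding) {
  z <- qnorm(p)
  if (is.finite(z_rounding)) z <- round(z, z_rounding)
  z
}

#' Required sample size for a two-proportion non-inferiority trial
#'
#' Standard normal-approximation formula with unpooled variance:
#' `n/arm = ceiling((z_{1-alpha} + z_{1-beta})^2 * (p_S(1-p_S) +
#' p_A(1-p_A)) / delta^2)` with `p_A = assumed_true_p_A`.
#'
#' @param trial A [trial_design()].
#' @param delta Non-inferiority margin on the risk-difference scale; must be
#'   positive.
#' @return An object of class `sample_size` with `n_per_arm`, `n_total` and
#'   the formula inputs echoed.
#' @examples
#' required_sample_size(trial_design(p_S = 0.01), delta = 0.0042) # 9617/arm
#' @export
required_sample_size <- function(trial, delta) {
  stopifnot(inherits(trial, "trial_design"))
  check_scalar(delta, "delta")
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  z_a <- z_quantile(1 - trial$alpha_one_sided, trial$z_rounding)
  z_b <- z_quantile(trial$power, trial$z_rounding)
  pS <- trial$p_S
  pA <- trial$assumed_true_p_A
  var_sum <- pS * (1 - pS) + pA * (1 - pA)
  n_real <- (z_a + z_b)^2 * var_sum / delta^2
  n_arm <- as.integer(ceiling(n_real - 1e-9))
  structure(list(n_per_arm = n_arm, n_total = 2L * n_arm, delta = delta,
                 p_S = pS, assumed_true_p_A = pA,
                 alpha_one_sided = trial$alpha_one_sided, power = trial$power,
                 z_alpha = z_a, z_beta = z_b, n_real = n_real),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf("Non-inferiority sample size (delta = %.4g)\n", x$delta))
  cat(sprintf("  p_S = %g, assumed true p_A = %g, alpha = %g, power = %g\n",
              x$p_S, x$assumed_true_p_A, x$alpha_one_sided, x$power))
  cat(sprintf("  z quantiles %.3f + %.3f\n", x$z_alpha, x$z_beta))
  cat(sprintf("  n = %d per arm, %d total\n", x$n_per_arm, x$n_total))
  invisible(x)
}

#' Analytic power of the non-inferiority Wald test
#'
#' Normal-approximation power `Phi(delta_eff / SE - z_{1-alpha})` where
#' `delta_eff = delta - (p_A - p_S)` and `SE` uses the true rates.
#'
#' @param n_per_arm Patients per arm.
#' @param trial A [trial_design()].
#' @param delta Non-inferiority margin.
#' @param true_p_A True alternative-arm event probability; defaults to the
#'   design's `assumed_true_p_A`.
#' @return Power as a probability.
#' @export
analytic_power <- function(n_per_arm, trial, delta,
                           true_p_A = trial$assumed_true_p_A) {
  stopifnot(inherits(trial, "trial_design"))
  pS <- trial$p_S
  se <- sqrt((pS * (1 - pS) + true_p_A * (1 - true_p_A)) / n_per_arm)
  z_a <- z_quantile(1 - trial$alpha_one_sided, trial$z_rounding)
  pnorm((delta - (true_p_A - pS)) / se - z_a)
}

#' Monte-Carlo power of the non-inferiority Wald test
#'
#' Simulates binomial event counts in both arms and applies the one-sided
#' unpooled Wald test: reject inferiority when `(p_hat_A - p_hat_S - delta) /
#' SE < -z_{1-alpha}` with `SE = sqrt(p_hat_A(1-p_hat_A)/n +
#' p_hat_S(1-p_hat_S)/n)`. Degenerate replicates with `SE = 0` reject when
#' the point estimate beats the margin.
#'
#' @param n_per_arm Patients per arm in each simulated trial.
#' @param trial A [trial_design()] (supplies `p_S`, alpha and the z-rounding
#'   convention).
#' @param delta Non-inferiority margin.
#' @param true_p_A True alternative-arm event probability.
#' @param n_sim Number of simulated trials (>= 10,000).
#' @param seed Seed for the binomial draws.
#' @return A list with `power` (rejection fraction), `mc_se` (Monte-Carlo
#'   standard error), `n_sim`, `n_per_arm` and `delta`.
#' @export
simulate_power <- function(n_per_arm, trial, delta,
                           true_p_A = trial$assumed_true_p_A,
                           n_sim = 1e5, seed = 1L) {
  stopifnot(inherits(trial, "trial_design"))
  if (n_sim < 1e4) stop("`n_sim` must be at least 10,000", call. = FALSE)
  n <- as.integer(n_per_arm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xA <- rbinom(n_sim, n, true_p_A)
  xS <- rbinom(n_sim, n, trial$p_S)
  pA <- xA / n
  pS <- xS / n
  se <- sqrt(pA * (1 - pA) / n + pS * (1 - pS) / n)
  z_a <- z_quantile(1 - trial$alpha_one_sided, trial$z_rounding)
  stat_ok <- se > 0
  reject <- logical(n_sim)
  reject[stat_ok] <- (pA[stat_ok] - pS[stat_ok] - delta) / se[stat_ok] < -z_a
  reject[!stat_ok] <- (pA[!stat_ok] - pS[!stat_ok] - delta) < 0
  pow <- mean(reject)
  list(power = pow, mc_se = sqrt(pow * (1 - pow) / n_sim), n_sim = n_sim,
       n_per_arm = n, delta = delta, true_p_A = true_p_A)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
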