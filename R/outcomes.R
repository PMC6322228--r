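DAYS_PER_YEAR <- 365.25

#' QALY losses from surveillance exams and their complications
#'
#' Surveillance loss: exams times the per-exam disutility. Complication loss:
#' exams with polypectomy times the age-specific complication probability
#' times the per-complication utility loss. Complication deaths: exams with
#' polypectomy times the fatal complication probability (these deaths are
#' also lived out in the cohort trace itself, so their life-year cost is in
#' the trace's person-time, not here).
#'
#' @param trace A `cohort_trace` from [run_arm()].
#' @param burden A [colonoscopy_burden()].
#' @param model A [complication_model()].
#' @param cohort_size Reporting denominator; results are per `cohort_size`
#'   entering patients (default 1000).
#' @return A list with `qaly_lost_surveillance`, `qaly_lost_complications`
#'   (QALYs per `cohort_size`), `complications` and `complication_deaths`
#'   (counts per `cohort_size`).
#' @export
surveillance_losses <- function(trace, burden, model, cohort_size = 1000) {
  stopifnot(inherits(burden, "colonoscopy_burden"),
            inherits(model, "complication_model"))
  w <- trace$discount_start
  if (is.null(w)) w <- rep(1, length(trace$exams))
  d_days <- per_colonoscopy_disutility(burden)
  surv <- sum(trace$exams * w) * d_days / DAYS_PER_YEAR
  cprob <- complication_probability(trace$age, model)
  compl <- trace$exams * burden$polypectomy_fraction * cprob
  compl_loss <- sum(compl * w) * burden$complication_qaly_loss / DAYS_PER_YEAR
  deaths <- sum(trace$exams) * burden$polypectomy_fraction *
    burden$fatal_complication_probability
  list(qaly_lost_surveillance = surv * cohort_size,
       qaly_lost_complications = compl_loss * cohort_size,
       complications = sum(compl) * cohort_size,
       complication_deaths = deaths * cohort_size)
}

#' QALY losses from living with the disease
#'
#' Sums diagnosed person-years by phase (initial / continuing / terminal)
#' weighted by the phase utility decrements. Terminal person-time (the last
#' year before a disease death) replaces the initial/continuing time it
#' overlaps.
#'
#' @param trace A `cohort_trace`.
#' @param td A [treatment_disutility()].
#' @param cohort_size Reporting denominator (default 1000).
#' @return QALYs lost to diagnosis and treatment per `cohort_size` patients.
#' @export
treatment_losses <- function(trace, td, cohort_size = 1000) {
  stopifnot(inherits(td, "treatment_disutility"))
  n <- length(trace$py_initial)
  w <- trace$discount_mid
  if (is.null(w)) w <- rep(1, n)
  zero <- rep(0, n)
  term <- if (is.null(trace$py_terminal)) zero else trace$py_terminal
  ded_i <- if (is.null(trace$ded_initial)) zero else trace$ded_initial
  ded_c <- if (is.null(trace$ded_continuing)) zero else trace$ded_continuing
  cont <- if (is.null(trace$py_continuing)) zero else trace$py_continuing
  loss <- sum(w * ((trace$py_initial - ded_i) * td$initial +
                   (cont - ded_c) * td$continuing +
                   term * td$terminal))
  loss * cohort_size
}

# diagnosed person-years by phase, terminal-adjusted, discounted (internal)
phase_person_years <- function(trace) {
  w <- trace$discount_mid
  list(initial = sum(w * (trace$py_initial - trace$ded_initial)),
       continuing = sum(w * (trace$py_continuing - trace$ded_continuing)),
       terminal = sum(w * trace$py_terminal))
}

#' Assemble per-arm lifetime outcomes
#'
#' Collects lifetime life-years, the three QALY loss categories, total QALYs
#' (via the accounting identity `QALYs = life-years - losses`), costs and
#' exam counts, all per `cohort_size` entering patients.
#'
#' @param trace A `cohort_trace` from [run_arm()].
#' @param burden A [colonoscopy_burden()].
#' @param model A [complication_model()].
#' @param td A [treatment_disutility()].
#' @param econ An [econ_params()], or `NULL` to skip cost accounting.
#' @param cohort_size Reporting denominator (default 1000).
#' @return An `arm_outcomes` object.
#' @export
assemble_outcomes <- function(trace, burden, model, td, econ = NULL,
                              cohort_size = 1000) {
  wmid <- trace$discount_mid
  wstart <- trace$discount_start
  life_years <- sum(wmid * (trace$py_healthy + trace$py_initial +
                            trace$py_continuing + trace$py_cured)) *
    cohort_size
  sl <- surveillance_losses(trace, burden, model, cohort_size)
  treat <- treatment_losses(trace, td, cohort_size)
  n_colo <- sum(trace$exams) * cohort_size
  cost_total <- NA_real_
  if (!is.null(econ)) {
    stopifnot(inherits(econ, "econ_params"))
    cprob <- complication_probability(trace$age, model)
    compl_disc <- sum(trace$exams * burden$polypectomy_fraction * cprob *
                      wstart)
    py <- phase_person_years(trace)
    cost_total <- (sum(trace$exams * wstart) * econ$cost_per_colonoscopy +
                   compl_disc * econ$cost_per_complication +
                   py$initial * econ$cost_initial +
                   py$continuing * econ$cost_continuing +
                   py$terminal * econ$cost_terminal) * cohort_size
  }
  arm_outcomes(life_years = life_years,
               qaly_lost_surveillance = sl$qaly_lost_surveillance,
               qaly_lost_complications = sl$qaly_lost_complications,
               qaly_lost_treatment = treat,
               cost_total = cost_total,
               n_colonoscopies = n_colo,
               label = trace$strategy_label,
               target_p = trace$target_p)
}

#' Construct per-arm outcomes from their components
#'
#' Total QALYs are always derived from the accounting identity
#' `qaly_total = life_years - (surveillance + complication + treatment
#' losses)`, so the identity holds by construction for any component values
#' (for example, values printed in a published outcome table).
#'
#' @param life_years Lifetime life-years per cohort.
#' @param qaly_lost_surveillance,qaly_lost_complications,qaly_lost_treatment
#'   QALY losses per cohort; must be non-negative.
#' @param cost_total Total costs per cohort (optional).
#' @param n_colonoscopies Exam count per cohort (optional).
#' @param label,target_p Optional provenance fields.
#' @return An `arm_outcomes` object.
#' @export
arm_outcomes <- function(life_years, qaly_lost_surveillance,
                         qaly_lost_complications, qaly_lost_treatment,
                         cost_total = NA_real_, n_colonoscopies = NA_real_,
                         label = NULL, target_p = NA_real_) {
  check_scalar(life_years, "life_years", lower = 0)
  check_scalar(qaly_lost_surveillance, "qaly_lost_surveillance", lower = 0)
  check_scalar(qaly_lost_complications, "qaly_lost_complications", lower = 0)
  check_scalar(qaly_lost_treatment, "qaly_lost_treatment", lower = 0)
  qaly_total <- life_years - (qaly_lost_surveillance +
                              qaly_lost_complications + qaly_lost_treatment)
  structure(list(label = label, target_p = target_p,
                 life_years = life_years,
                 qaly_lost_surveillance = qaly_lost_surveillance,
                 qaly_lost_complications = qaly_lost_complications,
                 qaly_lost_treatment = qaly_lost_treatment,
                 qaly_total = qaly_total,
                 cost_total = cost_total,
                 n_colonoscopies = n_colonoscopies),
            class = "arm_outcomes")
}

#' Difference in total QALYs between two arms
#'
#' @param alternative,standard `arm_outcomes` objects.
#' @return `alternative$qaly_total - standard$qaly_total`.
#' @export
qaly_difference <- function(alternative, standard) {
  stopifnot(inherits(alternative, "arm_outcomes"),
            inherits(standard, "arm_outcomes"))
  alternative$qaly_total - standard$qaly_total
}

#' @export
print.arm_outcomes <- function(x, ...) {
  cat("Arm outcomes", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  life-years             %12.1f\n", x$life_years))
  cat(sprintf("  QALYs lost surveillance%12.2f\n", x$qaly_lost_surveillance))
  cat(sprintf("  QALYs lost complications%11.3f\n", x$qaly_lost_complications))
  cat(sprintf("  QALYs lost treatment   %12.2f\n", x$qaly_lost_treatment))
  cat(sprintf("  QALYs total            %12.1f\n", x$qaly_total))
  if (!is.na(x$cost_total)) {
    cat(sprintf("  total cost             %12.0f\n", x$cost_total))
  }
  if (!is.na(x$n_colonoscopies)) {
    cat(sprintf("  colonoscopies          %12.1f\n", x$n_colonoscopies))
  }
  invisible(x)
}

#' One-row data-frame view of arm outcomes
#'
#' Column names follow the conventional outcome-table layout (life-years,
#' QALYs lost by category, total QALYs, costs, exams), per 1000 patients.
#'
#' @param x An `arm_outcomes`.
#' @param row.names,optional,... Ignored; method compatibility.
#' @export
as.data.frame.arm_outcomes <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(strategy = if (is.null(x$label)) NA_character_ else x$label,
             cumulative_incidence = x$target_p,
             life_years_per_1000 = x$life_years,
             qalys_lost_surveillance_per_1000 = x$qaly_lost_surveillance,
             qalys_lost_complications_per_1000 = x$qaly_lost_complications,
             qalys_lost_treatment_per_1000 = x$qaly_lost_treatment,
             qalys_per_1000 = x$qaly_total,
             cost_total_per_1000 = x$cost_total,
             n_colonoscopies_per_1000 = x$n_colonoscopies)
}
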