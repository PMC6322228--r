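#' Per-exam burden of a surveillance colonoscopy
#'
#' Decomposes the quality-of-life burden of one surveillance exam into
#' pre-procedure anxiety and the preparation/procedure itself, plus the
#' consequences of complications. Defaults: 21 days of anxiety at a utility
#' decrement of 0.1 and 2 days of preparation and procedure at a decrement of
#' 0.5 (3.1 quality-adjusted days lost per exam); a two-week utility loss per
#' non-fatal complication; one fatal complication per 30,000 exams with
#' polypectomy; complications only occur in exams with polypectomy.
#'
#' @param anxiety_duration Days of pre-procedure anxiety.
#' @param anxiety_disutility Utility decrement during anxiety, in `[0, 1]`.
#' @param procedure_duration Days of preparation and procedure.
#' @param procedure_disutility Utility decrement during preparation and
#'   procedure, in `[0, 1]`.
#' @param complication_qaly_loss Days of full-health time lost per non-fatal
#'   complication.
#' @param fatal_complication_probability Probability of death per exam with
#'   polypectomy.
#' @param polypectomy_fraction Fraction of exams that include polypectomy
#'   (the only exams carrying complication risk).
#' @param scaling Unitless population-percentile factor multiplying the
#'   per-exam disutility (1 = population average; 0.8 and 1.2 probe less and
#'   more procedure-averse segments). Must be > 0 except in degenerate tests.
#' @return An object of class `colonoscopy_burden`.
#' @export
colonoscopy_burden <- function(anxiety_duration = 21,
                               anxiety_disutility = 0.1,
                               procedure_duration = 2,
                               procedure_disutility = 0.5,
                               complication_qaly_loss = 14,
                               fatal_complication_probability = 1 / 30000,
                               polypectomy_fraction = 0.3,
                               scaling = 1.0) {
  check_scalar(anxiety_duration, "anxiety_duration", lower = 0)
  check_scalar(anxiety_disutility, "anxiety_disutility", lower = 0, upper = 1)
  check_scalar(procedure_duration, "procedure_duration", lower = 0)
  check_scalar(procedure_disutility, "procedure_disutility", lower = 0, upper = 1)
  check_scalar(complication_qaly_loss, "complication_qaly_loss", lower = 0)
  check_scalar(fatal_complication_probability, "fatal_complication_probability",
               lower = 0, upper = 1)
  check_scalar(polypectomy_fraction, "polypectomy_fraction", lower = 0, upper = 1)
  check_scalar(scaling, "scaling", lower = 0)
  structure(list(anxiety_duration = anxiety_duration,
                 anxiety_disutility = anxiety_disutility,
                 procedure_duration = procedure_duration,
                 procedure_disutility = procedure_disutility,
                 complication_qaly_loss = complication_qaly_loss,
                 fatal_complication_probability = fatal_complication_probability,
                 polypectomy_fraction = polypectomy_fraction,
                 scaling = scaling),
            class = "colonoscopy_burden")
}

#' Quality-adjusted days lost per colonoscopy
#'
#' `scaling * (anxiety_duration * anxiety_disutility + procedure_duration *
#' procedure_disutility)`, in days. At the defaults this is 3.1 days.
#'
#' @param burden A [colonoscopy_burden()].
#' @return Days of full-health time lost per exam.
#' @examples
#' per_colonoscopy_disutility(colonoscopy_burden()) # 3.1
#' @export
per_colonoscopy_disutility <- function(burden) {
  stopifnot(inherits(burden, "colonoscopy_burden"))
  burden$scaling * (burden$anxiety_duration * burden$anxiety_disutility +
                    burden$procedure_duration * burden$procedure_disutility)
}

#' Age-dependent complication risk of colonoscopy with polypectomy
#'
#' The risk grows exponentially with age between two anchors. Defaults: 2
#' complications per 1000 exams at age 40 rising to 38 per 1000 at age 85.
#'
#' @param rate_at_40 Complication probability per exam with polypectomy at
#'   age 40; must be in `(0, 1)`.
#' @param rate_at_85 Same at age 85; must be at least `rate_at_40`.
#' @return An object of class `complication_model`.
#' @export
complication_model <- function(rate_at_40 = 0.002, rate_at_85 = 0.038) {
  check_scalar(rate_at_40, "rate_at_40", upper = 1)
  check_scalar(rate_at_85, "rate_at_85", upper = 1)
  if (rate_at_40 <= 0 || rate_at_85 <= 0) {
    stop("complication anchor rates must be positive", call. = FALSE)
  }
  if (rate_at_85 < rate_at_40) {
    stop("`rate_at_85` must be >= `rate_at_40`", call. = FALSE)
  }
  structure(list(rate_at_40 = rate_at_40, rate_at_85 = rate_at_85,
                 age_lo = 40, age_hi = 85),
            class = "complication_model")
}

#' Complication probability per exam with polypectomy at a given age
#'
#' `r(a) = rate_at_40 * exp(k * (a - 40))` with `k = log(rate_at_85 /
#' rate_at_40) / 45`; extrapolation beyond the anchor ages is allowed and the
#' result is capped at 1.
#'
#' @param age Age in years (vectorised); must be non-negative.
#' @param model A [complication_model()].
#' @return Probability per exam with polypectomy.
#' @examples
#' complication_probability(40, complication_model()) # 0.002
#' complication_probability(85, complication_model()) # 0.038
#' @export
complication_probability <- function(age, model) {
  stopifnot(inherits(model, "complication_model"))
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  k <- log(model$rate_at_85 / model$rate_at_40) / (model$age_hi - model$age_lo)
  pmin(1, model$rate_at_40 * exp(k * (age - model$age_lo)))
}

#' Utility decrements while living with the disease
#'
#' Phase-specific utility decrements applied to diagnosed person-time: the
#' first year after diagnosis (initial phase), subsequent diagnosed years up
#' to the cure horizon (continuing phase), and the last year of life before a
#' disease death (terminal phase, replacing the phase it overlaps). The
#' default values are synthetic placeholders of plausible magnitude; analyses
#' that depend on them should be read as orderings, not absolute levels.
#'
#' @param initial Utility decrement during the first year after diagnosis.
#' @param continuing Decrement in subsequent diagnosed years.
#' @param terminal Decrement in the last year before a disease death.
#' @return An object of class `treatment_disutility`.
#' @export
treatment_disutility <- function(initial = 0.30, continuing = 0.10,
                                 terminal = 0.45) {
  check_scalar(initial, "initial", lower = 0, upper = 1)
  check_scalar(continuing, "continuing", lower = 0, upper = 1)
  check_scalar(terminal, "terminal", lower = 0, upper = 1)
  structure(list(initial = initial, continuing = continuing,
                 terminal = terminal),
            class = "treatment_disutility")
}

#' Economic parameters for the net-monetary-benefit margin
#'
#' Unit costs and the willingness-to-pay threshold. The cost defaults are
#' synthetic placeholders of plausible European magnitude; the
#' willingness-to-pay default is the conventional EUR 20,000 per QALY.
#'
#' @param cost_per_colonoscopy Cost of one surveillance exam (currency units).
#' @param cost_per_complication Cost of managing one non-fatal complication.
#' @param cost_initial,cost_continuing,cost_terminal Disease-management cost
#'   per person-year in the initial / continuing / terminal phase.
#' @param wtp Willingness-to-pay per QALY (lambda); must be positive.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(cost_per_colonoscopy = 885,
                        cost_per_complication = 10000,
                        cost_initial = 25000,
                        cost_continuing = 2500,
                        cost_terminal = 30000,
                        wtp = 20000) {
  for (nm in c("cost_per_colonoscopy", "cost_per_complication",
               "cost_initial", "cost_continuing", "cost_terminal")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  check_scalar(wtp, "wtp")
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  structure(list(cost_per_colonoscopy = cost_per_colonoscopy,
                 cost_per_complication = cost_per_complication,
                 cost_initial = cost_initial,
                 cost_continuing = cost_continuing,
                 cost_terminal = cost_terminal,
                 wtp = wtp),
            class = "econ_params")
}
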