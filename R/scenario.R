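#' Build a complete analysis scenario
#'
#' A scenario bundles everything one margin analysis needs: the two
#' surveillance arms, background mortality, reduced-form natural history,
#' per-exam burden, the complication model, disease disutilities, economic
#' parameters, the trial design and the standard-arm event rate. The defaults
#' describe the worked example: 50-year-old low-risk adenoma patients under
#' 5-yearly (standard) versus 10-yearly (alternative) surveillance
#' colonoscopy to age 75, with a 10-year colorectal-cancer incidence of 1\%
#' expected under the standard arm.
#'
#' @param standard,alternative [surveillance_strategy()] objects for the two
#'   arms.
#' @param life A [life_table_params()].
#' @param nh A [natural_history_params()].
#' @param burden A [colonoscopy_burden()].
#' @param complications A [complication_model()].
#' @param treatment A [treatment_disutility()].
#' @param econ An [econ_params()].
#' @param trial A [trial_design()].
#' @param p_S Cumulative event rate under the standard arm over the trial
#'   horizon; default 0.01.
#' @param horizon_years Trial horizon for the event rate; default 10.
#' @return An object of class `ni_scenario`.
#' @export
ni_scenario <- function(standard = surveillance_strategy("5-yearly surveillance",
                                                         50, 5, 75),
                        alternative = surveillance_strategy("10-yearly surveillance",
                                                            50, 10, 75),
                        life = life_table_params(),
                        nh = natural_history_params(),
                        burden = colonoscopy_burden(),
                        complications = complication_model(),
                        treatment = treatment_disutility(),
                        econ = econ_params(),
                        trial = trial_design(),
                        p_S = 0.01,
                        horizon_years = 10) {
  stopifnot(inherits(standard, "surveillance_strategy"),
            inherits(alternative, "surveillance_strategy"),
            inherits(life, "life_table_params"),
            inherits(nh, "natural_history_params"),
            inherits(burden, "colonoscopy_burden"),
            inherits(complications, "complication_model"),
            inherits(treatment, "treatment_disutility"),
            inherits(econ, "econ_params"),
            inherits(trial, "trial_design"))
  check_scalar(p_S, "p_S", lower = 0, upper = 1 - 1e-12)
  check_scalar(horizon_years, "horizon_years")
  structure(list(standard = standard, alternative = alternative,
                 life = life, nh = nh, burden = burden,
                 complications = complications, treatment = treatment,
                 econ = econ, trial = trial, p_S = p_S,
                 horizon_years = horizon_years,
                 schema_version = SCENARIO_SCHEMA_VERSION),
            class = "ni_scenario")
}

SCENARIO_SCHEMA_VERSION <- 1L

#' @export
print.ni_scenario <- function(x, ...) {
  cat("Non-inferiority margin scenario (schema v", x$schema_version, ")\n",
      sep = "")
  cat(sprintf("  standard:    %s, exams at {%s}\n", x$standard$label,
              paste(x$standard$exam_ages, collapse = ", ")))
  cat(sprintf("  alternative: %s, exams at {%s}\n", x$alternative$label,
              paste(x$alternative$exam_ages, collapse = ", ")))
  cat(sprintf("  p_S = %g over %g years; per-exam disutility %.3g days\n",
              x$p_S, x$horizon_years, per_colonoscopy_disutility(x$burden)))
  invisible(x)
}

# per-exam fatal risk wired from the burden parameters
scenario_fatal_risk <- function(scenario) {
  scenario$burden$polypectomy_fraction *
    scenario$burden$fatal_complication_probability
}

# closure evaluating one arm's outcomes as a function of the event rate,
# with the hazard grid cached and the calibration warm-started from the
# previous call (the margin solvers and gap functions evaluate many nearby
# rates on the same arm)
scenario_evaluator <- function(scenario, arm = c("standard", "alternative")) {
  arm <- match.arg(arm)
  strat <- scenario[[arm]]
  grid <- cohort_grid(strat, scenario$nh, scenario$life)
  fatal <- scenario_fatal_risk(scenario)
  hc <- min(as.integer(round(scenario$horizon_years / grid$dt)),
            grid$n_cycles)
  last_psi <- NULL
  function(p) {
    psi <- calibrate_psi(grid, p, fatal, hc, init = last_psi)
    last_psi <<- psi
    trace <- run_arm_on_grid(grid, scenario$nh, strat$label, p, fatal, hc,
                             psi)
    assemble_outcomes(trace, scenario$burden, scenario$complications,
                      scenario$treatment, scenario$econ)
  }
}

# run one arm of the scenario at event rate p and assemble its outcomes
scenario_arm_outcomes <- function(scenario, arm = c("standard", "alternative"),
                                  p) {
  scenario_evaluator(scenario, arm)(p)
}

# ---- YAML configuration ----------------------------------------------------

# allowed keys per config section, mapped onto constructor arguments
scenario_schema <- function() {
  list(
    schema_version = NULL,
    p_S = NULL,
    horizon_years = NULL,
    standard = c("label", "start_age", "interval", "stop_age"),
    alternative = c("label", "start_age", "interval", "stop_age"),
    life = c("model", "gompertz_a", "gompertz_b", "reference_age", "table"),
    natural_history = c("baseline_rate", "baseline_ref_age", "doubling_time",
                        "per_exam_protection", "sensitivity_multiplier",
                        "excess_mortality_rate", "cure_horizon",
                        "cycle_length", "horizon_age", "discount_rate"),
    burden = c("anxiety_duration", "anxiety_disutility", "procedure_duration",
               "procedure_disutility", "complication_qaly_loss",
               "fatal_complication_probability", "polypectomy_fraction",
               "scaling"),
    complications = c("rate_at_40", "rate_at_85"),
    treatment = c("initial", "continuing", "terminal"),
    econ = c("cost_per_colonoscopy", "cost_per_complication", "cost_initial",
             "cost_continuing", "cost_terminal", "wtp"),
    trial = c("p_S", "alpha_one_sided", "power", "assumed_true_p_A",
              "z_rounding"),
    sweep = c("disutility_scalings", "sensitivity_multipliers", "criterion")
  )
}

#' Load a scenario from a YAML configuration file
#'
#' The file may override any subset of the default scenario; omitted sections
#' and fields keep their defaults (an empty file yields the full default
#' scenario). Unknown sections or fields are rejected with the offending
#' field path. The configuration format is YAML; see
#' `system.file("extdata", "adenoma_surveillance.yaml", package = "nimargin")` for a
#' documented example.
#'
#' @param path Path to a YAML file.
#' @param quiet If `FALSE` (default), the effective configuration is echoed
#'   as a message.
#' @return A validated [ni_scenario()], with the sweep grid (if any) attached
#'   as attribute `"sweep"`.
#' @export
load_scenario <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  schema <- scenario_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in intersect(names(cfg), names(schema))) {
    allowed <- schema[[sec]]
    if (is.null(allowed)) next
    if (!is.list(cfg[[sec]])) {
      stop("config section `", sec, "` must be a mapping", call. = FALSE)
    }
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad)) {
      stop("unknown config field(s): ",
           paste(paste0(sec, ".", bad), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(cfg$schema_version) &&
      cfg$schema_version != SCENARIO_SCHEMA_VERSION) {
    stop("unsupported schema_version: ", cfg$schema_version, call. = FALSE)
  }

  build <- function(fn, section, defaults = list()) {
    args <- modifyList(defaults, cfg[[section]] %||% list())
    tryCatch(do.call(fn, args), error = function(e) {
      stop("invalid config in section `", section, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  std_def <- list(label = "5-yearly surveillance", start_age = 50,
                  interval = 5, stop_age = 75)
  alt_def <- list(label = "10-yearly surveillance", start_age = 50,
                  interval = 10, stop_age = 75)
  life_cfg <- cfg$life %||% list()
  if (!is.null(life_cfg$table)) life_cfg$table <- as.data.frame(life_cfg$table)
  cfg$life <- life_cfg
  scen <- ni_scenario(
    standard = build(surveillance_strategy, "standard", std_def),
    alternative = build(surveillance_strategy, "alternative", alt_def),
    life = build(life_table_params, "life"),
    nh = build(natural_history_params, "natural_history"),
    burden = build(colonoscopy_burden, "burden"),
    complications = build(complication_model, "complications"),
    treatment = build(treatment_disutility, "treatment"),
    econ = build(econ_params, "econ"),
    trial = build(trial_design, "trial"),
    p_S = cfg$p_S %||% 0.01,
    horizon_years = cfg$horizon_years %||% 10
  )
  attr(scen, "sweep") <- build(sweep_grid, "sweep")
  if (!quiet) {
    message("effective configuration:\n",
            yaml::as.yaml(scenario_to_list(scen)))
  }
  scen
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-list view of a scenario (for hashing / manifests / echoing)
scenario_to_list <- function(scenario) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  list(schema_version = scenario$schema_version,
       p_S = scenario$p_S,
       horizon_years = scenario$horizon_years,
       standard = strip(scenario$standard),
       alternative = strip(scenario$alternative),
       life = strip(scenario$life),
       natural_history = strip(scenario$nh),
       burden = strip(scenario$burden),
       complications = strip(scenario$complications),
       treatment = strip(scenario$treatment),
       econ = strip(scenario$econ),
       trial = strip(scenario$trial))
}

#' Content hash of a scenario
#'
#' MD5 of the canonical JSON serialisation of the effective configuration;
#' used for provenance in result records and run manifests.
#'
#' @param scenario An [ni_scenario()].
#' @return A 32-character hex string.
#' @export
scenario_hash <- function(scenario) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(scenario_to_list(scenario), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
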