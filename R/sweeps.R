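#' Grid for one-way uncertainty sweeps
#'
#' The sweep repeats the margin analysis over a grid of per-exam disutility
#' scalings (population-percentile factors on the 3.1-day base burden) and
#' test-sensitivity multipliers (scaling the per-exam protection), tracing
#' the line of QALY (or NMB) equipoise with its margins and sample sizes.
#'
#' @param disutility_scalings Positive scaling factors for the per-exam
#'   disutility; default `c(0.5, 0.8, 1, 1.2, 1.5)`.
#' @param sensitivity_multipliers Positive multipliers on the per-exam
#'   protection; default `c(0.95, 1, 1.05)`.
#' @param criterion `"qaly"` or `"nmb"`.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(disutility_scalings = c(0.5, 0.8, 1, 1.2, 1.5),
                       sensitivity_multipliers = c(0.95, 1, 1.05),
                       criterion = c("qaly", "nmb")) {
  criterion <- match.arg(criterion)
  if (!length(disutility_scalings) || !length(sensitivity_multipliers)) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  if (any(disutility_scalings <= 0) || any(sensitivity_multipliers <= 0)) {
    stop("sweep grid values must be positive", call. = FALSE)
  }
  structure(list(disutility_scalings = sort(disutility_scalings),
                 sensitivity_multipliers = sort(sensitivity_multipliers),
                 criterion = criterion),
            class = "sweep_grid")
}

# scenario with one grid point applied
apply_grid_point <- function(scenario, scaling, sensitivity) {
  b <- scenario$burden
  b$scaling <- scaling
  nh <- scenario$nh
  nh$sensitivity_multiplier <- sensitivity
  if (nh$per_exam_protection * sensitivity > 1) {
    stop("per_exam_protection * sensitivity_multiplier exceeds 1 at ",
         "sensitivity ", sensitivity, call. = FALSE)
  }
  scenario$burden <- b
  scenario$nh <- nh
  scenario
}

#' Run the uncertainty sweep
#'
#' Solves the margin independently at every grid point (rows are a pure
#' function of the inputs; execution order does not matter) and attaches the
#' required sample size. Failed solves are recorded with a failure code in
#' the `status` column, never dropped.
#'
#' @param grid A [sweep_grid()].
#' @param scenario An [ni_scenario()].
#' @param trial A [trial_design()]; defaults to the scenario's.
#' @param tol Gap tolerance passed to the solver.
#' @return A data frame, one row per grid point, sorted by (scaling,
#'   sensitivity), with columns `scaling`, `sensitivity`,
#'   `per_exam_disutility_days`, `p_A_star`, `delta`, `n_per_arm`, `n_total`,
#'   `status`. The attribute `"max_n_total"` carries the conservative
#'   (largest) sample size over the grid.
#' @export
run_sweep <- function(grid, scenario, trial = scenario$trial, tol = 1e-4) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(scenario, "ni_scenario"))
  pts <- expand.grid(sensitivity = grid$sensitivity_multipliers,
                     scaling = grid$disutility_scalings)
  pts <- pts[order(pts$scaling, pts$sensitivity), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    sc <- pts$scaling[i]
    se <- pts$sensitivity[i]
    row <- data.frame(scaling = sc, sensitivity = se,
                      per_exam_disutility_days = NA_real_,
                      p_A_star = NA_real_, delta = NA_real_,
                      n_per_arm = NA_integer_, n_total = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      scen_i <- apply_grid_point(scenario, sc, se)
      row$per_exam_disutility_days <-
        per_colonoscopy_disutility(scen_i$burden)
      m <- if (grid$criterion == "qaly") {
        solve_margin_qaly(scen_i, trial = trial, tol = tol)
      } else {
        solve_margin_nmb(scen_i, trial = trial, tol = tol)
      }
      row$p_A_star <- m$p_A_star
      row$delta <- m$delta
      if (!is.null(m$sample_size)) {
        row$n_per_arm <- m$sample_size$n_per_arm
        row$n_total <- m$sample_size$n_total
      }
      row
    }, error = function(e) {
      row$status <- paste0("solve_failed: ", conditionMessage(e))
      row
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "criterion") <- grid$criterion
  attr(out, "max_n_total") <- if (all(is.na(out$n_total))) NA_integer_
                              else max(out$n_total, na.rm = TRUE)
  out
}

#' Write sweep results to CSV
#'
#' @param sweep A data frame from [run_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}

#' Plot the line of QALY equipoise
#'
#' Tipping-point event rate against per-exam disutility, one line per
#' sensitivity multiplier, annotated with the associated total sample sizes.
#' Requires ggplot2.
#'
#' @param sweep A data frame from [run_sweep()].
#' @return A ggplot object.
#' @export
plot_equipoise <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_equipoise() requires the ggplot2 package", call. = FALSE)
  }
  ok <- sweep[sweep$status == "ok", , drop = FALSE]
  ok$sensitivity_f <- factor(ok$sensitivity)
  ok$p_star_pct <- 100 * ok$p_A_star
  ggplot2::ggplot(ok, ggplot2::aes_string(x = "per_exam_disutility_days",
                                          y = "p_star_pct",
                                          colour = "sensitivity_f")) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes_string(label = "n_total"), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "per-exam disutility (days)",
                  y = "event rate at equipoise (%)",
                  colour = "sensitivity\nmultiplier",
                  title = "Line of QALY equipoise",
                  subtitle = "labels: total sample size at the implied margin") +
    ggplot2::theme_minimal()
}
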