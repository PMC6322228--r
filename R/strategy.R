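#' Define a surveillance strategy
#'
#' A surveillance strategy is an exam schedule: exams at `start_age + k *
#' interval` for k = 1, 2, ..., truncated at `stop_age`. The age at entry
#' itself carries no scheduled exam (the qualifying procedure happens at
#' entry and is common to all arms).
#'
#' @param label Short human-readable name for the arm.
#' @param start_age Age at cohort entry (years).
#' @param interval Years between scheduled exams; must be positive.
#' @param stop_age Age after which no exams are scheduled; must be at least
#'   `start_age`.
#' @return An object of class `surveillance_strategy` with the derived
#'   `exam_ages`.
#' @examples
#' surveillance_strategy("10-yearly", start_age = 50, interval = 10, stop_age = 75)
#' @export
surveillance_strategy <- function(label, start_age, interval, stop_age) {
  stopifnot(is.character(label), length(label) == 1L)
  check_scalar(start_age, "start_age", lower = 0)
  check_scalar(interval, "interval")
  check_scalar(stop_age, "stop_age", lower = 0)
  if (interval <= 0) {
    stop("`interval` must be positive (got ", interval, ")", call. = FALSE)
  }
  if (stop_age < start_age) {
    stop("`stop_age` must be >= `start_age`", call. = FALSE)
  }
  out <- structure(
    list(label = label, start_age = start_age, interval = interval,
         stop_age = stop_age),
    class = "surveillance_strategy"
  )
  out$exam_ages <- build_schedule(out)
  out
}

#' Exam ages implied by a surveillance strategy
#'
#' @param strategy A [surveillance_strategy()].
#' @return Sorted, duplicate-free exam ages in `(start_age, stop_age]`;
#'   possibly empty.
#' @examples
#' build_schedule(surveillance_strategy("5-yearly", 50, 5, 75))
#' @export
build_schedule <- function(strategy) {
  stopifnot(inherits(strategy, "surveillance_strategy"))
  if (strategy$interval <= 0) {
    stop("`interval` must be positive", call. = FALSE)
  }
  kmax <- floor((strategy$stop_age - strategy$start_age) / strategy$interval)
  if (kmax < 1) return(numeric(0))
  ages <- strategy$start_age + strategy$interval * seq_len(kmax)
  sort(unique(ages[ages <= strategy$stop_age]))
}

#' @export
print.surveillance_strategy <- function(x, ...) {
  cat("Surveillance strategy:", x$label, "\n")
  cat(sprintf("  entry age %g, exams every %g y until age %g\n",
              x$start_age, x$interval, x$stop_age))
  if (length(x$exam_ages)) {
    cat("  exam ages:", paste(x$exam_ages, collapse = ", "), "\n")
  } else {
    cat("  exam ages: none\n")
  }
  invisible(x)
}

# shared scalar validator
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop("`", name, "` must be in [", lower, ", ", upper, "] (got ", x, ")",
         call. = FALSE)
  }
  invisible(x)
}
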