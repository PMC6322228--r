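#' Background (other-cause) mortality parameters
#'
#' Either a Gompertz hazard, `mu(a) = gompertz_a * exp(gompertz_b * (a -
#' reference_age))`, or a tabulated set of annual death probabilities. The
#' defaults give a residual life expectancy at age 50 in the low twenties of
#' years, the magnitude typical of a screening-age cohort.
#'
#' @param model `"gompertz"` or `"tabulated"`.
#' @param gompertz_a Hazard at `reference_age`, per year; must be >= 0.
#' @param gompertz_b Log-hazard slope, per year of age; must be >= 0 so the
#'   hazard is non-decreasing with age.
#' @param reference_age Age (years) at which the hazard equals `gompertz_a`.
#' @param table For `model = "tabulated"`: a data frame with columns `age`
#'   and `qx` (annual death probability in `[0, 1)`), one row per integer
#'   age. Ages beyond the last row reuse the last `qx`'s hazard.
#' @return An object of class `life_table_params`.
#' @export
life_table_params <- function(model = c("gompertz", "tabulated"),
                              gompertz_a = 0.004, gompertz_b = 0.09,
                              reference_age = 50, table = NULL) {
  model <- match.arg(model)
  if (model == "gompertz") {
    check_scalar(gompertz_a, "gompertz_a", lower = 0)
    check_scalar(gompertz_b, "gompertz_b", lower = 0)
    check_scalar(reference_age, "reference_age", lower = 0)
  } else {
    if (is.null(table) || !all(c("age", "qx") %in% names(table))) {
      stop("tabulated life table needs a `table` with columns age, qx",
           call. = FALSE)
    }
    table <- as.data.frame(table)[order(table$age), , drop = FALSE]
    if (any(table$qx < 0 | table$qx >= 1)) {
      stop("tabulated qx must be in [0, 1)", call. = FALSE)
    }
  }
  structure(list(model = model, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, reference_age = reference_age,
                 table = table),
            class = "life_table_params")
}

# instantaneous other-cause hazard at (possibly fractional) ages
lt_hazard <- function(params, age) {
  stopifnot(inherits(params, "life_table_params"))
  if (params$model == "gompertz") {
    h <- params$gompertz_a *
      exp(params$gompertz_b * (age - params$reference_age))
  } else {
    tb <- params$table
    hz <- -log(1 - tb$qx) # piecewise-constant hazard per age year
    idx <- findInterval(age, tb$age)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(tb)] <- nrow(tb)
    h <- hz[idx]
  }
  if (any(h < 0)) stop("negative mortality hazard", call. = FALSE)
  h
}

#' Annual death probabilities from mortality parameters
#'
#' Converts the hazard to annual death probabilities `qx = 1 - exp(-H)`,
#' with `H` the hazard integrated over each year of age.
#'
#' @param params A [life_table_params()].
#' @param ages Integer ages at which to evaluate (years); default 0..109.
#' @return A data frame with columns `age` and `qx`.
#' @export
build_life_table <- function(params, ages = 0:109) {
  H <- vapply(ages, function(a) {
    integrate_hazard(params, a, a + 1)
  }, numeric(1))
  data.frame(age = ages, qx = 1 - exp(-H))
}

# exact cumulative hazard on [a0, a1]
integrate_hazard <- function(params, a0, a1) {
  if (params$model == "gompertz") {
    a <- params$gompertz_a; b <- params$gompertz_b; r <- params$reference_age
    if (b == 0) return(a * (a1 - a0))
    (a / b) * (exp(b * (a1 - r)) - exp(b * (a0 - r)))
  } else {
    # piecewise-constant hazard: integrate year by year
    grid <- seq(floor(a0), ceiling(a1))
    tot <- 0
    for (i in seq_len(length(grid) - 1)) {
      lo <- max(a0, grid[i]); hi <- min(a1, grid[i + 1])
      if (hi > lo) tot <- tot + lt_hazard(params, lo) * (hi - lo)
    }
    tot
  }
}

#' Residual life expectancy implied by the annual life table
#'
#' Standard abridged computation from annual death probabilities with a
#' half-year correction for the year of death.
#'
#' @param params A [life_table_params()].
#' @param from_age Starting age (years).
#' @param max_age Upper truncation age for the summation.
#' @return Residual life expectancy in years.
#' @export
life_expectancy <- function(params, from_age, max_age = 110) {
  tb <- build_life_table(params, ages = from_age:(max_age - 1))
  px <- 1 - tb$qx
  l <- cumprod(c(1, px))       # survivors at each birthday
  lx <- l[-length(l)]
  # person-years in each year: survivors of the year + half a year for deaths
  sum(lx * (px + (1 - px) / 2))
}
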