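#' Parameters for the cell-population composition model
#'
#' The model tracks two co-cultured populations in daily (24 h) steps: a
#' non-dividing adipocyte-derived population and an "other" proliferative
#' population (e.g. contaminating multipotent progenitors). Each day both
#' populations are thinned by a common survival fraction and the proliferative
#' population additionally grows by the daily growth factor
#' `1 + 24/division_time` (the default, linear within-day approximation) or
#' `2^(24/division_time)` (exact exponential doubling, available via
#' `growth = "exponential"`).
#'
#' @param survival Fraction of each population surviving every 24 h period,
#'   in (0, 1]. Default 0.99 (99% daily survival).
#' @param division_time Doubling time of the proliferative population, in
#'   hours; must be > 0. Default 24.
#' @param adipocyte_0,other_0 Non-negative initial abundances (counts or
#'   fractions; only their ratio matters for composition). Defaults 99 and 1,
#'   i.e. a 1% initial proliferative fraction.
#' @param n_days Non-negative integer number of 24 h steps to simulate.
#'   Default 26, the culture duration from isolation to endpoint.
#' @param growth Within-day growth model for the proliferative population:
#'   `"linear"` (factor `1 + 24/division_time`, the default) or
#'   `"exponential"` (factor `2^(24/division_time)`).
#'
#' @return An object of class `population_model_params` (a named list).
#' @seealso [simulate_composition()], [closed_form_fraction()],
#'   [sweep_doubling_times()]
#' @export
#' @examples
#' population_model_params(survival = 0.99, division_time = 24, n_days = 26)
population_model_params <- function(survival = 0.99, division_time = 24,
                                    adipocyte_0 = 99, other_0 = 1,
                                    n_days = 26,
                                    growth = c("linear", "exponential")) {
  growth <- match.arg(growth)
  stopifnot(
    "survival must be in (0, 1]" = is.numeric(survival) &&
      length(survival) == 1 && survival > 0 && survival <= 1,
    "division_time must be > 0" = is.numeric(division_time) &&
      length(division_time) == 1 && division_time > 0,
    "initial abundances must be non-negative" =
      adipocyte_0 >= 0 && other_0 >= 0,
    "at least one population must be present" = adipocyte_0 + other_0 > 0,
    "n_days must be a non-negative integer" =
      is.numeric(n_days) && length(n_days) == 1 &&
      n_days >= 0 && n_days == round(n_days)
  )
  structure(
    list(survival = survival, division_time = division_time,
         adipocyte_0 = adipocyte_0, other_0 = other_0,
         n_days = as.integer(n_days), growth = growth),
    class = "population_model_params"
  )
}

# daily growth factor of the proliferative population
daily_growth_factor <- function(division_time, growth = "linear") {
  if (division_time <= 0) stop("division_time must be > 0")
  switch(growth,
    linear      = 1 + 24 / division_time,
    exponential = 2^(24 / division_time),
    stop("unknown growth model: ", growth)
  )
}

#' Advance the composition model by one 24 h step
#'
#' Applies the daily recurrence exactly:
#' `adipocyte' = adipocyte * survival` and
#' `other' = other * survival * (1 + 24/division_time)`
#' (or with the exponential growth factor when the parameters request it).
#' No rescaling or normalisation is performed.
#'
#' @param adipocyte,other Non-negative current abundances.
#' @param params A [population_model_params()] object.
#' @return Named numeric vector with elements `adipocyte` and `other`.
#' @export
#' @examples
#' p <- population_model_params(survival = 0.99, division_time = 24)
#' step_composition(99, 1, p)  # c(adipocyte = 98.01, other = 1.98)
step_composition <- function(adipocyte, other, params) {
  stopifnot(inherits(params, "population_model_params"))
  adipocyte <- unname(adipocyte)
  other <- unname(other)
  if (is.na(adipocyte) || is.na(other) || adipocyte < 0 || other < 0) {
    stop("abundances must be non-negative")
  }
  g <- daily_growth_factor(params$division_time, params$growth)
  c(adipocyte = adipocyte * params$survival,
    other     = other * params$survival * g)
}

#' Simulate the day-by-day composition trajectory
#'
#' Iterates [step_composition()] for `n_days` steps and records, for each day
#' `n = 0..n_days`, the abundances and the proliferative ("other") fraction
#' `100 * other_n / (other_n + adipocyte_n)` in percent.
#'
#' @param params A [population_model_params()] object.
#' @return A data frame of class `composition_trajectory` with columns
#'   `day`, `adipocyte`, `other`, `other_fraction_pct`.
#' @export
#' @examples
#' tr <- simulate_composition(population_model_params())
#' tail(tr, 1)  # > 95% proliferative after 26 days from a 1% seed
simulate_composition <- function(params) {
  stopifnot(inherits(params, "population_model_params"))
  n <- params$n_days
  adipocyte <- numeric(n + 1)
  other <- numeric(n + 1)
  adipocyte[1] <- params$adipocyte_0
  other[1] <- params$other_0
  if (n > 0) {
    for (i in seq_len(n)) {
      s <- step_composition(adipocyte[i], other[i], params)
      adipocyte[i + 1] <- s[["adipocyte"]]
      other[i + 1] <- s[["other"]]
    }
  }
  out <- data.frame(
    day = 0:n,
    adipocyte = adipocyte,
    other = other,
    other_fraction_pct = 100 * other / (other + adipocyte)
  )
  class(out) <- c("composition_trajectory", "data.frame")
  out
}

#' Closed-form proliferative fraction after n days
#'
#' Because both populations share the same daily survival, survival cancels
#' from the composition: with initial proliferative fraction `f0` and daily
#' growth factor `g`, the fraction after `n_days` is
#' `f0 * g^n / (f0 * g^n + (1 - f0))`.
#'
#' @param f0 Initial proliferative fraction in \[0, 1\].
#' @param division_time Doubling time in hours (> 0).
#' @param n_days Non-negative integer number of days.
#' @param growth Growth model, as in [population_model_params()].
#' @return Proliferative fraction in \[0, 1\] after `n_days`.
#' @export
#' @examples
#' closed_form_fraction(0.01, division_time = 24, n_days = 26)  # > 0.95
closed_form_fraction <- function(f0, division_time, n_days,
                                 growth = c("linear", "exponential")) {
  growth <- match.arg(growth)
  stopifnot(
    "f0 must be in [0, 1]" = all(f0 >= 0 & f0 <= 1),
    "n_days must be a non-negative integer" =
      n_days >= 0 && n_days == round(n_days)
  )
  g <- daily_growth_factor(division_time, growth)
  gr <- g^n_days
  f0 * gr / (f0 * gr + (1 - f0))
}

#' Smallest initial proliferative fraction reaching a target composition
#'
#' Inverts [closed_form_fraction()] algebraically: the smallest `f0` with
#' final fraction at least `target_fraction` after `n_days` is
#' `target / (g^n * (1 - target) + target)`. For `n_days = 0` this reduces to
#' the target itself (no growth).
#'
#' @param target_fraction Target proliferative fraction in (0, 1).
#' @param division_time Doubling time in hours (> 0).
#' @param n_days Non-negative integer number of days.
#' @param growth Growth model, as in [population_model_params()].
#' @return The minimal initial fraction `f0` in (0, 1).
#' @export
#' @examples
#' # < 1% suffices to reach 95% of the culture by day 26 at a 24 h doubling time
#' minimal_initial_fraction(0.95, division_time = 24, n_days = 26)
minimal_initial_fraction <- function(target_fraction, division_time, n_days,
                                     growth = c("linear", "exponential")) {
  growth <- match.arg(growth)
  stopifnot(
    "target_fraction must be in (0, 1)" =
      target_fraction > 0 && target_fraction < 1,
    "n_days must be a non-negative integer" =
      n_days >= 0 && n_days == round(n_days)
  )
  g <- daily_growth_factor(division_time, growth)
  gr <- g^n_days
  target_fraction / (gr * (1 - target_fraction) + target_fraction)
}

#' Sweep the composition model over candidate doubling times
#'
#' Runs [simulate_composition()] once per doubling time, keeping the initial
#' fraction, survival and horizon fixed, and reports the initial and final
#' proliferative percentage for each — the desk estimate of how fast a
#' contaminating population must divide to dominate the culture.
#'
#' @param division_times Vector of positive doubling times in hours.
#' @param f0 Initial proliferative fraction in (0, 1). Default 0.01.
#' @param survival Daily survival fraction. Default 0.99.
#' @param n_days Number of days. Default 26.
#' @param growth Growth model, as in [population_model_params()].
#' @return Data frame with columns `division_time_h`, `initial_pct`,
#'   `final_pct`, one row per doubling time.
#' @export
#' @examples
#' sweep_doubling_times(c(24, 48, 72))
sweep_doubling_times <- function(division_times, f0 = 0.01, survival = 0.99,
                                 n_days = 26,
                                 growth = c("linear", "exponential")) {
  growth <- match.arg(growth)
  stopifnot(
    "division_times must be a non-empty positive vector" =
      length(division_times) > 0 && all(division_times > 0),
    "f0 must be in (0, 1)" = f0 > 0 && f0 < 1
  )
  final_pct <- vapply(division_times, function(dt) {
    p <- population_model_params(
      survival = survival, division_time = dt,
      adipocyte_0 = 1 - f0, other_0 = f0, n_days = n_days, growth = growth
    )
    tr <- simulate_composition(p)
    tr$other_fraction_pct[nrow(tr)]
  }, numeric(1))
  data.frame(
    division_time_h = division_times,
    initial_pct = 100 * f0,
    final_pct = final_pct
  )
}
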