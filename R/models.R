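#' Two-stage (MVK) carcinogenesis onset model
#'
#' Parameterises the age-at-onset distribution of breast cancer with the
#' Moolgavkar--Venzon--Knudson two-stage clonal expansion model, reduced to
#' the three derived parameters `A`, `B` and `delta` (see
#' [mvk_params_from_rates()] for the mapping from the four Poisson event
#' rates).  Onset is operationalised as the tumor reaching a diameter of
#' 0.5 mm.  Ages at onset are sampled on a discrete grid of candidate ages,
#' with the residual probability mass assigned to a "no onset in lifetime"
#' category, and the sampled ages adjusted downwards for the Ghanaian
#' incidence level, which is roughly 0.48 times the Northern European level
#' the `A`, `B`, `delta` estimates were derived from.
#'
#' @param A Negative MVK parameter (dimensionless). Default -0.0722.
#' @param B Positive MVK parameter (dimensionless). Default 1.18e-3.
#' @param delta Positive MVK parameter, the ratio of first-mutation to
#'   division rates. Default 0.0952.
#' @param age_grid Strictly increasing integer candidate onset ages in
#'   years. Default `38:92`.
#' @param age_scale Incidence adjustment factor in (0, 1]; how it is applied
#'   depends on `adjustment`. Default 0.48 (= 41.5/86.4, the ratio of
#'   West-African to Northern-European age-standardised incidence).
#' @param adjustment Either `"age-scale"` (default; sampled onset ages are
#'   multiplied by `age_scale`, shifting onset earlier) or `"thin"` (the
#'   onset probabilities are multiplied by `age_scale`, leaving ages
#'   unchanged).
#' @param no_onset_allowed If `TRUE` (default) the residual mass
#'   `1 - sum(f_T(age_grid))` is an explicit "never develops a tumor"
#'   category.
#'
#' @return An object of class `onset_model`.
#' @seealso [onset_density()], [sample_onset()]
#' @export
#' @examples
#' m <- onset_model()
#' onset_survival(50, m)
onset_model <- function(A = -0.0722, B = 1.18e-3, delta = 0.0952,
                        age_grid = 38:92, age_scale = 0.48,
                        adjustment = c("age-scale", "thin"),
                        no_onset_allowed = TRUE) {
  adjustment <- match.arg(adjustment)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A < 0)
  stopifnot(is.numeric(B), length(B) == 1L, is.finite(B), B > 0)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta), delta > 0)
  stopifnot(is.numeric(age_grid), length(age_grid) >= 1L,
            all(diff(age_grid) > 0), all(age_grid >= 0))
  stopifnot(is.numeric(age_scale), length(age_scale) == 1L,
            age_scale > 0, age_scale <= 1)
  structure(
    list(A = A, B = B, delta = delta, age_grid = as.numeric(age_grid),
         age_scale = age_scale, adjustment = adjustment,
         no_onset_allowed = isTRUE(no_onset_allowed)),
    class = "onset_model")
}

#' Gamma model for the inverse tumor growth rate
#'
#' The inverse growth rate `r` (years; the time constant of exponential
#' volume growth, so the volume doubling time is `ln(2) * r`) varies between
#' tumors and follows a gamma distribution with shape `a` and rate `b`
#' (scale `1/b`).  The defaults are the maximum-likelihood estimates from
#' the Korle Bu clinical tumor-size series, fitted under the constraint
#' `a = b` so that the population mean inverse growth rate is 1.
#'
#' @param a Gamma shape (> 0). Default 0.8162.
#' @param b Gamma rate (> 0). Defaults to `a` when `constrain_equal`.
#' @param constrain_equal If `TRUE` (default) require `a == b`.
#'
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(a = 0.8162, b = if (constrain_equal) a else 0.8162,
                         constrain_equal = TRUE) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  if (constrain_equal && !isTRUE(all.equal(a, b)))
    stop("growth_model: 'constrain_equal' requires a == b")
  structure(list(a = a, b = b, constrain_equal = isTRUE(constrain_equal)),
            class = "growth_model")
}

#' Symptomatic-detection model
#'
#' Symptoms are noticed at a hazard proportional to current tumor volume:
#' the rate at time `x` is `eta * V(x)`.  `eta` is the symptomatic-detection
#' hazard per unit tumor volume; `d0` is the tumor diameter at onset (the
#' size at which the tumor is considered formed) and `v0` the corresponding
#' spherical volume.
#'
#' @param eta Hazard per mm^3 per year (> 0). Default `exp(-9.644)`
#'   (~6.48e-5), the clinical-series estimate.
#' @param d0 Onset diameter in mm (> 0). Default 0.5 mm, giving
#'   `v0 = pi * d0^3 / 6` of about 0.065 mm^3.
#'
#' @return An object of class `detection_model` with fields `eta`, `d0`,
#'   `v0`.
#' @export
detection_model <- function(eta = exp(-9.644), d0 = 0.5) {
  stopifnot(is.numeric(eta), length(eta) == 1L, is.finite(eta), eta > 0)
  stopifnot(is.numeric(d0), length(d0) == 1L, is.finite(d0), d0 > 0)
  structure(list(eta = eta, d0 = d0, v0 = pi * d0^3 / 6),
            class = "detection_model")
}

#' Cohort specification for the simulated population
#'
#' The disease population is simulated as `births_per_cohort` births in each
#' of `n_cohorts` yearly birth cohorts (default 5,000 x 35 = 175,000
#' individuals).  Cohort calendar years are labels only; follow-up is
#' age-based and ends at `max_follow_up_age`.
#'
#' @param births_per_cohort Births per cohort (default 5000).
#' @param n_cohorts Number of yearly cohorts (default 35).
#' @param first_cohort_year Calendar year label of the first cohort
#'   (default 1985).
#' @param max_follow_up_age Age (years) at which follow-up ends; tumors
#'   becoming symptomatic later are never diagnosed. Default 100.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(births_per_cohort = 5000, n_cohorts = 35,
                        first_cohort_year = 1985, max_follow_up_age = 100) {
  stopifnot(births_per_cohort >= 1, n_cohorts >= 1, max_follow_up_age > 0)
  structure(list(births_per_cohort = as.integer(births_per_cohort),
                 n_cohorts = as.integer(n_cohorts),
                 first_cohort_year = as.integer(first_cohort_year),
                 max_follow_up_age = max_follow_up_age),
            class = "cohort_spec")
}

#' Screening policy (age range and interval)
#'
#' @param start_age First scheduled screening age in years.
#' @param end_age Upper age limit of the program; screens are scheduled at
#'   `start_age, start_age + interval, ...` up to `end_age`.
#' @param interval Years between screens (1, 2 or 3 in the evaluated
#'   strategies; any positive value is accepted).
#'
#' @return An object of class `screening_policy`.
#' @export
screening_policy <- function(start_age, end_age, interval) {
  stopifnot(is.numeric(start_age), is.numeric(end_age), is.numeric(interval),
            start_age < end_age, interval > 0)
  structure(list(start_age = start_age, end_age = end_age,
                 interval = interval),
            class = "screening_policy")
}

.sensitivity_scenarios <- list(
  low      = c(beta0 = -5.45, beta1 = 0.48),
  moderate = c(beta0 = -5.04, beta1 = 0.56),
  high     = c(beta0 = -4.67, beta1 = 0.65)
)

#' Mammography sensitivity parameters
#'
#' The probability that an attended screen detects an existing tumor of
#' diameter `d` mm is logistic: `plogis(beta0 + beta1 * d)`.  Three
#' literature scenarios are built in (low, moderate, high); explicit
#' `beta0`/`beta1` override the scenario, and `perturb` applies a
#' proportional change to both coefficients for sensitivity analyses
#' (e.g. `perturb = 0.1` for +10%).
#'
#' @param scenario One of `"low"`, `"moderate"`, `"high"`.
#' @param beta0,beta1 Optional explicit logit intercept (dimensionless) and
#'   slope (per mm, > 0).
#' @param perturb Proportional perturbation applied to both coefficients
#'   (default 0).
#'
#' @return An object of class `sensitivity_params`.
#' @export
#' @examples
#' s <- sensitivity_params("moderate")
#' screen_sensitivity(9, s)   # 0.5: the moderate half-detection size is 9 mm
sensitivity_params <- function(scenario = c("moderate", "low", "high"),
                               beta0 = NULL, beta1 = NULL, perturb = 0) {
  scenario <- match.arg(scenario)
  ref <- .sensitivity_scenarios[[scenario]]
  b0 <- if (is.null(beta0)) unname(ref["beta0"]) else beta0
  b1 <- if (is.null(beta1)) unname(ref["beta1"]) else beta1
  b0 <- b0 * (1 + perturb)
  b1 <- b1 * (1 + perturb)
  stopifnot(is.finite(b0), is.finite(b1), b1 > 0)
  structure(list(beta0 = b0, beta1 = b1, scenario_label = scenario),
            class = "sensitivity_params")
}

#' Screening attendance model
#'
#' Attendance is a two-type mixture: a fraction of the population are
#' regular attenders who show up at each scheduled screen with a high
#' probability, the rest are irregular attenders with a low per-screen
#' probability.  `"perfect"` makes everyone attend every screen; `"none"`
#' disables attendance altogether (useful as the no-screening arm).
#'
#' @param mode `"imperfect"` (default), `"perfect"` or `"none"`.
#' @param regular_fraction Fraction of regular attenders (default 0.80).
#' @param p_regular Per-screen attendance probability of regular attenders
#'   (default 0.90).
#' @param p_irregular Per-screen attendance probability of irregular
#'   attenders (default 0.15).
#'
#' @return An object of class `attendance_model`.
#' @export
attendance_model <- function(mode = c("imperfect", "perfect", "none"),
                             regular_fraction = 0.80, p_regular = 0.90,
                             p_irregular = 0.15) {
  mode <- match.arg(mode)
  stopifnot(regular_fraction >= 0, regular_fraction <= 1,
            p_regular >= 0, p_regular <= 1,
            p_irregular >= 0, p_irregular <= 1)
  structure(list(mode = mode, regular_fraction = regular_fraction,
                 p_regular = p_regular, p_irregular = p_irregular),
            class = "attendance_model")
}

#' @export
print.onset_model <- function(x, ...) {
  cat("MVK onset model: A =", x$A, ", B =", x$B, ", delta =", x$delta, "\n")
  cat("  age grid:", min(x$age_grid), "..", max(x$age_grid),
      "; adjustment:", x$adjustment, "(factor", x$age_scale, ")\n")
  invisible(x)
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Gamma inverse-growth-rate model: shape a =", x$a, ", rate b =", x$b,
      if (x$constrain_equal) "(constrained a = b)" else "", "\n")
  cat("  mean doubling time:", round(365 * log(2) * x$a / x$b, 1), "days\n")
  invisible(x)
}
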