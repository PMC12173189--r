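#' Onset survival function
#'
#' Probability that tumor onset has not occurred by age `t` under the
#' two-stage MVK model:
#' `G_T(t) = [ (B - A) e^{B t} / (B e^{(B - A) t} - A) ]^delta`.
#'
#' @param t Age(s) in years, >= 0.
#' @param m An [onset_model()].
#' @return Survival probabilities in (0, 1].
#' @export
onset_survival <- function(t, m) {
  stopifnot(inherits(m, "onset_model"))
  if (any(!is.finite(t)) || any(t < 0)) stop("onset_survival: t must be finite and >= 0")
  A <- m$A; B <- m$B; d <- m$delta
  ((B - A) * exp(B * t) / (B * exp((B - A) * t) - A))^d
}

#' Onset hazard function
#'
#' Age-specific onset hazard
#' `h_T(t) = delta A B (1 - e^{(B - A) t}) / (B e^{(B - A) t} - A)`,
#' nonnegative for `A < 0`, `B > 0`.
#'
#' @inheritParams onset_survival
#' @return Hazard rates per year.
#' @export
onset_hazard <- function(t, m) {
  stopifnot(inherits(m, "onset_model"))
  if (any(!is.finite(t)) || any(t < 0)) stop("onset_hazard: t must be finite and >= 0")
  A <- m$A; B <- m$B; d <- m$delta
  d * A * B * (1 - exp((B - A) * t)) / (B * exp((B - A) * t) - A)
}

#' Onset probability density
#'
#' Density of the age at tumor onset, `f_T(t) = -dG_T(t)/dt`:
#' `f_T(t) = delta A B (B - A)^delta e^{delta B t} (1 - e^{(B - A) t}) /
#'           (B e^{(B - A) t} - A)^{delta + 1}`.
#' Identically `f_T = h_T * G_T`.
#'
#' @inheritParams onset_survival
#' @return Densities per year.
#' @export
onset_density <- function(t, m) {
  stopifnot(inherits(m, "onset_model"))
  if (any(!is.finite(t)) || any(t < 0)) stop("onset_density: t must be finite and >= 0")
  A <- m$A; B <- m$B; d <- m$delta
  d * A * B * (B - A)^d * exp(d * B * t) * (1 - exp((B - A) * t)) /
    (B * exp((B - A) * t) - A)^(d + 1)
}

#' Map the four MVK event rates to (A, B, delta)
#'
#' The two-stage model's Poisson event rates -- cell division `alpha`,
#' first mutation `nu`, cell death `beta`, second mutation `mu` -- determine
#' the reduced parameters: `delta = nu / alpha`, and `A`, `B` are the two
#' roots of `z^2 - (beta + mu - alpha) z - alpha mu = 0`, assigned so that
#' `A < 0 <= B` (so `A + B = beta + mu - alpha` and `A * B = -alpha * mu`).
#'
#' @param alpha Cell division rate (> 0).
#' @param nu First mutation rate (>= 0).
#' @param beta Cell death rate (>= 0).
#' @param mu Second mutation rate (>= 0).
#' @return A named list with `A`, `B`, `delta`.
#' @export
mvk_params_from_rates <- function(alpha, nu, beta, mu) {
  stopifnot(alpha > 0, nu >= 0, beta >= 0, mu >= 0)
  s <- beta + mu - alpha
  disc <- s^2 + 4 * alpha * mu
  if (disc < 0) stop("mvk_params_from_rates: negative discriminant")
  root_hi <- (s + sqrt(disc)) / 2
  root_lo <- (s - sqrt(disc)) / 2
  list(A = root_lo, B = root_hi, delta = nu / alpha)
}

#' Onset-age grid weights
#'
#' Probability weights used for discrete onset-age sampling: the density
#' `f_T` evaluated at each grid age (thinned by `age_scale` under the
#' `"thin"` adjustment), plus the residual no-onset mass.
#'
#' @param m An [onset_model()].
#' @return A list with `ages`, `weights` (same length) and `p_no_onset`.
#' @export
onset_grid_weights <- function(m) {
  stopifnot(inherits(m, "onset_model"))
  w <- onset_density(m$age_grid, m)
  if (m$adjustment == "thin") w <- w * m$age_scale
  total <- sum(w)
  if (total > 1) stop("onset_grid_weights: grid onset probabilities sum to more than 1")
  if (!m$no_onset_allowed && total < 1) w <- w / total
  list(ages = m$age_grid, weights = w, p_no_onset = max(0, 1 - sum(w)))
}

#' Sample ages at tumor onset
#'
#' For each of `n` individuals, draws either "no onset" (with the residual
#' probability) or a grid age with probability proportional to the onset
#' density at that age.  A drawn integer age is jittered uniformly within
#' the year, and -- under the default `"age-scale"` adjustment -- multiplied
#' by `age_scale` to account for the lower Ghanaian incidence.  At most one
#' tumor per individual.
#'
#' @param n Number of individuals.
#' @param m An [onset_model()].
#' @return Numeric vector of length `n`: onset age in years, or `NA` for
#'   individuals who never develop a tumor.
#' @export
#' @examples
#' set.seed(1)
#' ages <- sample_onset(1e4, onset_model())
#' mean(!is.na(ages))   # lifetime onset fraction, about 0.20
sample_onset <- function(n, m) {
  stopifnot(inherits(m, "onset_model"), n >= 1)
  gw <- onset_grid_weights(m)
  idx <- sample.int(length(gw$ages) + 1L, n, replace = TRUE,
                    prob = c(gw$p_no_onset, gw$weights))
  has <- idx > 1L
  out <- rep(NA_real_, n)
  k <- sum(has)
  if (k > 0) {
    ages <- gw$ages[idx[has] - 1L] + stats::runif(k)
    if (m$adjustment == "age-scale") ages <- ages * m$age_scale
    out[has] <- ages
  }
  out
}
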