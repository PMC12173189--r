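#' Sample inverse growth rates
#'
#' Draws tumor-specific inverse growth rates `r` from the gamma law
#' `f_R(r) = b^a / Gamma(a) * r^{a-1} e^{-b r}` (shape `a`, rate `b`).
#'
#' @param n Number of draws.
#' @param g A [growth_model()].
#' @return Positive numeric vector of length `n` (years).
#' @export
sample_inverse_growth_rate <- function(n, g) {
  stopifnot(inherits(g, "growth_model"), n >= 1)
  stats::rgamma(n, shape = g$a, rate = g$b)
}

#' Tumor volume at a given age
#'
#' Exponential growth from the onset volume:
#' `V(x) = v0 * exp((x - t) / r)` for `x >= t`.
#'
#' @param x Age in years (>= `t`).
#' @param t Age at onset in years.
#' @param r Inverse growth rate in years (> 0).
#' @param v0 Volume at onset in mm^3.
#' @return Volume in mm^3.
#' @export
tumor_volume_at_age <- function(x, t, r, v0 = detection_model()$v0) {
  if (any(x < t)) stop("tumor_volume_at_age: age x must be >= onset age t")
  stopifnot(all(r > 0))
  v0 * exp((x - t) / r)
}

#' Tumor diameter at a given age
#'
#' The spherical diameter of the growing tumor,
#' `d_{r,t}(x) = (6 v0 e^{(x - t)/r} / pi)^{1/3}`.
#'
#' @inheritParams tumor_volume_at_age
#' @return Diameter in mm.
#' @export
tumor_diameter_at_age <- function(x, t, r, v0 = detection_model()$v0) {
  diameter_from_volume(tumor_volume_at_age(x, t, r, v0))
}

#' Convert between spherical tumor volume and diameter
#'
#' Tumors are modelled as spheres: `d = (6 v / pi)^{1/3}` and
#' `v = pi d^3 / 6`.
#'
#' @param v Volume(s) in mm^3 (> 0).
#' @param d Diameter(s) in mm (> 0).
#' @return Diameter in mm, or volume in mm^3.
#' @export
#' @examples
#' volume_from_diameter(0.5)   # onset volume, about 0.065 mm^3
diameter_from_volume <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("diameter_from_volume: volume must be positive")
  (6 * v / pi)^(1 / 3)
}

#' @rdname diameter_from_volume
#' @export
volume_from_diameter <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("volume_from_diameter: diameter must be positive")
  pi * d^3 / 6
}

#' Sample the tumor volume at symptomatic detection
#'
#' Inverse-CDF sampling of the volume at which symptoms surface, given the
#' inverse growth rate `r`: `V(U) = v0 - log(1 - u) / (eta * r)`, so that
#' `V - v0` is exponential with rate `eta * r` (the symptomatic hazard is
#' proportional to current volume).
#'
#' @param r Inverse growth rate(s) in years (> 0).
#' @param dm A [detection_model()].
#' @param u Uniform variate(s) in `[0, 1)`.
#' @return Volume(s) in mm^3, `> v0`.
#' @export
sample_symptomatic_volume <- function(r, dm = detection_model(), u) {
  stopifnot(inherits(dm, "detection_model"), all(r > 0))
  if (any(u < 0) || any(u >= 1)) stop("sample_symptomatic_volume: u must lie in [0, 1)")
  dm$v0 - log(1 - u) / (dm$eta * r)
}

#' Time from onset to symptomatic detection
#'
#' Inverts the growth curve at the symptomatic volume:
#' `U' = r * log(V / v0)`; the age at symptomatic detection is the onset
#' age plus `U'`.
#'
#' @param V Symptomatic volume(s) in mm^3 (>= `v0`).
#' @param r Inverse growth rate(s) in years.
#' @param v0 Volume at onset in mm^3.
#' @return Duration(s) in years.
#' @export
time_to_symptomatic <- function(V, r, v0 = detection_model()$v0) {
  if (any(V < v0)) stop("time_to_symptomatic: V must be >= v0")
  stopifnot(all(r > 0))
  r * log(V / v0)
}
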