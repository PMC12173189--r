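#' Simulate the no-screening natural history of a population
#'
#' Simulates `births_per_cohort * n_cohorts` independent individuals.  For
#' each: (i) an onset age is sampled from the MVK grid distribution (most
#' individuals never develop a tumor); (ii) onset cases receive a
#' gamma-distributed inverse growth rate; (iii) a symptomatic volume is
#' drawn from the volume-proportional hazard via a fresh uniform variate,
#' truncated so the symptomatic diameter does not exceed `max_diameter`
#' (inverse-CDF truncation, equivalent in distribution to redrawing the
#' uniform until the cap is respected); (iv) the symptomatic diameter and
#' age follow from the growth curve.  Each stochastic sub-process uses its
#' own named RNG stream derived from `seed`, so screening overlays on the
#' same histories share identical natural histories across policies.
#'
#' @param cohorts A [cohort_spec()].
#' @param onset An [onset_model()].
#' @param growth A [growth_model()].
#' @param detection A [detection_model()].
#' @param seed Master seed (mandatory).
#' @param max_diameter Cap on the symptomatic diameter in mm (default 120).
#'
#' @return A data.frame of class `tumor_histories` with one row per
#'   individual: `individual_id`, `cohort_year`, `onset_age`,
#'   `inv_growth_rate`, `symptomatic_volume`, `symptomatic_diameter`,
#'   `symptomatic_age` (all `NA` past `cohort_year` for individuals without
#'   onset).  Models, seed and cap are kept as attributes.
#' @export
#' @examples
#' h <- simulate_natural_history(cohort_spec(100, 2), seed = 1)
#' table(is.na(h$onset_age))
simulate_natural_history <- function(cohorts = cohort_spec(),
                                     onset = onset_model(),
                                     growth = growth_model(),
                                     detection = detection_model(),
                                     seed,
                                     max_diameter = 120) {
  stopifnot(inherits(cohorts, "cohort_spec"), inherits(onset, "onset_model"),
            inherits(growth, "growth_model"),
            inherits(detection, "detection_model"))
  if (missing(seed)) stop("simulate_natural_history: a master seed is required")
  n <- cohorts$births_per_cohort * cohorts$n_cohorts

  onset_age <- with_stream(seed, "onset", sample_onset(n, onset))
  has <- !is.na(onset_age)
  m <- sum(has)

  r <- V <- rep(NA_real_, n)
  if (m > 0) {
    r[has] <- with_stream(seed, "growth", sample_inverse_growth_rate(m, growth))
    u <- with_stream(seed, "symptomatic", stats::runif(m))
    vmax <- volume_from_diameter(max_diameter)
    # truncated inverse CDF: scale u by the CDF mass below the cap
    p_cap <- 1 - exp(-detection$eta * r[has] * (vmax - detection$v0))
    V[has] <- sample_symptomatic_volume(r[has], detection, u * p_cap)
  }

  d_sym <- age_sym <- rep(NA_real_, n)
  d_sym[has] <- diameter_from_volume(V[has])
  age_sym[has] <- onset_age[has] +
    time_to_symptomatic(V[has], r[has], detection$v0)

  out <- data.frame(
    individual_id = seq_len(n),
    cohort_year = cohorts$first_cohort_year +
      (seq_len(n) - 1L) %/% cohorts$births_per_cohort,
    onset_age = onset_age,
    inv_growth_rate = r,
    symptomatic_volume = V,
    symptomatic_diameter = d_sym,
    symptomatic_age = age_sym)
  structure(out,
            class = c("tumor_histories", "data.frame"),
            models = list(cohorts = cohorts, onset = onset, growth = growth,
                          detection = detection),
            seed = seed, max_diameter = max_diameter)
}

#' Export simulated histories to CSV
#'
#' Writes the flat per-individual table (empty fields for individuals
#' without onset).
#'
#' @param histories A `tumor_histories` data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_histories <- function(histories, path) {
  stopifnot(inherits(histories, "tumor_histories"))
  df <- histories[, c("individual_id", "cohort_year", "onset_age",
                      "inv_growth_rate", "symptomatic_age",
                      "symptomatic_diameter")]
  names(df)[names(df) == "symptomatic_diameter"] <- "symptomatic_diameter_mm"
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
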