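#' Scheduled screening ages of a policy
#'
#' Screens run from `start_age` in steps of `interval` up to the largest
#' age not exceeding `end_age`.
#'
#' @param p A [screening_policy()].
#' @return Numeric vector of screen ages (nonempty).
#' @export
#' @examples
#' screening_schedule(screening_policy(50, 69, 2))  # 50, 52, ..., 68
screening_schedule <- function(p) {
  stopifnot(inherits(p, "screening_policy"))
  seq(p$start_age, p$end_age, by = p$interval)
}

#' Screening sensitivity for a tumor of a given diameter
#'
#' Logistic probability that an attended mammogram detects an existing
#' tumor of diameter `d` mm: `exp(b0 + b1 d) / (1 + exp(b0 + b1 d))`,
#' evaluated in numerically stable form.
#'
#' @param d Tumor diameter(s) in mm (>= 0).
#' @param s A [sensitivity_params()].
#' @return Detection probabilities.
#' @export
screen_sensitivity <- function(d, s) {
  stopifnot(inherits(s, "sensitivity_params"))
  if (any(d < 0)) stop("screen_sensitivity: diameter must be >= 0")
  stats::plogis(s$beta0 + s$beta1 * d)
}

#' Per-individual, per-screen attendance indicators
#'
#' Under `"perfect"` attendance everyone attends every screen; under
#' `"imperfect"` each individual is permanently typed regular (probability
#' `regular_fraction`) or irregular, and then attends each screen
#' independently with the type's probability; `"none"` disables attendance.
#'
#' @param n Number of individuals.
#' @param am An [attendance_model()].
#' @param schedule Vector of screen ages (only its length matters here).
#' @param seed Seed for the attendance stream.
#' @return Logical matrix, `n` rows by `length(schedule)` columns.
#' @export
assign_attendance <- function(n, am, schedule, seed) {
  stopifnot(inherits(am, "attendance_model"), n >= 1)
  k <- length(schedule)
  if (am$mode == "perfect") return(matrix(TRUE, n, k))
  if (am$mode == "none") return(matrix(FALSE, n, k))
  with_stream(seed, "attendance", {
    p <- ifelse(stats::runif(n) < am$regular_fraction,
                am$p_regular, am$p_irregular)
    matrix(stats::runif(n * k) < rep(p, k), n, k)
  })
}

#' Overlay a screening policy on simulated natural histories
#'
#' Walks each individual's scheduled screens in order.  At every attended
#' screen age `x` with the tumor latent (`onset <= x <` symptomatic age;
#' at a tie the symptomatic detection wins), the tumor's current diameter
#' is computed from the growth curve and detection is a Bernoulli draw with
#' the logistic size-dependent sensitivity; the first success makes the
#' case screen-detected at that age and size.  A symptomatic case that
#' follows at least one attended negative screen and surfaces before the
#' next scheduled screen (or before the end of the program, after the last
#' screen) is an interval cancer.  Remaining symptomatic cases within
#' follow-up are `other_symptomatic`; individuals without onset, or whose
#' symptomatic age exceeds the follow-up limit and who were never
#' screen-detected, are `none`.
#'
#' Attendance and sensitivity use their own named RNG streams derived from
#' `seed`, and sensitivity draws are independent across screens; natural
#' histories are untouched, so different policies overlaid on the same
#' histories share the identical disease population (common random
#' numbers).
#'
#' @param histories A `tumor_histories` data.frame from
#'   [simulate_natural_history()].
#' @param p A [screening_policy()].
#' @param s A [sensitivity_params()].
#' @param am An [attendance_model()].
#' @param seed Seed for the screening streams; defaults to the master seed
#'   stored in `histories`.
#' @return A data.frame of class `detection_outcomes` with one row per
#'   individual: `individual_id`, `mode` (factor: `screen_detected`,
#'   `interval`, `other_symptomatic`, `none`), `detection_age`,
#'   `detection_diameter`, `n_attended_negative_screens`, plus the natural
#'   history columns `onset_age`, `inv_growth_rate`, `symptomatic_age`
#'   carried along for evaluation.
#' @export
apply_screening <- function(histories, p, s, am,
                            seed = attr(histories, "seed")) {
  stopifnot(inherits(histories, "tumor_histories"),
            inherits(p, "screening_policy"),
            inherits(s, "sensitivity_params"),
            inherits(am, "attendance_model"))
  if (is.null(seed)) stop("apply_screening: no seed available")
  models <- attr(histories, "models")
  follow_up <- models$cohorts$max_follow_up_age
  v0 <- models$detection$v0
  schedule <- screening_schedule(p)

  n <- nrow(histories)
  has <- !is.na(histories$onset_age)
  m <- sum(has)
  t_on <- histories$onset_age[has]
  r <- histories$inv_growth_rate[has]
  sage <- histories$symptomatic_age[has]

  det_age <- rep(NA_real_, m)
  det_d <- rep(NA_real_, m)
  n_neg <- integer(m)
  last_neg <- rep(-Inf, m)
  detected <- rep(FALSE, m)

  if (am$mode != "none" && m > 0) {
    type_p <- if (am$mode == "perfect") rep(1, m) else
      with_stream(seed, "attendance-type",
                  ifelse(stats::runif(m) < am$regular_fraction,
                         am$p_regular, am$p_irregular))
    for (j in seq_along(schedule)) {
      x <- schedule[j]
      u_att <- if (am$mode == "perfect") numeric(m) else
        with_stream(seed, paste0("attendance#", j), stats::runif(m))
      u_sens <- with_stream(seed, paste0("sensitivity#", j), stats::runif(m))
      att <- !detected & t_on <= x & x < sage & u_att < type_p
      if (!any(att)) next
      dx <- tumor_diameter_at_age(x, t_on[att], r[att], v0)
      hit <- u_sens[att] < screen_sensitivity(dx, s)
      idx <- which(att)
      hit_idx <- idx[hit]
      detected[hit_idx] <- TRUE
      det_age[hit_idx] <- x
      det_d[hit_idx] <- dx[hit]
      neg_idx <- idx[!hit]
      n_neg[neg_idx] <- n_neg[neg_idx] + 1L
      last_neg[neg_idx] <- x
    }
  }

  sympt <- !detected & sage <= follow_up
  next_sched <- last_neg + p$interval
  bound <- ifelse(next_sched > max(schedule), p$end_age, next_sched)
  is_int <- sympt & is.finite(last_neg) & sage <= bound

  mode_t <- rep("none", m)
  mode_t[sympt] <- "other_symptomatic"
  mode_t[is_int] <- "interval"
  mode_t[detected] <- "screen_detected"
  det_age[sympt] <- sage[sympt]
  det_d[sympt] <- histories$symptomatic_diameter[has][sympt]

  mode <- rep("none", n)
  mode[has] <- mode_t
  out <- data.frame(
    individual_id = histories$individual_id,
    mode = factor(mode, levels = c("screen_detected", "interval",
                                   "other_symptomatic", "none")),
    detection_age = NA_real_,
    detection_diameter = NA_real_,
    n_attended_negative_screens = 0L,
    onset_age = histories$onset_age,
    inv_growth_rate = histories$inv_growth_rate,
    symptomatic_age = histories$symptomatic_age)
  out$detection_age[has] <- det_age
  out$detection_diameter[has] <- det_d
  out$n_attended_negative_screens[has] <- n_neg
  structure(out,
            class = c("detection_outcomes", "data.frame"),
            policy = p, sensitivity = s, attendance = am,
            seed = seed, follow_up = follow_up,
            n_individuals = n)
}

#' Export detection outcomes to CSV
#'
#' @param outcomes A `detection_outcomes` data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "detection_outcomes"))
  df <- outcomes[, c("individual_id", "mode", "detection_age",
                     "detection_diameter", "n_attended_negative_screens")]
  names(df)[names(df) == "detection_diameter"] <- "detection_diameter_mm"
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
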