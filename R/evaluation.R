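#' Overdiagnosis percentage
#'
#' `Q = 100 * (N_scr - N_abs) / N_scr`: the excess of diagnoses in the
#' screened arm over the unscreened arm, as a share of screened-arm
#' diagnoses.
#'
#' @param n_scr Diagnosed count in the screened arm (> 0).
#' @param n_abs Diagnosed count in the absence of screening.
#' @return Percentage.
#' @export
#' @examples
#' overdiagnosis_pct(22099, 20867)  # 5.57
overdiagnosis_pct <- function(n_scr, n_abs) {
  if (any(n_scr <= 0)) stop("overdiagnosis_pct: n_scr must be positive")
  100 * (n_scr - n_abs) / n_scr
}

#' Percent change in diagnosed counts
#'
#' `100 * (N_scr - N_abs) / N_abs`, the screened-arm excess relative to the
#' unscreened count.
#'
#' @inheritParams overdiagnosis_pct
#' @return Percentage.
#' @export
percent_change <- function(n_scr, n_abs) {
  if (any(n_abs <= 0)) stop("percent_change: n_abs must be positive")
  100 * (n_scr - n_abs) / n_abs
}

#' Strategy-comparison metrics for a screening policy
#'
#' Counts diagnoses whose detection age falls inside the policy's age
#' window `[start_age, end_age]` in each arm, and derives the percent
#' change, overdiagnosis percentage, and the screen-detected and
#' interval-cancer shares of screened-arm diagnoses.
#'
#' @param no_screen_outcomes `detection_outcomes` of the unscreened arm
#'   (e.g. from [apply_screening()] with `attendance_model("none")`).
#' @param screen_outcomes `detection_outcomes` of the screened arm.
#' @param p The [screening_policy()] under evaluation.
#' @return An object of class `strategy_metrics`: a one-row data.frame with
#'   `n_no_screening`, `n_screening`, `pct_change`, `pct_overdiagnosis`,
#'   `pct_screen_detected`, `pct_interval`.
#' @export
strategy_metrics <- function(no_screen_outcomes, screen_outcomes, p) {
  stopifnot(inherits(no_screen_outcomes, "detection_outcomes"),
            inherits(screen_outcomes, "detection_outcomes"),
            inherits(p, "screening_policy"))
  if (!identical(attr(no_screen_outcomes, "n_individuals"),
                 attr(screen_outcomes, "n_individuals")))
    stop("strategy_metrics: outcome sets derive from different populations")
  in_win <- function(o) !is.na(o$detection_age) & o$mode != "none" &
    o$detection_age >= p$start_age & o$detection_age <= p$end_age
  w_abs <- in_win(no_screen_outcomes)
  w_scr <- in_win(screen_outcomes)
  n_abs <- sum(w_abs)
  n_scr <- sum(w_scr)
  out <- data.frame(
    n_no_screening = n_abs,
    n_screening = n_scr,
    pct_change = percent_change(n_scr, n_abs),
    pct_overdiagnosis = overdiagnosis_pct(n_scr, n_abs),
    pct_screen_detected =
      100 * sum(w_scr & screen_outcomes$mode == "screen_detected") / n_scr,
    pct_interval =
      100 * sum(w_scr & screen_outcomes$mode == "interval") / n_scr)
  class(out) <- c("strategy_metrics", "data.frame")
  out
}

#' Tumor-size distribution in clinical reporting bins
#'
#' Bins diameters into 0-9 mm, 10-19 mm, 20-50 mm and >50 mm (the 20-50
#' bin is closed at 50; >50 is strictly greater).
#'
#' @param diameters Tumor diameters in mm.
#' @return A data.frame with `bin`, `count`, `percent`.
#' @export
size_category_table <- function(diameters) {
  diameters <- diameters[!is.na(diameters)]
  if (length(diameters) == 0) stop("size_category_table: no diameters")
  if (any(diameters < 0)) stop("size_category_table: negative diameter")
  labels <- c("0-9 mm", "10-19 mm", "20-50 mm", ">50 mm")
  counts <- c(sum(diameters < 10),
              sum(diameters >= 10 & diameters < 20),
              sum(diameters >= 20 & diameters <= 50),
              sum(diameters > 50))
  data.frame(bin = labels, count = counts,
             percent = 100 * counts / length(diameters))
}

#' Tumor volume doubling time
#'
#' `365 * ln(2) * r` days for an inverse growth rate `r` in years.
#'
#' @param r Inverse growth rate(s) in years (> 0).
#' @return Doubling time(s) in days.
#' @export
doubling_time_days <- function(r) {
  if (any(r <= 0)) stop("doubling_time_days: r must be positive")
  365 * log(2) * r
}

#' Five-number summary used throughout the evaluation tables
#'
#' @param x Numeric sample.
#' @return A one-row data.frame: `mean`, `sd`, `q1`, `median`, `q3`, `n`.
#' @export
summary_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("summary_stats: empty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(mean = mean(x), sd = stats::sd(x),
             q1 = q[1], median = q[2], q3 = q[3], n = length(x))
}

#' Doubling-time summaries by detection mode
#'
#' Converts each diagnosed case's inverse growth rate to a doubling time
#' and summarises screen-detected and interval cancers separately (the
#' length-bias contrast: screen-detected tumors grow more slowly).
#'
#' @param outcomes A `detection_outcomes` data.frame.
#' @return A data.frame with one row per mode present, columns `mode` plus
#'   the [summary_stats()] columns (days).
#' @export
doubling_time_summary <- function(outcomes) {
  stopifnot(inherits(outcomes, "detection_outcomes"))
  modes <- c("screen_detected", "interval")
  rows <- lapply(modes, function(mo) {
    r <- outcomes$inv_growth_rate[outcomes$mode == mo]
    if (length(r) == 0) return(NULL)
    cbind(mode = mo, summary_stats(doubling_time_days(r)))
  })
  do.call(rbind, rows)
}

#' Tumor presence time of interval cancers
#'
#' Presence time is the duration from onset (0.5 mm) to symptomatic
#' detectability, `U' = symptomatic age - onset age`; the continuous-model
#' analogue of the sojourn time, summarised for interval cancers.
#'
#' @param outcomes A `detection_outcomes` data.frame.
#' @return A [summary_stats()] row (years).
#' @export
presence_time_summary <- function(outcomes) {
  stopifnot(inherits(outcomes, "detection_outcomes"))
  iv <- outcomes$mode == "interval"
  if (!any(iv)) stop("presence_time_summary: no interval cancers present")
  summary_stats(outcomes$symptomatic_age[iv] - outcomes$onset_age[iv])
}

#' Detection-age summary of diagnosed cases
#'
#' @param outcomes A `detection_outcomes` data.frame.
#' @param window Optional `c(lower, upper)` age window restricting the
#'   summarised detections (e.g. the policy's screening ages).
#' @return A [summary_stats()] row (years).
#' @export
age_summary <- function(outcomes, window = NULL) {
  stopifnot(inherits(outcomes, "detection_outcomes"))
  ages <- outcomes$detection_age[outcomes$mode != "none"]
  ages <- ages[!is.na(ages)]
  if (!is.null(window)) ages <- ages[ages >= window[1] & ages <= window[2]]
  summary_stats(ages)
}
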