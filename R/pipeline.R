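#' Read a run configuration file
#'
#' The configuration is a YAML file with blocks mirroring the model
#' constructors (`cohorts`, `onset`, `growth`, `detection`), a mandatory
#' top-level `seed`, an optional `max_diameter`, and a list of `scenarios`,
#' each with `start_age`, `end_age`, `interval`, `attendance`
#' (perfect/imperfect/none), `sensitivity` (low/moderate/high) and optional
#' `perturb` (e.g. 0.1 for a +10% sensitivity-parameter perturbation).
#' Omitted fields take the constructors' defaults.
#'
#' @param path Path to the YAML configuration.
#' @return An object of class `run_config`: a list with `seed`, model
#'   objects, `max_diameter` and a list of scenario descriptors.
#' @export
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "cgmscreen"))
#' cfg$scenarios[[1]]$policy
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("read_run_config: a master 'seed' is mandatory")
  build <- function(ctor, block) do.call(ctor, as.list(block))
  onset_block <- cfg$onset
  if (!is.null(onset_block$age_grid_min) || !is.null(onset_block$age_grid_max)) {
    onset_block$age_grid <- seq(onset_block$age_grid_min %||% 38,
                                onset_block$age_grid_max %||% 92)
    onset_block$age_grid_min <- onset_block$age_grid_max <- NULL
  }
  scenarios <- lapply(cfg$scenarios %||% list(), function(sc) {
    for (f in c("start_age", "end_age", "interval"))
      if (is.null(sc[[f]])) stop("read_run_config: scenario missing '", f, "'")
    list(policy = screening_policy(sc$start_age, sc$end_age, sc$interval),
         attendance = attendance_model(sc$attendance %||% "imperfect"),
         sensitivity = sensitivity_params(sc$sensitivity %||% "moderate",
                                          perturb = sc$perturb %||% 0),
         label = sc$name %||%
           sprintf("%d-%d/%dy/%s/%s", sc$start_age, sc$end_age, sc$interval,
                   sc$attendance %||% "imperfect",
                   sc$sensitivity %||% "moderate"))
  })
  structure(list(seed = cfg$seed,
                 cohorts = build(cohort_spec, cfg$cohorts),
                 onset = build(onset_model, onset_block),
                 growth = build(growth_model, cfg$growth),
                 detection = build(detection_model, cfg$detection),
                 max_diameter = cfg$max_diameter %||% 120,
                 scenarios = scenarios,
                 raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the growth/symptomatic-detection model to a tumor-size CSV
#'
#' Reads a `diameter_mm` CSV, fits the marginal-volume MLE and writes the
#' result as JSON and a summary-table CSV into `out_dir`.
#'
#' @param data_path CSV of tumor diameters (column `diameter_mm`).
#' @param out_dir Output directory (created if needed).
#' @param constrain_equal Impose `a = b` (default `TRUE`).
#' @param z_multiplier Interval multiplier (default 1.645; see
#'   [fit_mle()]).
#' @return The `cgm_fit`, invisibly.
#' @export
run_fit <- function(data_path, out_dir = ".", constrain_equal = TRUE,
                    z_multiplier = 1.645) {
  data <- read_tumor_sizes(data_path)
  fit <- fit_mle(data, constrain_equal = constrain_equal,
                 z_multiplier = z_multiplier)
  if (!isTRUE(fit$converged))
    stop("run_fit: maximum-likelihood fit did not converge")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fit_result(fit,
                   json_path = file.path(out_dir, "fit_result.json"),
                   csv_path = file.path(out_dir, "fit_table.csv"))
  message(sprintf("run_fit: n = %d, eta = %.4g, b = %.4g, logLik = %.2f",
                  fit$n, fit$estimate["eta"], fit$estimate["b"], fit$log_lik))
  invisible(fit)
}

#' Simulate and evaluate all configured screening scenarios
#'
#' Simulates the shared natural history once from the configuration's
#' master seed, overlays every scenario on the same population (common
#' random numbers), and writes: `strategy_metrics.csv` (one row per
#' scenario with counts, percent change, overdiagnosis, screen-detected
#' and interval shares), `descriptive_summary.csv` (per-arm detection-age
#' statistics and size-bin distribution for the first scenario), and
#' `natural_history_summary.csv` (onset-age statistics, doubling times by
#' detection mode and interval-cancer presence times for the first
#' scenario).  All artifacts carry the master seed and a configuration
#' hash in header comments.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @param out_dir Output directory.
#' @return A list with `metrics` (data.frame) and `histories`, invisibly.
#' @export
run_compare <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (length(config$scenarios) == 0)
    stop("run_compare: the configuration defines no scenarios")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config$raw)

  h <- simulate_natural_history(config$cohorts, config$onset, config$growth,
                                config$detection, seed = config$seed,
                                max_diameter = config$max_diameter)

  rows <- list()
  first <- NULL
  for (sc in config$scenarios) {
    none <- apply_screening(h, sc$policy, sc$sensitivity,
                            attendance_model("none"))
    scr <- apply_screening(h, sc$policy, sc$sensitivity, sc$attendance)
    met <- strategy_metrics(none, scr, sc$policy)
    rows[[sc$label]] <- cbind(
      data.frame(scenario = sc$label, start_age = sc$policy$start_age,
                 end_age = sc$policy$end_age, interval = sc$policy$interval,
                 attendance = sc$attendance$mode,
                 sensitivity = sc$sensitivity$scenario_label), met)
    if (is.null(first)) first <- list(sc = sc, none = none, scr = scr)
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_csv_with_header(metrics, file.path(out_dir, "strategy_metrics.csv"),
                        seed = config$seed, hash = hash)

  win <- c(first$sc$policy$start_age, first$sc$policy$end_age)
  in_win <- function(o) !is.na(o$detection_age) & o$mode != "none" &
    o$detection_age >= win[1] & o$detection_age <= win[2]
  desc <- rbind(
    cbind(arm = "no_screening", age_summary(first$none, win)),
    cbind(arm = "screening", age_summary(first$scr, win)))
  sizes <- rbind(
    cbind(arm = "no_screening",
          size_category_table(first$none$detection_diameter[in_win(first$none)])),
    cbind(arm = "screening",
          size_category_table(first$scr$detection_diameter[in_win(first$scr)])))
  write_csv_with_header(merge(desc, sizes, by = "arm"),
                        file.path(out_dir, "descriptive_summary.csv"),
                        seed = config$seed, hash = hash)

  nh <- rbind(
    cbind(quantity = "onset_age_years",
          summary_stats(h$onset_age)),
    cbind(quantity = "presence_time_interval_years",
          presence_time_summary(first$scr)),
    local({
      dt <- doubling_time_summary(first$scr)
      cbind(quantity = paste0("doubling_time_days_", dt$mode),
            dt[, setdiff(names(dt), "mode")])
    }))
  write_csv_with_header(nh, file.path(out_dir, "natural_history_summary.csv"),
                        seed = config$seed, hash = hash)

  message(sprintf("run_compare: %d scenario(s) evaluated on %d individuals",
                  length(config$scenarios), nrow(h)))
  invisible(list(metrics = metrics, histories = h))
}
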