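# Shared fixtures: study-condition models and a small simulated population.

default_onset <- onset_model()
default_growth <- growth_model()
default_detection <- detection_model()
moderate <- sensitivity_params("moderate")

# A modest shared population for screening/evaluation tests (kept small for
# speed; acceptance tests use the full study sizes).
small_histories <- function(seed = 101, births = 4000, cohorts = 10) {
  simulate_natural_history(cohort_spec(births, cohorts), seed = seed)
}

# Direct transcriptions of the closed-form onset functions, used as
# independent oracles against the package implementations.
oracle_survival <- function(t, A, B, d) {
  ((B - A) * exp(B * t) / (B * exp((B - A) * t) - A))^d
}
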