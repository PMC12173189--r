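# cgmscreen

Microsimulation of breast cancer natural history and mammography
screening strategies, built on a continuous tumor growth model and
calibrated to a Ghanaian clinical setting.

Settings without organized screening programs have no screening data to
evaluate policy options against. `cgmscreen` addresses this by simulating
the full latent disease course of a population — when tumors arise, how
fast they grow, when they would surface symptomatically — and then
overlaying candidate screening programs (age range, interval, attendance,
test sensitivity) on the *same* simulated population, so that strategies
can be compared on overdiagnosis, interval cancers, screen-detection
shares and the size and growth-rate mix of what each program finds.

## The model

* **Onset.** The age at which a tumor reaches 0.5 mm
  (volume `v0 = pi 0.5^3/6 ≈ 0.065 mm³`) follows the two-stage
  Moolgavkar–Venzon–Knudson carcinogenesis model with survival
  `G_T(t) = [(B−A)e^{Bt} / (Be^{(B−A)t} − A)]^δ`
  (defaults `A = −0.0722`, `B = 1.18e−3`, `δ = 0.0952`), sampled on ages
  38–92 with the residual mass as lifetime freedom from disease, and
  scaled by 0.48 for the West-African-to-Northern-European incidence
  ratio.
* **Growth.** Exponential in volume, `V(x) = v0 e^{(x−t)/r}`, with
  tumor-specific inverse growth rate `r ~ Gamma(a, b)`,
  `a = b = 0.8162`; doubling time `ln(2)·r` (253 days at `r = 1`).
* **Symptomatic detection.** Hazard proportional to current volume,
  `η V(x)` with `η = e^{−9.644} ≈ 6.48e−5` per mm³·year, making the
  excess volume at diagnosis exponential given `r` and the marginal a
  Lomax law — the likelihood `fit_mle()` maximizes over clinical
  diameters.
* **Screening.** Scheduled screens with a two-type attendance mixture
  (80% attend each screen with probability 0.90, 20% with 0.15) and
  logistic size-dependent sensitivity
  `p(d) = logit⁻¹(β0 + β1 d)` (moderate scenario: half-detection at
  9 mm). First Bernoulli success → screen-detected; symptomatic cases
  after an attended negative screen and before the next scheduled one →
  interval cancers.

## Worked example

Fit the tumor-size model to a (synthetic) 187-case clinical series, then
compare a biennial ages-30–65 program against no screening on a
175,000-person population:

```r
library(cgmscreen)

sizes <- generate_clinical_dataset(generator_spec(n_cases = 187, seed = 42))
fit_mle(sizes)
#> Marginal symptomatic-volume MLE (a = b constrained)
#>       estimate        se      lower      upper
#> eta 8.4272e-05 1.421e-05 0.00006089 0.00010765
#> a   6.7156e-01 8.432e-02 0.53285000 0.81027000
#> b   6.7156e-01 8.432e-02 0.53285000 0.81027000
#> log-likelihood: -2219.79  (n = 187 , z = 1.645 )

h    <- simulate_natural_history(cohort_spec(5000, 35), seed = 42)
pol  <- screening_policy(30, 65, 2)
sens <- sensitivity_params("moderate")
arm0 <- apply_screening(h, pol, sens, attendance_model("none"))
arm1 <- apply_screening(h, pol, sens, attendance_model("imperfect"))

strategy_metrics(arm0, arm1, pol)
#>   n_no_screening n_screening pct_change pct_overdiagnosis pct_screen_detected
#> 1          29243       30604   4.654105          4.447131            60.84172
#>   pct_interval
#> 1     13.28258

doubling_time_summary(arm1)
#>              mode     mean       sd        q1    median       q3     n
#> 1 screen_detected 304.3385 232.5194 130.99237 245.74550 420.5619 18620
#> 2        interval 139.8153 174.7923  37.86057  70.32785 162.1225  4065
```

Reading the output: at `n = 187` the fitted gamma shape carries a wide
standard error (~0.08–0.11), so a synthetic draw of that size lands
visibly off the generating values (`η = 6.481e−5`, `b = 0.8162`) — at
`n = 20,000` the fit recovers them to within 2%. In the strategy
comparison, screening adds ~4.4% excess diagnoses (overdiagnosis) within
ages 30–65, three in five diagnoses are made at screen, and
screen-detected tumors double in ~246 days versus ~70 days for interval
cancers — the length-bias signature: screening preferentially finds
slow-growing tumors.

Batch runs are driven by a YAML configuration
(`inst/extdata/example_config.yaml` documents the format) through
`run_compare()`, which writes strategy tables, descriptive summaries and
natural-history summaries as seed-stamped CSVs; `run_fit()` does the same
for the estimation step.

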