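dm <- default_detection
v0 <- dm$v0

test_that("conditional volume density is exponential in the excess volume", {
  r <- 0.9
  expect_equal(conditional_volume_density(v0 + 1e-12, r, dm), dm$eta * r,
               tolerance = 1e-6)
  expect_equal(conditional_volume_density(v0 - 1, r, dm), 0)
  total <- integrate(conditional_volume_density, v0, Inf, r = r, dm = dm,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  med <- v0 + log(2) / (dm$eta * r)
  below <- integrate(conditional_volume_density, v0, med, r = r, dm = dm,
                     rel.tol = 1e-10)$value
  expect_equal(below, 0.5, tolerance = 1e-8)
})

test_that("joint density factorizes and marginalizes correctly", {
  eta <- 6.481e-5; a <- 0.8162; b <- 0.8162
  v <- c(500, 5000, 50000); r <- c(0.4, 1.1, 2.3)
  expect_equal(joint_density(v, r, eta, a, b, v0),
               conditional_volume_density(v, r, detection_model(eta = eta)) *
                 dgamma(r, shape = a, rate = b))
  for (vv in c(200, 2000, 20000)) {
    marg <- integrate(function(rr) joint_density(rep(vv, length(rr)), rr,
                                                 eta, a, b, v0),
                      0, Inf, rel.tol = 1e-10)$value
    expect_equal(marg, marginal_volume_density(vv, eta, a, b, v0),
                 tolerance = 1e-6)
  }
  expect_true(all(joint_density(v, r, eta, a, b, v0) >= 0))
})

test_that("marginal volume density is the Lomax law with the right limits", {
  eta <- 6.481e-5; ab <- 0.8162
  # at the onset volume with a = b the density collapses to eta
  expect_equal(marginal_volume_density(v0 + 1e-9, eta, ab, ab, v0), eta,
               tolerance = 1e-4)
  total <- integrate(marginal_volume_density, v0, Inf, eta = eta,
                     a = ab, b = ab, v0 = v0, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # large equal shape/rate concentrates the growth rate at r = 1
  big <- 1e4
  v <- c(1000, 10000)
  expect_equal(marginal_volume_density(v, eta, big, big, v0),
               conditional_volume_density(v, 1, detection_model(eta = eta)),
               tolerance = 1e-3)
})

test_that("log-likelihood is the sum of log marginal densities", {
  d <- generate_clinical_dataset(generator_spec(n_cases = 50, seed = 2))
  eta <- 5e-5; ab <- 0.9
  expect_equal(log_likelihood(d, eta, ab, ab),
               sum(log(marginal_volume_density(d$volumes, eta, ab, ab, d$v0))),
               tolerance = 1e-10)
  # a single observation at the onset volume: l -> log(eta) when a = b
  tiny <- tumor_size_data(0.5 * (1 + 1e-9))
  expect_equal(log_likelihood(tiny, eta, ab, ab), log(eta), tolerance = 1e-6)
  # offending records are named
  d2 <- tumor_size_data(c(5, 1, 8))
  expect_error(log_likelihood(d2, eta, ab, ab, v0 = volume_from_diameter(2)),
               "record 2")
})

test_that("tumor size data validates its inputs", {
  expect_error(tumor_size_data(numeric(0)), "no diameters")
  expect_error(tumor_size_data(c(3, 0.4)), "exceed")
  expect_error(suppressWarnings(read_tumor_sizes(tempfile())),
               "cannot open|No such|does not exist")
  d <- tumor_size_data(c(12, 25.5))
  expect_equal(d$volumes, pi * c(12, 25.5)^3 / 6)
})

test_that("the MLE recovers generating parameters from a large sample", {
  d <- generate_clinical_dataset(generator_spec(n_cases = 20000, seed = 3))
  fit <- fit_mle(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate["b"] - 0.8162) / 0.8162, 0.02)
  expect_lt(abs(fit$estimate["eta"] - 6.481e-5) / 6.481e-5, 0.05)
  expect_equal(fit$estimate[["a"]], fit$estimate[["b"]])
  # optimality: fitted log-likelihood >= log-likelihood at the truth
  expect_gte(fit$log_lik, log_likelihood(d, 6.481e-5, 0.8162, 0.8162))
  # score is numerically zero at the optimum (log-parameter scale)
  p <- log(fit$estimate[c("eta", "b")])
  g <- vapply(1:2, function(i) {
    hh <- 1e-6
    pp <- p; pp[i] <- p[i] + hh
    pm <- p; pm[i] <- p[i] - hh
    (log_likelihood(d, exp(pp[1]), exp(pp[2]), exp(pp[2])) -
       log_likelihood(d, exp(pm[1]), exp(pm[2]), exp(pm[2]))) / (2 * hh)
  }, numeric(1))
  expect_lt(max(abs(g)) / abs(fit$log_lik), 1e-6)
  # interval half-width is exactly z * SE
  expect_equal(unname(fit$ci[, "upper"] - fit$estimate),
               unname(fit$z_multiplier * fit$se))
})

test_that("volume rescaling shifts eta and leaves the shape untouched", {
  d <- generate_clinical_dataset(generator_spec(n_cases = 3000, seed = 8))
  fit1 <- fit_mle(d)
  c3 <- 10^(1 / 3)                     # scales volumes by 10
  d10 <- tumor_size_data(d$diameters * c3, d0 = 0.5 * c3)
  fit10 <- fit_mle(d10)
  expect_equal(fit10$estimate[["b"]], fit1$estimate[["b"]], tolerance = 1e-4)
  expect_equal(fit10$estimate[["eta"]], fit1$estimate[["eta"]] / 10,
               tolerance = 1e-4)
})

test_that("estimator precision improves with sample size", {
  small <- parameter_recovery_experiment(
    generator_spec(n_cases = 200, seed = 40), n_replicates = 15)
  big <- parameter_recovery_experiment(
    generator_spec(n_cases = 20000, seed = 50), n_replicates = 4)
  rmse_b <- function(x) x$summary$rmse[x$summary$parameter == "b"]
  expect_lt(rmse_b(big), rmse_b(small))
  expect_lt(abs(big$summary$bias[big$summary$parameter == "b"]),
            abs(small$summary$bias[small$summary$parameter == "b"]) + 0.02)
})

test_that("degenerate and unconstrained fits behave sensibly", {
  dgn <- fit_mle(tumor_size_data(rep(20, 10)))
  expect_false(dgn$converged)
  expect_match(dgn$message, "degenerate")
  expect_error(fit_mle(tumor_size_data(5)), "at least 2")

  d <- generate_clinical_dataset(generator_spec(n_cases = 4000, seed = 12))
  fit3 <- fit_mle(d, constrain_equal = FALSE)
  expect_true(fit3$converged)
  expect_lt(abs(fit3$estimate["a"] - 0.8162) / 0.8162, 0.25)
  expect_gte(fit3$log_lik, fit_mle(d)$log_lik - 1e-6)
})
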