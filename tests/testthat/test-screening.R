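test_that("screening schedules enumerate the program ages", {
  expect_equal(screening_schedule(screening_policy(30, 65, 2)),
               seq(30, 64, by = 2))
  expect_length(screening_schedule(screening_policy(30, 65, 2)), 18)
  expect_length(screening_schedule(screening_policy(50, 69, 2)), 10)
  expect_length(screening_schedule(screening_policy(40, 74, 1)), 35)
  expect_error(screening_policy(65, 30, 2))
})

test_that("logistic screening sensitivity has the documented anchors", {
  s <- moderate
  expect_equal(screen_sensitivity(9, s), 0.5)       # -beta0/beta1 = 9 mm
  expect_equal(screen_sensitivity(15, s), 1 / (1 + exp(-3.36)))
  expect_equal(screen_sensitivity(1e4, s), 1)
  expect_gt(screen_sensitivity(10, sensitivity_params("high")),
            screen_sensitivity(10, sensitivity_params("low")))
  pert <- sensitivity_params("moderate", perturb = 0.1)
  expect_equal(pert$beta1, 0.56 * 1.1)
  expect_error(screen_sensitivity(-1, s), ">= 0")
})

test_that("attendance modes generate the right participation patterns", {
  sched <- screening_schedule(screening_policy(30, 65, 2))
  A <- assign_attendance(50, attendance_model("perfect"), sched, seed = 1)
  expect_true(all(A))
  expect_equal(dim(A), c(50, 18))
  expect_false(any(assign_attendance(50, attendance_model("none"), sched, 1)))
  B <- assign_attendance(2e5, attendance_model("imperfect"), sched[1:3], 2)
  p <- 0.8 * 0.9 + 0.2 * 0.15
  for (j in 1:3)
    expect_lt(abs(mean(B[, j]) - p), 3 * sqrt(p * (1 - p) / 2e5))
  expect_identical(assign_attendance(100, attendance_model(), sched, 3),
                   assign_attendance(100, attendance_model(), sched, 3))
})

h <- small_histories()
pol <- screening_policy(30, 65, 2)

test_that("zero sensitivity or zero attendance reduce to the natural history", {
  blind <- sensitivity_params("moderate", beta0 = -1e6, beta1 = 0.56)
  o <- apply_screening(h, pol, blind, attendance_model("imperfect"))
  expect_equal(sum(o$mode == "screen_detected"), 0)
  sympt <- !is.na(h$symptomatic_age) & h$symptomatic_age <= 100
  expect_equal(o$detection_age[sympt], h$symptomatic_age[sympt])

  o0 <- apply_screening(h, pol, moderate, attendance_model("none"))
  expect_equal(sum(o0$mode %in% c("screen_detected", "interval")), 0)
  expect_equal(o0$detection_age[sympt], h$symptomatic_age[sympt])
  expect_setequal(as.character(unique(o0$mode)), c("other_symptomatic", "none"))
})

test_that("screening outcomes respect the natural-history timeline", {
  o <- apply_screening(h, pol, moderate, attendance_model("imperfect"))
  scr <- o$mode == "screen_detected"
  expect_gt(sum(scr), 0)
  # screening never delays detection
  expect_true(all(o$detection_age[scr] <= h$symptomatic_age[scr]))
  # screen ages are scheduled ages
  expect_true(all(o$detection_age[scr] %in% screening_schedule(pol)))
  # diameter consistent with the growth curve at the screen age
  expect_equal(o$detection_diameter[scr],
               tumor_diameter_at_age(o$detection_age[scr],
                                     h$onset_age[scr],
                                     h$inv_growth_rate[scr]),
               tolerance = 1e-12)
  # interval cancers follow at least one attended negative screen
  iv <- o$mode == "interval"
  expect_gt(sum(iv), 0)
  expect_true(all(o$n_attended_negative_screens[iv] >= 1))
  expect_true(all(o$detection_age[iv] == h$symptomatic_age[iv]))
  # individuals with no onset or out-of-follow-up symptoms are 'none'
  expect_true(all(o$mode[is.na(h$onset_age)] == "none"))
})

test_that("screen-detected tumors show the length-bias signature", {
  hh <- small_histories(seed = 404, births = 10000, cohorts = 10)
  o <- apply_screening(hh, pol, moderate, attendance_model("imperfect"))
  scr <- o$mode == "screen_detected"; iv <- o$mode == "interval"
  expect_gt(sum(scr), 1000)
  expect_gt(sum(iv), 200)
  # smaller at detection, and slower growing (longer doubling times)
  expect_lt(median(o$detection_diameter[scr]), median(o$detection_diameter[iv]))
  expect_gt(median(doubling_time_days(o$inv_growth_rate[scr])),
            median(doubling_time_days(o$inv_growth_rate[iv])))
})

test_that("common random numbers couple the arms and sensitivity monotonically", {
  o_lo <- apply_screening(h, pol, sensitivity_params("low"), attendance_model())
  o_hi <- apply_screening(h, pol, sensitivity_params("high"), attendance_model())
  # natural-history component identical across overlays
  expect_identical(o_lo$symptomatic_age, o_hi$symptomatic_age)
  expect_identical(o_lo$onset_age, o_hi$onset_age)
  # raising the sensitivity slope never loses a screen detection
  expect_true(all(o_lo$mode != "screen_detected" |
                    o_hi$mode == "screen_detected"))
  # raising attendance to perfect never loses one either
  o_pf <- apply_screening(h, pol, sensitivity_params("low"),
                          attendance_model("perfect"))
  expect_true(all(o_lo$mode != "screen_detected" |
                    o_pf$mode == "screen_detected"))
  # identical call is fully reproducible
  expect_identical(
    as.data.frame(apply_screening(h, pol, moderate, attendance_model())),
    as.data.frame(apply_screening(h, pol, moderate, attendance_model())))
})

test_that("outcome CSV export keeps the contract columns", {
  o <- apply_screening(h, pol, moderate, attendance_model("imperfect"))
  path <- tempfile(fileext = ".csv")
  write_outcomes(o, path)
  back <- read.csv(path)
  expect_named(back, c("individual_id", "mode", "detection_age",
                       "detection_diameter_mm",
                       "n_attended_negative_screens"))
  expect_equal(nrow(back), nrow(h))
  unlink(path)
})
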