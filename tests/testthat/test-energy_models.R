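# Frozen expected values are direct evaluations of the published closed
# forms (exp(a*v+b), the quadratic cost, the ACSM linear equations),
# computed independently of the implementation.

test_that("horizontal METs matches the log-linear model on both branches", {
  expect_equal(mets_horizontal(0), exp(0.254354), tolerance = 1e-7)
  expect_equal(mets_horizontal(0), 1.2896, tolerance = 1e-4 / 1.2896)
  # each branch at the threshold, and their agreement
  expect_equal(exp(0.224528 * 8.69 + 0.254354), 9.074809, tolerance = 1e-6)
  expect_equal(mets_horizontal(8.69), exp(0.065439 * 8.69 + 1.636715),
               tolerance = 1e-12)
  expect_equal(mets_horizontal(8.69), 9.073698, tolerance = 1e-6)
  # fastest mean speed in the validation dataset
  expect_equal(mets_horizontal(17.4), 16.0443, tolerance = 1e-3 / 16)
  expect_error(mets_horizontal(-1), ">= 0")
  expect_warning(mets_horizontal(21), "extrapolates")
})

test_that("METs is strictly increasing in speed over [0, 20] km/h", {
  v <- seq(0, 20, by = 0.05)
  expect_true(all(diff(mets_horizontal(v)) > 0))
})

test_that("slope cost evaluates the published quadratic with intercept 1", {
  expect_identical(cost_of_slope(0), 1)
  expect_equal(cost_of_slope(10), 1.65573, tolerance = 1e-5 / 1.65573)
  expect_equal(cost_of_slope(-10), 0.61731, tolerance = 1e-5 / 0.61731)
  # vertex near -19% (= -b/2a) and positivity over the whole valid range
  s <- seq(-45, 45, by = 0.1)
  cost <- cost_of_slope(s)
  expect_equal(s[which.min(cost)], -19.0, tolerance = 0.1 / 19)
  expect_true(all(cost > 0))
  # clipping: slopes beyond +/-45% cost the same as the bound, with a note
  expect_message(c60 <- cost_of_slope(60), "clipped 1 slope")
  expect_equal(c60, suppressMessages(cost_of_slope(45)))
})

test_that("slope-adjusted METs is the product of its two factors", {
  expect_equal(mets_on_slope(10, 0), 9.886, tolerance = 1e-3 / 9.886)
  expect_equal(mets_on_slope(10, 10), 16.368, tolerance = 5e-3 / 16.368)
  expect_equal(mets_on_slope(0, 0), mets_horizontal(0))
  set.seed(8)
  v <- runif(20, 0, 18); s <- runif(20, -40, 40)
  expect_equal(mets_on_slope(v, s), mets_horizontal(v) * cost_of_slope(s),
               tolerance = 1e-12)
})

test_that("ACSM equations reproduce their printed flat-speed values", {
  expect_equal(acsm_walk_vo2(8, 0), 16.83333, tolerance = 1e-5)
  expect_equal(round(acsm_walk_vo2(8, 0), 1), 16.8)
  expect_equal(acsm_run_vo2(8, 0), 30.16667, tolerance = 1e-5)
  expect_equal(round(acsm_run_vo2(8, 0), 1), 30.2)
  expect_equal(acsm_walk_vo2(0, 0), 3.5)
  expect_equal(acsm_run_vo2(0, 0), 3.5)
  expect_equal(acsm_walk_vo2(5, 0.05), 19.33, tolerance = 0.01 / 19.33)
  expect_equal(acsm_run_vo2(12, 0.05), 52.5, tolerance = 0.01 / 52.5)
  expect_error(acsm_walk_vo2(-2), ">= 0")
})

test_that("the speed-switched ACSM equation jumps at 8 km/h where METs does not", {
  expect_equal(acsm_rw_vo2(7.99, 0), acsm_walk_vo2(7.99, 0))
  expect_equal(acsm_rw_vo2(7.99, 0), 16.82, tolerance = 0.01 / 16.8)
  expect_equal(acsm_rw_vo2(8, 0), acsm_run_vo2(8, 0))
  expect_equal(acsm_rw_vo2(5, 0), acsm_walk_vo2(5, 0))
  jump <- acsm_rw_vo2(8, 0) - acsm_rw_vo2(7.999, 0)
  expect_equal(jump, 13.335, tolerance = 1e-4)  # 30.1667 - 16.8317
  # the METs model's VO2-rate is continuous across its own threshold
  rate <- function(v) mets_horizontal(v) * 3.5
  expect_lt(abs(rate(8.69 + 1e-9) - rate(8.69 - 1e-9)), 0.01 * 3.5)
})

test_that("accumulation matches hand-computed single-leg totals", {
  b <- generate_track(leg_spec(10, 0, 360))
  kin <- segment_track(b$track)
  s <- accumulate_energy(kin, "mets")
  expect_equal(s$total_met_hours, 0.9886, tolerance = 1e-3 / 0.9886)
  expect_equal(s$vo2_ml_per_kg, 207.6, tolerance = 0.2 / 207.6)
  expect_true(is.na(s$vo2_l) && is.na(s$energy_kcal))
  s60 <- accumulate_energy(kin, "mets", athlete_profile(60))
  expect_equal(s60$vo2_l, 12.46, tolerance = 0.02 / 12.46)
  expect_equal(s60$energy_kcal, 62.3, tolerance = 0.1 / 62.3)
  # running equation at 10 km/h: (166.67*0.2 + 3.5) ml/kg/min over 6 min
  s_run <- accumulate_energy(kin, "acsm_run")
  expect_equal(s_run$vo2_ml_per_kg, (10 * 1000 / 60 * 0.2 + 3.5) * 6,
               tolerance = 1e-6)
  expect_equal(s_run$vo2_ml_per_kg, 221.0, tolerance = 0.1 / 221)
})

test_that("segment energy upholds its internal identities", {
  b <- generate_track(list(leg_spec(6, 8, 120), leg_spec(12, -8, 120)))
  kin <- segment_track(b$track)
  seg <- segment_energy(kin, "mets")
  expect_equal(seg$mets_slope, seg$mets_horizontal * seg$cost_slope,
               tolerance = 1e-9)
  expect_equal(seg$vo2_ml_per_kg, seg$met_hours * 3.5 * 60, tolerance = 1e-9)
  expect_equal(sum(seg$vo2_ml_per_kg),
               accumulate_energy(kin, "mets")$vo2_ml_per_kg)
})

test_that("accumulation is additive under segment splitting", {
  # one 600 s leg vs the same leg cut into 5 equal sub-legs
  whole <- generate_track(leg_spec(9, 4, 600))
  split5 <- generate_track(replicate(5, leg_spec(9, 4, 120), simplify = FALSE))
  k1 <- segment_track(whole$track); k5 <- segment_track(split5$track)
  for (m in c("mets", "acsm_rw", "acsm_run")) {
    a <- accumulate_energy(k1, m)$vo2_ml_per_kg
    b <- accumulate_energy(k5, m)$vo2_ml_per_kg
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("VO2 from the METs method is monotone in slope at fixed speed", {
  for (v in c(5, 10, 15)) {
    vals <- sapply(c(-10, 0, 10), function(s) {
      b <- generate_track(leg_spec(v, s, 60))
      accumulate_energy(segment_track(b$track), "mets")$vo2_ml_per_kg
    })
    expect_true(all(diff(vals) > 0))
  }
})

test_that("empty kinematics and missing mass raise the documented errors", {
  b <- generate_track(leg_spec(10, 0, 10))
  kin <- segment_track(b$track)
  kin$segments <- kin$segments[0, ]
  expect_error(accumulate_energy(kin, "mets"), "empty track")
  expect_error(accumulate_energy(segment_track(b$track), "mets",
                                 profile = list(mass = 60)),
               "athlete_profile")
})

test_that("coefficient overrides are honoured and validated", {
  expect_equal(cost_of_slope(10, model_coefficients(cost_b = 1e-9)),
               13.6524e-4 * 100 + 1, tolerance = 1e-7)
  expect_error(model_coefficients(nonsense = 1), "unknown coefficient")
})
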