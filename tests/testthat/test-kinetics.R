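test_that("maximum turbidity handles constant, logistic and decreasing curves", {
  t <- seq(0, 3600, 15)
  expect_equal(max_turbidity(turbidity_curve(t, rep(5, length(t)), 0.3)), 5)

  cv <- make_logistic_curve(9.35, 10.2e-3, 210)
  expect_lt(abs(max_turbidity(cv) - 9.35) / 9.35, 0.01)

  dec <- turbidity_curve(t, seq(8, 1, length.out = length(t)), 0.3)
  sm <- max_turbidity(dec)
  # strictly decreasing: the maximum is the first smoothed value
  expect_equal(sm, mean(dec$turbidity[1:3]))
  expect_error(max_turbidity(turbidity_curve(numeric(0), numeric(0), 0.3)),
               "empty")
})

test_that("maximal slope matches a ramp exactly and the logistic closed form", {
  t <- seq(0, 3600, 15)
  ramp <- turbidity_curve(t, 0.01 * t, 0.3)
  for (w in c(3L, 5L, 9L))
    expect_equal(max_slope_rate(ramp, w), 0.01)

  # logistic max derivative P*k/4; parameters mirror a mid-grid purified clot
  P <- 5.24; k <- 0.00525
  cv <- turbidity_curve(t, P / (1 + exp(-k * (t - 1500))), 0.3)
  expect_lt(abs(max_slope_rate(cv) - P * k / 4) / (P * k / 4), 0.02)

  expect_equal(max_slope_rate(turbidity_curve(t, rep(2, length(t)), 0.3)), 0)

  # fast clots: when the logistic transition is comparable to the combined
  # smoothing + window support the estimate biases low; stays within 10%
  # at the fastest published plasma magnitudes
  Pf <- 11.42; kf <- 4 * 59e-3 / Pf
  fast <- turbidity_curve(t, Pf / (1 + exp(-kf * (t - 400))), 0.3)
  expect_lt(abs(max_slope_rate(fast) - Pf * kf / 4) / (Pf * kf / 4), 0.10)
})

test_that("tangent lag equals the logistic closed form across the study range", {
  for (P in c(0.8, 5.24, 12)) for (lag in c(0, 100, 250)) {
    cv <- make_logistic_curve(P, P * 1.3e-3, lag)
    lg <- lag_time(cv)
    expect_false(lg$censored)
    expect_lt(abs(lg$time - lag), 15)   # within one sampling interval
  }
})

test_that("lag censoring and threshold conventions behave", {
  # clot essentially at plateau from the first read -> censored dash
  cv <- make_logistic_curve(5, 5e-3, -5000)
  expect_true(lag_time(cv)$censored)
  # lag before the first reading, curve still rising -> censored
  cv2 <- make_logistic_curve(3.5, 1.5e-3, -30)
  expect_true(lag_time(cv2)$censored)
  # threshold method returns the first sample at/above baseline + threshold
  t <- seq(0, 600, 15)
  tau <- pmax(0, 0.01 * (t - 300))
  cv3 <- turbidity_curve(t, tau, 0.3)
  lg <- lag_time(cv3, method = "threshold", threshold = 0.6)
  expect_true(lg$time >= 345 && lg$time <= 375)
  # flat zero curve -> undefined lag
  flat <- turbidity_curve(t, rep(0, length(t)), 0.3)
  expect_true(lag_time(flat)$undefined)
})

test_that("kinetics are time-shift and amplitude equivariant", {
  base <- make_logistic_curve(5.24, 6.88e-3, 155)
  shifted <- turbidity_curve(base$times,
                             oracle_logistic(base$times - 60, 5.24, 6.88e-3,
                                             155), 0.3)
  expect_equal(lag_time(shifted)$time, lag_time(base)$time + 60,
               tolerance = 1e-6)
  expect_equal(max_slope_rate(shifted), max_slope_rate(base), tolerance = 5e-3)
  expect_equal(max_turbidity(shifted), max_turbidity(base), tolerance = 1e-3)

  scaled <- turbidity_curve(base$times, 3 * base$turbidity, 0.3)
  expect_equal(max_turbidity(scaled), 3 * max_turbidity(base))
  expect_equal(max_slope_rate(scaled), 3 * max_slope_rate(base))
  expect_equal(lag_time(scaled)$time, lag_time(base)$time, tolerance = 1e-9)
})

test_that("extract_kinetics bundles the three parameters and never aborts", {
  cv <- make_logistic_curve(5.24, 6.88e-3, 155)
  k <- extract_kinetics(cv)
  expect_lt(abs(k$max_turbidity_cm - 5.24) / 5.24, 0.01)
  expect_lt(abs(k$rate_cm_s - 6.88e-3) / 6.88e-3, 0.02)
  expect_lt(abs(k$lag_s - 155), 15)

  t <- seq(0, 3600, 15)
  flat <- turbidity_curve(t, rep(0, length(t)), 0.3)
  kf <- extract_kinetics(flat)
  expect_equal(kf$max_turbidity_cm, 0)
  expect_equal(kf$rate_cm_s, 0)
  expect_true(kf$lag_undefined)

  expect_identical(extract_kinetics(cv), extract_kinetics(cv))
})
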