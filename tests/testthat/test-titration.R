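cfg <- titration_config()

test_that("risk index has its minimum near 112.5 and is symmetric-shaped", {
  g <- exp(5.381^(1 / 1.084))
  expect_lt(glycemic_risk(g), 1e-20)         # closed-form minimum
  expect_equal(g, 112.5, tolerance = 0.01)
  expect_gt(glycemic_risk(50), glycemic_risk(70))
  expect_gt(glycemic_risk(250), glycemic_risk(180))
  expect_true(all(glycemic_risk(seq(21, 599, by = 1)) >= 0))
  expect_error(glycemic_risk(-5), "positive")
})

test_that("night window is the longest bolus-free clock gap with margins", {
  # boluses at 07:00 / 13:00 / 19:00 daily
  tb <- rep(c(420, 780, 1140), 4) + rep((0:3) * 1440, each = 3)
  nw <- detect_night_window(tb, cfg)
  expect_equal(nw$start, 1200)  # 19:00 + 60 min margin
  expect_equal(nw$end, 390)     # 07:00 - 30 min margin
  expect_true(all(basalopt:::night_mask(seq(0, 355, by = 5), nw)))

  # no boluses at all -> fallback
  nw0 <- detect_night_window(numeric(0), cfg)
  expect_equal(c(nw0$start, nw0$end), c(0, 360))

  # boluses every 3 h leave no qualifying gap -> fallback
  nw3 <- detect_night_window(seq(0, 1439, by = 180), cfg)
  expect_equal(c(nw3$start, nw3$end), c(0, 360))
})

test_that("dead-zone and saturation follow the exact piecewise formula", {
  expect_equal(deadzone_saturation(0.4 * 0.5, 0.5, 4), 0)
  expect_equal(deadzone_saturation(-2 * 4, 0.5, 4), -4)
  expect_equal(deadzone_saturation(2.5, 0.5, 4), 2.5)
  # vectorized exactness on a grid
  x <- seq(-10, 10, by = 0.1)
  phi <- deadzone_saturation(x, 1, 3)
  expect_true(all(phi[abs(x) < 1] == 0))
  expect_true(all(phi[abs(x) > 3] == sign(x[abs(x) > 3]) * 3))
  keep <- abs(x) >= 1 & abs(x) <= 3
  expect_equal(phi[keep], x[keep])
})

test_that("run-to-run update saturates, dead-zones and contracts to B_opt", {
  cfg2 <- titration_config(x_min = 0.5, x_max = 4)
  expect_equal(run_to_run_update(20, 20.3, cfg2), 20)     # dead zone
  expect_equal(run_to_run_update(20, 30, cfg2), 24)       # saturation
  # repeated application converges within the predicted number of steps
  B <- 10; B_opt <- 31.4
  kmax <- ceiling(abs(B_opt - B) / 4) + 1
  for (k in seq_len(kmax)) B <- run_to_run_update(B, B_opt, cfg2)
  expect_lt(abs(B - B_opt), 0.5 + cfg2$dose_resolution)
})

test_that("fasting prediction matches plain simulation and is monotone in dose", {
  fw <- make_fit_window()
  fit <- fit_window(fw)
  y20 <- predict_fasting_profile(fit, 20)
  # definitional check against simulate() with meals and boluses zeroed
  model <- discretize(basalopt:::model_from_theta(fit), 5)
  ub <- numeric(288); ub[420 / 5 + 1] <- 20
  y_ref <- simulate_glucose(model, steady_state_init(model, 20, 420, 0),
                            u_basal = ub)
  expect_equal(y20, y_ref, tolerance = 1e-9)
  # more insulin, pointwise lower glucose
  y26 <- predict_fasting_profile(fit, 26)
  expect_true(all(y26 <= y20 + 1e-9))

  # at the steady-state requirement with no residual signal the profile
  # stays flat near the therapy basal glucose
  ctx <- fit$context
  m1 <- mean(basalopt:::fasting_day_parts(fit)$y_unit)
  dose_req <- (ctx$Gb - ctx$offset) / m1
  yreq <- predict_fasting_profile(fit, dose_req)
  expect_lt(max(abs(yreq - ctx$Gb)), 2.5)
})

test_that("grid search equals an independent exhaustive oracle", {
  fw <- make_fit_window(noise_cv = 0.07, seed = 31)
  fit <- fit_window(fw)
  om <- estimate_residual_signal(fw$bundle, fit)
  night <- detect_night_window(fw$doses, cfg)
  B_c <- 20
  rec <- optimize_basal_dose(fit, B_c, night, cfg, omegas = list(om))
  # oracle: brute-force evaluation of the printed cost over the same grid
  doses <- B_c * (1 + seq(-40, 40) / 100)
  clock <- seq(0, 1435, by = 5)
  nidx <- basalopt:::night_mask(clock, night)
  cost <- vapply(doses, function(b) {
    y <- predict_fasting_profile(fit, b, om)
    sum(glycemic_risk(pmax(y, 1e-8))) +
      cfg$alpha * sum(pmax(1 - y[nidx] / cfg$Gt, 0))
  }, numeric(1))
  expect_equal(rec$per_day[1], doses[which.min(cost)])
})

test_that("inverse-crime optimization lands within a grid step of the truth", {
  # the window's generating model wants fasting at Gb: the dose that
  # achieves it is known in closed form from the unit response
  fw <- make_fit_window(Si_factor = 1.1)
  fit <- fit_window(fw)
  ctx <- fit$context
  m1 <- mean(basalopt:::fasting_day_parts(fit)$y_unit)
  # risk-optimal fasting level is ~112.5; solve for the matching dose
  dose_star <- (112.5 - ctx$offset) / m1
  B_c <- dose_star * 1.1  # within the +-40 percent grid
  night <- structure(list(start = 0, end = 360), class = "night_window")
  rec <- optimize_basal_dose(fit, B_c, night, titration_config(alpha = 0))
  expect_lt(abs(rec$per_day[1] - dose_star), 0.011 * B_c + 1e-9)

  # true requirement far outside the grid clamps at the +40 percent edge
  B_far <- dose_star / 1.6
  rec2 <- optimize_basal_dose(fit, B_far, night, titration_config(alpha = 0))
  expect_equal(rec2$per_day[1], 1.4 * B_far, tolerance = 1e-9)
})

test_that("a flat in-range profile leaves the dose within a step of B_c", {
  fw <- make_fit_window()
  fit <- fit_window(fw)
  ctx <- fit$context
  m1 <- mean(basalopt:::fasting_day_parts(fit)$y_unit)
  # dose whose flat fasting level is exactly the risk minimum
  B_c <- (112.5 - ctx$offset) / m1
  night <- structure(list(start = 0, end = 360), class = "night_window")
  rec <- optimize_basal_dose(fit, B_c, night, titration_config(alpha = 0))
  expect_lt(abs(rec$per_day[1] - B_c), 0.011 * B_c)
})
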