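# Individualization: MAP fit of daily Si and per-meal absorption, then
# residual-signal deconvolution. Windows are generated through the public
# simulation path at known parameters (see helper-fixtures.R).

test_that("the fast objective path equals the public simulation path", {
  fw <- make_fit_window()
  pr <- fw$priors
  p <- fx_params
  ctx <- basalopt:::fit_context(fw$bundle, p$pop, p$basal, pr,
                                init_dose = fw$dose, t_b = fw$t_b,
                                Gb = fw$Gb)
  theta_log <- c(log(fw$Si_true), rep(log(c(fw$meal_true$f, fw$meal_true$kq1,
                                            fw$meal_true$kq2,
                                            fw$meal_true$kq12)), 4))
  y_fast <- basalopt:::cpp_fit_trace(theta_log, ctx$y_ins_unit,
                                     ctx$meal_idx0, ctx$meal_mg, ctx$dt,
                                     ctx$Sg, ctx$VgBW, ctx$offset)
  # fw$G_clean was produced by simulate_glucose() on the 9-state model
  expect_equal(as.numeric(y_fast), fw$G_clean, tolerance = 1e-6)

  # confluent absorption rates (kq2 equal to Sg) stay finite and accurate
  mc <- meal_absorption_parameters(f = 0.8, kq1 = 0.0025,
                                   kq2 = fx_params$pop$Sg, kq12 = 0.019)
  fwc <- make_fit_window(meal_true = mc)
  ctxc <- basalopt:::fit_context(fwc$bundle, p$pop, p$basal, pr,
                                 init_dose = fwc$dose, t_b = fwc$t_b,
                                 Gb = fwc$Gb)
  tlc <- c(log(fwc$Si_true), rep(log(c(mc$f, mc$kq1, mc$kq2, mc$kq12)), 4))
  yc <- basalopt:::cpp_fit_trace(tlc, ctxc$y_ins_unit, ctxc$meal_idx0,
                                 ctxc$meal_mg, ctxc$dt, ctxc$Sg, ctxc$VgBW,
                                 ctxc$offset)
  expect_true(all(is.finite(yc)))
  expect_lt(max(abs(as.numeric(yc) - fwc$G_clean)), 0.05)
})

test_that("negative log posterior behaves at its limits", {
  fw <- make_fit_window()
  p <- fx_params
  pr <- fw$priors
  theta_true <- c(fw$Si_true, rep(c(fw$meal_true$f, fw$meal_true$kq1,
                                    fw$meal_true$kq2, fw$meal_true$kq12), 4))
  v_true <- negative_log_posterior(theta_true, fw$bundle, pr, p$pop, p$basal,
                                   p$meal, init_dose = fw$dose, t_b = fw$t_b)
  theta_off <- theta_true; theta_off[1] <- theta_true[1] * 1.5
  v_off <- negative_log_posterior(theta_off, fw$bundle, pr, p$pop, p$basal,
                                  p$meal, init_dose = fw$dose, t_b = fw$t_b)
  expect_lt(v_true, v_off)

  # fully masked data reduces to the negative log prior
  bm <- fw$bundle
  bm$G[] <- NA
  bm$mask[] <- FALSE
  v_masked <- negative_log_posterior(theta_true, bm, pr, p$pop, p$basal,
                                     p$meal, init_dose = fw$dose,
                                     t_b = fw$t_b)
  pv_cost <- sum(0.5 * ((log(theta_true) -
    c(log(p$pop$Si), rep(log(c(p$meal$f, p$meal$kq1, p$meal$kq2,
                               p$meal$kq12)), 4))) /
    c(basalopt:::cv_to_sdlog(pr$si_cv),
      rep(basalopt:::cv_to_sdlog(pr$meal_cv), 16)))^2)
  expect_equal(v_masked, pv_cost, tolerance = 1e-9)
})

test_that("daily insulin sensitivity is recovered from noise-free data", {
  fw <- make_fit_window(Si_factor = 1.25)
  fit <- fit_window(fw)
  expect_lt(abs(fit$Si - fw$Si_true) / fw$Si_true, 0.05)
  # structural content: one parameter set per meal in the window
  expect_equal(nrow(fit$meal_params), 4)
})

test_that("Si recovery degrades gracefully under CGM noise", {
  errs <- vapply(1:12, function(r) {
    fw <- make_fit_window(Si_factor = 1.2, noise_cv = 0.07, seed = 100 + r)
    fit <- fit_window(fw)
    abs(fit$Si - fw$Si_true) / fw$Si_true
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("a day with no meals or boluses estimates only Si", {
  fw <- make_fit_window()
  b <- fw$bundle
  b$u_meal[] <- 0
  b$u_bolus[] <- 0
  fit <- suppressWarnings(fit_daily_parameters(
    b, fw$priors, fx_params$pop, fx_params$basal, fx_params$meal,
    init_dose = fw$dose, t_b = fw$t_b, Gb = fw$Gb))
  expect_equal(nrow(fit$meal_params), 0)
  expect_true(is.finite(fit$Si))
})

test_that("deconvolution recovers nothing when nothing is missing", {
  fw <- make_fit_window()
  fit <- fit_window(fw)
  om <- estimate_residual_signal(fw$bundle, fit)
  expect_lt(max(abs(om$omega)), 0.5)
})

test_that("deconvolution recovers an injected sinusoidal disturbance", {
  fw0 <- make_fit_window(fasting = TRUE)
  om_true <- 1.0 * sin(2 * pi * (fw0$tgrid - fw0$w0) / 360)
  fw <- make_fit_window(omega_true = om_true, fasting = TRUE)
  fit <- fit_window(fw)
  om <- estimate_residual_signal(fw$bundle, fit)
  truth_at_knots <- 1.0 * sin(2 * pi * (om$knot_time - fw0$w0) / 360)
  expect_gte(cor(om$omega, truth_at_knots), 0.8)
})

test_that("large regularization shrinks the residual signal to zero", {
  fw <- make_fit_window(noise_cv = 0.07, seed = 5)
  fit <- fit_window(fw)
  om <- estimate_residual_signal(fw$bundle, fit, lambda = 1e9)
  expect_lt(max(abs(om$omega)), 0.05)
})

test_that("including the residual signal never worsens the fit", {
  for (s in 1:5) {
    fw <- make_fit_window(Si_factor = 0.9 + 0.1 * s, noise_cv = 0.05,
                          seed = 200 + s)
    fit <- fit_window(fw)
    om <- estimate_residual_signal(fw$bundle, fit)
    keep <- fw$bundle$mask
    r0 <- (fw$bundle$G - fitted_trace(fit))[keep]
    r1 <- (fw$bundle$G - fitted_trace(fit, om))[keep]
    expect_lte(sqrt(mean(r1^2)), sqrt(mean(r0^2)) + 1e-9)
  }
})
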