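# Shared fixtures: all synthetic, built in code at test time.

fx_params <- default_parameters()

# A padded one-day identification window (18:00 of day 0 to 02:00 of day 2)
# generated through the public model path at known parameters. Data are
# produced at the algorithm's own linearization point so that parameter
# recovery is well-posed (inverse crime by design).
make_fit_window <- function(Si_factor = 1.25,
                            meal_true = meal_absorption_parameters(
                              f = 0.8, kq1 = 0.0025, kq2 = 0.011,
                              kq12 = 0.019),
                            dose = 20, t_b = 420, Gb = 115,
                            noise_cv = 0, seed = 1,
                            omega_true = NULL, fasting = FALSE) {
  p <- fx_params
  dt <- 5
  w0 <- 1080
  w1 <- 3000
  n <- (w1 - w0) / dt
  tgrid <- seq(w0, w1 - dt, by = dt)
  pop_t <- p$pop
  pop_t$Si <- p$pop$Si * Si_factor
  mt <- build_continuous_model(pop_t, p$basal, meal_true, output_offset = 0)
  md <- discretize(mt, dt)
  mk <- function(tt) as.integer((tt - w0) / dt) + 1L
  ub <- numeric(n)
  ub[mk(1440 + t_b)] <- dose
  bolus_t <- c(1140, 1440 + 420, 1440 + 780, 1440 + 1140)
  bolus_u <- c(5, 3.5, 5, 5)
  if (fasting) bolus_u <- rep(0, 4)
  ul <- numeric(n); ul[mk(bolus_t)] <- bolus_u
  meal_t <- bolus_t
  meal_g <- if (fasting) rep(0, 4) else c(65, 50, 75, 75)
  um <- numeric(n); um[mk(meal_t)] <- meal_g
  x0 <- steady_state_init(mt, dose, t_b, t_0 = w0 %% 1440)
  y_x1 <- simulate_glucose(md, x0, u_basal = ub, u_bolus = ul, u_meal = um,
                           omega = omega_true)
  de <- if (fasting) {
    dose_events(c(t_b, 1440 + t_b), c(dose, dose), c("basal", "basal"))
  } else {
    dose_events(c(t_b, 1440 + t_b, bolus_t), c(dose, dose, bolus_u),
                c("basal", "basal", rep("bolus", 4)))
  }
  gs0 <- glucose_series(tgrid, rep(Gb, n))
  b0 <- resample_bundle(gs0, de, dt, c(w0, w1))
  pr <- prior_spec()
  ctx0 <- basalopt:::fit_context(b0, p$pop, p$basal, pr, init_dose = dose,
                                 t_b = t_b, Gb = Gb)
  G <- y_x1 + ctx0$offset
  if (noise_cv > 0) {
    set.seed(seed)
    G <- G * (1 + noise_cv * rnorm(n))
  }
  bundle <- resample_bundle(glucose_series(tgrid, G), de, dt, c(w0, w1))
  if (!fasting) bundle$u_meal[mk(meal_t)] <- meal_g
  list(bundle = bundle, doses = de, Si_true = pop_t$Si,
       meal_true = meal_true, dose = dose, t_b = t_b, Gb = Gb,
       offset = ctx0$offset, w0 = w0, w1 = w1, dt = dt, n = n,
       tgrid = tgrid, meal_t = meal_t, meal_g = meal_g, priors = pr,
       G_clean = y_x1 + ctx0$offset)
}

fit_window <- function(fw, ...) {
  suppressWarnings(fit_daily_parameters(
    fw$bundle, fw$priors, fx_params$pop, fx_params$basal, fx_params$meal,
    init_dose = fw$dose, t_b = fw$t_b, Gb = fw$Gb, day_start = 1440, ...))
}

# tiny CSV fixtures written on the fly
write_cgm_csv <- function(path, times, values,
                          origin = "2024-03-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  df <- data.frame(timestamp = format(t0 + times * 60, "%Y-%m-%dT%H:%M:%S"),
                   glucose_mgdl = values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_pen_csv <- function(path, times, units, kind,
                          origin = "2024-03-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  df <- data.frame(timestamp = format(t0 + times * 60, "%Y-%m-%dT%H:%M:%S"),
                   units = units, kind = kind)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
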