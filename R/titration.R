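#' Titration configuration
#'
#' @param Gt night glucose target (mg/dL)
#' @param alpha night-penalty weight (dimensionless)
#' @param grid_span half-width of the dose search grid as a fraction of the
#'   current dose (default 0.40, i.e. changes up to plus/minus 40 percent)
#' @param grid_step grid step as a fraction of the current dose (default
#'   0.01)
#' @param x_min dead-zone half-width of the update rule (U)
#' @param x_max saturation bound of the update rule (U); `NULL` uses
#'   `max(1, 0.05 * B_c)` — a per-cycle change cap of about one unit,
#'   consistent with clinical titration steps
#' @param dose_resolution pen dose resolution (U)
#' @param cycle_days titration period (days)
#' @param night_min_duration minimum night-window duration (minutes)
#' @param margin_evening,margin_morning margins applied after the last
#'   evening bolus and before the first morning bolus (minutes)
#' @return an object of class `titration_config`
#' @export
titration_config <- function(Gt = 110, alpha = 100, grid_span = 0.40,
                             grid_step = 0.01, x_min = 0.5, x_max = NULL,
                             dose_resolution = 0.5, cycle_days = 3,
                             night_min_duration = 240, margin_evening = 60,
                             margin_morning = 30) {
  if (grid_step <= 0 || grid_step > grid_span)
    stop("titration_config: need 0 < grid_step <= grid_span")
  if (!is.null(x_max) && x_min >= x_max)
    stop("titration_config: need x_min < x_max")
  if (dose_resolution <= 0)
    stop("titration_config: dose_resolution must be positive")
  structure(list(Gt = Gt, alpha = alpha, grid_span = grid_span,
                 grid_step = grid_step, x_min = x_min, x_max = x_max,
                 dose_resolution = dose_resolution, cycle_days = cycle_days,
                 night_min_duration = night_min_duration,
                 margin_evening = margin_evening,
                 margin_morning = margin_morning),
            class = "titration_config")
}

x_max_eff <- function(cfg, B_c) cfg$x_max %||% max(1, 0.05 * B_c)

#' Blood-glucose risk index
#'
#' Symmetric glycemic risk, high in hypoglycemia (< 70 mg/dL) and
#' hyperglycemia (> 180 mg/dL):
#' `risk(g) = 10 * (1.509 * ((ln g)^1.084 - 5.381))^2`, with its minimum at
#' about 112.5 mg/dL.
#'
#' @param g glucose (mg/dL), positive
#' @return risk values (nonnegative)
#' @export
glycemic_risk <- function(g) {
  if (any(g <= 0)) stop("glycemic_risk: glucose must be positive")
  10 * (1.509 * (log(g)^1.084 - 5.381))^2
}

#' Night window personalized from the dose history
#'
#' The night period is the longest clock-time interval (mod 24 h) that
#' contains no insulin bolus on any observed day, shrunk by a margin after
#' the last evening bolus and before the first morning bolus. If no
#' bolus-free interval of at least `night_min_duration` remains, the fixed
#' fallback 00:00-06:00 is used.
#'
#' @param x a `data_bundle`, a `dose_events`, or a numeric vector of bolus
#'   clock times (minutes after midnight)
#' @param cfg [titration_config()]
#' @return an object of class `night_window` with `start` and `end` clock
#'   minutes (`end < start` means the window wraps past midnight)
#' @export
detect_night_window <- function(x, cfg = titration_config()) {
  tb <- if (inherits(x, "data_bundle")) x$time[x$u_bolus > 0]
        else if (inherits(x, "dose_events")) x$time[x$kind == "bolus"]
        else x
  fallback <- structure(list(start = 0, end = 360), class = "night_window")
  ck <- sort(unique(round(tb %% 1440)))
  if (length(ck) == 0) return(fallback)
  gaps_from <- ck
  gaps_to <- c(ck[-1], ck[1] + 1440)
  len <- gaps_to - gaps_from
  i <- which.max(len)
  start <- (gaps_from[i] + cfg$margin_evening) %% 1440
  end <- (gaps_to[i] - cfg$margin_morning) %% 1440
  dur <- (end - start) %% 1440
  if (dur < cfg$night_min_duration) return(fallback)
  structure(list(start = start, end = end), class = "night_window")
}

night_mask <- function(clock, night) {
  if (night$start <= night$end)
    clock >= night$start & clock < night$end
  else
    clock >= night$start | clock < night$end
}

# 9-state model materialized at the fitted daily insulin sensitivity,
# sharing the Gb coupling and affine intercept of the fit context
model_from_theta <- function(theta) {
  ctx <- theta$context
  pop <- ctx$pop
  pop$Si <- theta$Si
  pop$Gb <- ctx$Gb
  meal <- default_parameters()$meal
  build_continuous_model(pop, ctx$basal, meal, output_offset = ctx$offset)
}

# unit-dose fasting-day response and the residual-signal day response for
# one fitted day; both on the midnight-to-midnight grid at step dt
fasting_day_parts <- function(theta, omega = NULL, dt = 5) {
  ctx <- theta$context
  model <- discretize(model_from_theta(theta), dt)
  n <- as.integer(1440 / dt)
  ub <- numeric(n)
  ub[as.integer((ctx$t_b %% 1440) / dt) + 1L] <- 1
  x0 <- steady_state_init(model, 1, ctx$t_b, t_0 = 0)
  model0 <- model
  model0$output_offset <- 0
  y_unit <- simulate_glucose(model0, x0, u_basal = ub)
  y_om <- numeric(n)
  if (!is.null(omega)) {
    resp <- omega$fitted
    k0 <- as.integer(round((theta$day_start - ctx$time[1]) / ctx$dt))
    idx <- k0 + seq_len(as.integer(1440 / ctx$dt))
    idx <- idx[idx >= 1 & idx <= length(resp)]
    y_day <- rep(0, as.integer(1440 / ctx$dt))
    y_day[seq_along(idx)] <- resp[idx]
    if (abs(dt - ctx$dt) > 1e-9)
      y_day <- approx(seq_along(y_day), y_day, n = n)$y
    y_om <- y_day
  }
  list(y_unit = y_unit, y_om = y_om, offset = ctx$offset, n = n)
}

#' Predicted carbohydrate-free fasting profile
#'
#' Simulates the individualized model over one day under the basal dose
#' alone (no meals, no boluses), starting from the periodic steady state at
#' the tested dose, with the deconvolved residual signal as the only other
#' input.
#'
#' @param theta a `theta_estimate`
#' @param basal_dose dose to test (U)
#' @param omega optional `residual_signal`
#' @param dt simulation step (minutes)
#' @return glucose trace (mg/dL) over midnight-to-midnight
#' @export
predict_fasting_profile <- function(theta, basal_dose, omega = NULL, dt = 5) {
  p <- fasting_day_parts(theta, omega, dt)
  p$offset + basal_dose * p$y_unit + p$y_om
}

#' Optimize the basal dose by risk-weighted grid search
#'
#' For each fitted day, evaluates the daily cost
#' `sum_k risk(Y_basal(k)) + alpha * sum_{k in night} max(1 - Y_basal(k)/Gt, 0)`
#' over the candidate grid `B_c * (1 + j * grid_step)` for
#' `j = -grid_span/grid_step ... +grid_span/grid_step`, picks the
#' minimizer (ties resolved toward the smaller dose), averages the per-day
#' optima and rounds to the pen resolution.
#'
#' @param fits a `theta_estimate` or list of them (one per day)
#' @param B_c current basal dose (U)
#' @param night a `night_window`
#' @param cfg [titration_config()]
#' @param omegas optional list of `residual_signal` objects matching `fits`
#' @param dt prediction step (minutes)
#' @return an object of class `dose_recommendation` with `B_opt`, `per_day`
#'   optima, `risk` at the optimum, and `B_next` filled by
#'   [run_to_run_update()]
#' @export
optimize_basal_dose <- function(fits, B_c, night, cfg = titration_config(),
                                omegas = NULL, dt = 5) {
  if (inherits(fits, "theta_estimate")) fits <- list(fits)
  if (length(fits) == 0) stop("optimize_basal_dose: empty day list")
  steps <- round(cfg$grid_span / cfg$grid_step)
  js <- seq(-steps, steps)
  doses <- B_c * (1 + js * cfg$grid_step)
  doses <- doses[doses >= 0]
  per_day <- numeric(length(fits))
  risks <- numeric(length(fits))
  for (i in seq_along(fits)) {
    om_i <- if (is.null(omegas)) NULL else omegas[[i]]
    p <- fasting_day_parts(fits[[i]], om_i, dt)
    clock <- (seq_len(p$n) - 1L) * dt
    nidx <- night_mask(clock, night)
    cost <- vapply(doses, function(b) {
      y <- p$offset + b * p$y_unit + p$y_om
      if (any(y <= 0)) return(Inf)
      sum(glycemic_risk(y)) +
        cfg$alpha * sum(pmax(1 - y[nidx] / cfg$Gt, 0))
    }, numeric(1))
    k <- which.min(cost)   # first minimum = smallest dose on the ascending grid
    per_day[i] <- doses[k]
    risks[i] <- cost[k]
  }
  B_opt <- round_to(mean(per_day), cfg$dose_resolution)
  structure(list(B_opt = B_opt, per_day = per_day, risk = mean(risks),
                 B_next = NA_real_), class = "dose_recommendation")
}

#' Dead-zone and saturation nonlinearity
#'
#' `Phi(x) = 0` when `|x| < x_min`; `sign(x) * x_max` when `|x| > x_max`;
#' `x` otherwise.
#'
#' @param x proposed dose change (U)
#' @param x_min dead-zone half-width (U)
#' @param x_max saturation bound (U)
#' @return shaped change (U)
#' @export
deadzone_saturation <- function(x, x_min, x_max) {
  stopifnot(x_min >= 0, x_min < x_max)
  ifelse(abs(x) < x_min, 0, ifelse(abs(x) > x_max, sign(x) * x_max, x))
}

#' Run-to-run dose update
#'
#' `B_next = B_c + Phi(B_opt - B_c)`, rounded to the pen resolution and
#' floored at zero.
#'
#' @param B_c current dose (U)
#' @param B_opt optimal dose from any of the titration algorithms (U)
#' @param cfg [titration_config()]
#' @return updated dose (U)
#' @export
run_to_run_update <- function(B_c, B_opt, cfg = titration_config()) {
  xm <- x_max_eff(cfg, B_c)
  step <- deadzone_saturation(B_opt - B_c, cfg$x_min, xm)
  max(0, round_to(B_c + step, cfg$dose_resolution))
}

#' Recommend a basal dose from CGM and pen records
#'
#' End-to-end pipeline: grids the records day by day (each day padded by a
#' 6-hour head and a 2-hour tail), reconstructs carbohydrate inputs from
#' the bolus record (or takes supplied counted carbohydrates), augments
#' them with detected unbolused intakes, fits the daily parameters,
#' deconvolves the residual signal, optimizes the dose on each day and
#' applies the run-to-run update.
#'
#' @param glucose a [glucose_series()]
#' @param doses a [dose_events()]
#' @param current_dose current basal dose `B_c` (U)
#' @param therapy [therapy_parameters()]
#' @param days integer vector of day indices (0-based from the reference
#'   midnight) to analyze; default all complete days
#' @param params parameter set from [default_parameters()]
#' @param cfg [titration_config()]
#' @param priors [prior_spec()]
#' @param t_b basal dosing clock time (minutes); default inferred from the
#'   basal dose record
#' @param counted_carbs optional data frame `time` (minutes), `grams`:
#'   when supplied, these replace the bolus-record reconstruction
#' @param dt grid step (minutes)
#' @param lambda deconvolution weight
#' @param maxit,restarts optimizer schedule passed to
#'   [fit_daily_parameters()]
#' @return list with `B_opt`, `B_next`, `per_day`, `night_window`, `fits`
#' @export
recommend_basal_dose <- function(glucose, doses, current_dose, therapy,
                                 days = NULL, params = default_parameters(),
                                 cfg = titration_config(),
                                 priors = prior_spec(), t_b = NULL,
                                 counted_carbs = NULL, dt = 5,
                                 lambda = 250, maxit = 60, restarts = 3) {
  if (is.null(t_b)) {
    bt <- doses$time[doses$kind == "basal"] %% 1440
    t_b <- if (length(bt)) round(median(bt)) else 420
  }
  span <- range(glucose$time[glucose$valid])
  if (is.null(days)) {
    d0 <- ceiling((span[1] + 360) / 1440)
    d1 <- floor((span[2] - 120) / 1440) - 1L
    days <- seq(d0, max(d0, d1))
  }
  night <- detect_night_window(doses, cfg)
  fits <- list()
  omegas <- list()
  for (d in days) {
    w0 <- d * 1440 - 360
    w1 <- (d + 1) * 1440 + 120
    w0 <- max(w0, floor(span[1] / dt) * dt)
    w1 <- min(w1, (floor(span[2] / dt) + 1) * dt)
    w0 <- w0 + (w1 - w0) %% dt
    bundle <- resample_bundle(glucose, doses, dt, c(w0, w1))
    if (is.null(counted_carbs)) {
      bundle$u_meal <- reconstruct_meals(bundle$G, bundle$u_bolus, therapy)
    } else {
      cc <- counted_carbs[counted_carbs$time >= w0 & counted_carbs$time < w1, ]
      if (nrow(cc)) {
        ci <- pmin(pmax(round((cc$time - w0) / dt) + 1L, 1L), bundle$n)
        for (i in seq_along(ci))
          bundle$u_meal[ci[i]] <- bundle$u_meal[ci[i]] + cc$grams[i]
      }
    }
    det <- detect_unbolused_meals(bundle$G, dt, bundle$u_bolus,
                                  u_meal = bundle$u_meal,
                                  Vg = params$pop$Vg, BW = params$pop$BW,
                                  f = params$meal$f)
    if (nrow(det))
      bundle$u_meal[det$index] <- bundle$u_meal[det$index] + det$grams
    prior_basal <- doses$time[doses$kind == "basal" & doses$time < w0]
    init_dose <- if (length(prior_basal)) {
      doses$units[doses$kind == "basal" &
                    doses$time == max(prior_basal)][1]
    } else current_dose
    th <- fit_daily_parameters(bundle, priors, params$pop, params$basal,
                               params$meal, init_dose = init_dose,
                               t_b = t_b, Gb = therapy$Gb,
                               day_start = d * 1440,
                               ref_dose = therapy$TDI / 2,
                               restarts = restarts, maxit = maxit)
    om <- estimate_residual_signal(bundle, th, lambda = lambda)
    fits[[length(fits) + 1L]] <- th
    omegas[[length(omegas) + 1L]] <- om
  }
  rec <- optimize_basal_dose(fits, current_dose, night, cfg, omegas, dt)
  rec$B_next <- run_to_run_update(current_dose, rec$B_opt, cfg)
  list(B_opt = rec$B_opt, B_next = rec$B_next, per_day = rec$per_day,
       night_window = night, fits = fits, omegas = omegas, risk = rec$risk)
}
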