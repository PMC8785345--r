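#' Scenario configuration for the in-silico experiment
#'
#' The *nominal* scenario serves three identical meals every day (50, 75
#' and 75 g at 07:00, 13:00 and 19:00) with no behavioural or metabolic
#' variability beyond sensor noise. The *variance* scenario draws variable
#' meal sizes (daily total 200-300 g, main meals above 30 g), up to three
#' unannounced snacks below 40 g, uniform carbohydrate-counting errors
#' within plus/minus 40 percent, bolus delays up to 60 minutes, and
#' intra-day (dawn-phased sinusoid, 20 percent amplitude) plus day-to-day
#' (log-normal, 15 percent CV) insulin-sensitivity variability.
#'
#' @param kind `"nominal"` or `"variance"`
#' @param meal_times clock minutes of the three main meals
#' @param meal_sizes nominal meal sizes (g)
#' @param total_range daily carbohydrate bounds (g), variance scenario
#' @param main_min minimum main-meal size (g)
#' @param snack_max maximum snack size (g)
#' @param max_snacks maximum snacks per day
#' @param count_error carbohydrate-counting error half-range (fraction)
#' @param max_delay maximum bolus delay after a meal (minutes)
#' @param si_day_cv day-to-day insulin-sensitivity CV
#' @param si_intraday_amp intra-day sinusoid amplitude (fraction)
#' @param cgm_sd stationary CGM additive error sd (mg/dL)
#' @param cgm_phi CGM AR(1) lag-1 coefficient
#' @param smbg_cv SMBG proportional error CV
#' @param bolus_target bolus-calculator glucose target (mg/dL)
#' @param treat_grams rescue carbohydrate size (g)
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(kind = c("nominal", "variance"),
                            meal_times = c(420, 780, 1140),
                            meal_sizes = c(50, 75, 75),
                            total_range = c(200, 300), main_min = 30,
                            snack_max = 40, max_snacks = 3,
                            count_error = 0.40, max_delay = 60,
                            si_day_cv = 0.15, si_intraday_amp = 0.20,
                            cgm_sd = 15, cgm_phi = 0.7, smbg_cv = 0.05,
                            bolus_target = 110, treat_grams = 15) {
  kind <- match.arg(kind)
  structure(list(kind = kind, meal_times = meal_times,
                 meal_sizes = meal_sizes, total_range = total_range,
                 main_min = main_min, snack_max = snack_max,
                 max_snacks = max_snacks, count_error = count_error,
                 max_delay = max_delay, si_day_cv = si_day_cv,
                 si_intraday_amp = si_intraday_amp, cgm_sd = cgm_sd,
                 cgm_phi = cgm_phi, smbg_cv = smbg_cv,
                 bolus_target = bolus_target, treat_grams = treat_grams),
            class = "scenario_config")
}

# One subject's behavioural and noise streams for a whole trial, drawn from
# a dedicated seed so that every treatment arm consumes identical streams.
generate_behavior <- function(subject, scenario, days, stream_seed) {
  set.seed(stream_seed)
  nm <- length(scenario$meal_times)
  day_list <- vector("list", days)
  for (d in seq_len(days)) {
    if (scenario$kind == "nominal") {
      meals <- data.frame(time = scenario$meal_times,
                          grams = scenario$meal_sizes,
                          counted = scenario$meal_sizes,
                          delay = rep(0, nm))
      snacks <- data.frame(time = numeric(0), grams = numeric(0))
      si_day <- 1
      si_intraday <- rep(1, 1440)
    } else {
      repeat {
        total <- runif(1, scenario$total_range[1], scenario$total_range[2])
        ns <- sample(0:scenario$max_snacks, 1)
        sn <- if (ns > 0) runif(ns, 10, scenario$snack_max - 0.6)
             else numeric(0)
        rem <- total - sum(sn)
        if (rem < nm * (scenario$main_min + 1)) next
        w <- runif(nm, 0.5, 1.5)
        mains <- scenario$main_min + 1 +
          (rem - nm * (scenario$main_min + 1)) * w / sum(w)
        if (all(mains > scenario$main_min)) break
      }
      snack_times <- if (ns > 0)
        sort(sample(setdiff(seq(570, 1380, by = 30),
                            c(outer(scenario$meal_times, -60:60, "+"))),
                    ns))
      else numeric(0)
      mains <- round(mains)
      sn <- round(sn)
      # keep the rounded daily total inside the scenario bounds
      mains[1] <- mains[1] + round(total) - sum(mains) - sum(sn)
      counted <- round(mains * (1 + runif(nm, -scenario$count_error,
                                          scenario$count_error)))
      # rounding must not push the counting error past the stated bound
      counted <- clip(counted, ceiling(mains * (1 - scenario$count_error)),
                      floor(mains * (1 + scenario$count_error)))
      meals <- data.frame(time = scenario$meal_times,
                          grams = mains,
                          counted = counted,
                          delay = round(runif(nm, 0, scenario$max_delay)))
      snacks <- data.frame(time = snack_times, grams = sn)
      si_day <- exp(rnorm(1, 0, cv_to_sdlog(scenario$si_day_cv)))
      tt <- 0:1439
      si_intraday <- 1 - scenario$si_intraday_amp *
        cos(2 * pi * (tt - 360) / 1440)
    }
    day_list[[d]] <- list(meals = meals, snacks = snacks, si_day = si_day,
                          si_intraday = si_intraday)
  }
  # CGM additive AR(1) noise, continuous across the whole trial
  ntot <- days * 288L
  innov <- rnorm(ntot, 0, scenario$cgm_sd * sqrt(1 - scenario$cgm_phi^2))
  noise <- as.numeric(stats::filter(innov, scenario$cgm_phi,
                                    method = "recursive",
                                    init = rnorm(1, 0, scenario$cgm_sd)))
  cgm_noise <- matrix(noise, nrow = days, ncol = 288, byrow = TRUE)
  smbg_z <- rnorm(days)
  treat_u <- matrix(runif(days * 1440L), nrow = days, ncol = 1440)
  list(days = day_list, cgm_noise = cgm_noise, smbg_z = smbg_z,
       treat_u = treat_u)
}
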