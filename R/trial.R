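#' Meal bolus calculator
#'
#' Standard bolus arithmetic: carbohydrates over the carbohydrate ratio
#' plus a correction toward the target over the insulin sensitivity
#' factor, floored at zero and rounded to the pen resolution.
#'
#' @param carbs_counted counted carbohydrates (g)
#' @param G glucose at dosing time (mg/dL)
#' @param therapy [therapy_parameters()]
#' @param target correction target (mg/dL)
#' @param resolution pen resolution (U)
#' @return bolus dose (U)
#' @export
compute_bolus <- function(carbs_counted, G, therapy, target = 110,
                          resolution = 0.5) {
  round_to(pmax(0, carbs_counted / therapy$CR + (G - target) / therapy$ISF),
           resolution)
}

#' Hypoglycemia rescue-treatment policy
#'
#' While true glucose is below 70 mg/dL, each minute carries a 10 percent
#' chance that the episode is treated with rescue carbohydrates (so an
#' episode stays untreated past 30 minutes with probability 0.9^30, about
#' 4 percent); a 30-minute refractory period follows a treatment. Episodes
#' between 00:00 and 06:00 are never treated.
#'
#' @param true_glucose minute-resolution glucose (mg/dL)
#' @param clock clock minutes for each sample (defaults to starting at
#'   midnight)
#' @param u uniform draws, one per minute (defaults to fresh draws)
#' @param prob per-minute treatment probability
#' @param grams rescue carbohydrate size (g)
#' @param refractory minutes without further treatment after one
#' @param night no-treatment clock window `c(start, end)` in minutes
#' @return data frame with columns `minute` (1-based index) and `grams`
#' @export
hypo_treatment_policy <- function(true_glucose,
                                  clock = seq_along(true_glucose) - 1,
                                  u = NULL, prob = 0.10, grams = 15,
                                  refractory = 30, night = c(0, 360)) {
  n <- length(true_glucose)
  if (is.null(u)) u <- runif(n)
  ck <- clock %% 1440
  eligible <- true_glucose < 70 & !(ck >= night[1] & ck < night[2])
  hit <- eligible & u < prob
  minutes <- integer(0)
  ref <- 0L
  for (k in seq_len(n)) {
    if (ref > 0L) { ref <- ref - 1L; next }
    if (hit[k]) { minutes <- c(minutes, k); ref <- as.integer(refractory) }
  }
  data.frame(minute = minutes, grams = rep(grams, length(minutes)))
}

# 1-minute discretizations of a subject's true model, split into the
# insulin subsystem and the two carbohydrate chains (meal and rescue)
subject_truth <- function(subject) {
  pop <- subject$pop; basal <- subject$basal
  A <- matrix(0, 6, 6)  # x2 action, x3 precip, x4 soluble, x5, x6, x7
  A[1, 1] <- -pop$p2; A[1, 6] <- pop$p2 / (pop$Vi * pop$BW)
  A[2, 2] <- -basal$ksp
  A[3, 2] <- basal$ksp; A[3, 3] <- -basal$ka
  A[4, 4] <- -(pop$kc1 + pop$kc12)
  A[5, 4] <- pop$kc12; A[5, 5] <- -pop$kc2
  A[6, 3] <- basal$ka; A[6, 4] <- pop$kc1; A[6, 5] <- pop$kc2
  A[6, 6] <- -pop$kcl
  chain <- function(mp) cpp_expm(matrix(c(-(mp$kq1 + mp$kq12), mp$kq12,
                                          0, -mp$kq2), 2, 2))
  kpf <- subject$basal$precip_fraction
  list(Ad_z = cpp_expm(A),
       Ad_m = chain(subject$meal), Ad_r = chain(subject$rescue),
       Bz_basal = c(0, kpf * basal$F, (1 - kpf) * basal$F, 0, 0, 0),
       Bz_bolus = c(0, 0, 0, 1, 0, 0),
       gm = subject$meal$f / (pop$Vg * pop$BW),
       gr = subject$rescue$f / (pop$Vg * pop$BW),
       Sg = pop$Sg, SiGb_base = pop$Si * pop$Gb)
}

#' Simulate one day of a virtual subject
#'
#' Minute-resolution simulation of the subject's true model under the
#' day's behaviour stream: main meals and snacks, boluses computed from
#' counted carbohydrates and the CGM reading at (possibly delayed) dosing
#' time, the basal impulse at the subject's dosing clock time, the
#' hypoglycemia rescue policy, CGM sampling with AR(1) additive noise, and
#' one pre-breakfast SMBG draw with proportional error.
#'
#' @param subject a `virtual_subject`
#' @param truth cached [subject_truth()] matrices
#' @param scenario a `scenario_config`
#' @param behavior_day one element of the behaviour stream
#' @param cgm_noise_day 288 CGM noise values
#' @param treat_u_day 1440 uniform draws for the rescue policy
#' @param smbg_z_day standard-normal draw for the SMBG error
#' @param state carried model state (from the previous day)
#' @param basal_dose today's basal dose (U)
#' @param bolus_mult bolus alteration multiplier
#' @param treat_on whether rescue treatments are enabled
#' @return list with `true_g` (1440), `cgm` (288), `smbg`, `boluses`,
#'   `treatments`, `state`, insulin and carbohydrate totals
#' @export
simulate_day <- function(subject, truth, scenario, behavior_day,
                         cgm_noise_day, treat_u_day, smbg_z_day, state,
                         basal_dose, bolus_mult = 1, treat_on = TRUE) {
  meals <- behavior_day$meals
  snacks <- behavior_day$snacks
  SiGb <- truth$SiGb_base * behavior_day$si_day * behavior_day$si_intraday
  bolus_times <- sort(unique(pmin(meals$time + meals$delay, 1439L)))
  bounds <- c(0L, bolus_times, 1440L)
  bounds <- unique(bounds)
  all_meal_t <- c(meals$time, if (nrow(snacks)) snacks$time else numeric(0))
  all_meal_g <- c(meals$grams, if (nrow(snacks)) snacks$grams else numeric(0))
  o <- order(all_meal_t)
  all_meal_t <- all_meal_t[o]; all_meal_g <- all_meal_g[o]
  true_g <- numeric(1440)
  treatments <- integer(0)
  boluses <- data.frame(time = numeric(0), units = numeric(0))
  pend_bolus_t <- integer(0); pend_bolus_u <- numeric(0)
  z <- state$z; mch <- state$m; rch <- state$r; x1 <- state$x1
  refract <- state$refract %||% 0L
  for (si in seq_len(length(bounds) - 1L)) {
    a <- bounds[si]; b <- bounds[si + 1L]
    seg <- a:(b - 1L)
    in_seg <- function(tt) tt >= a & tt < b
    bi <- which(in_seg(pend_bolus_t))
    mi <- which(in_seg(all_meal_t))
    ba_idx <- if (subject$t_basal >= a && subject$t_basal < b)
      as.integer(subject$t_basal - a) else integer(0)
    out <- cpp_day_segment(
      truth$Ad_z, z, truth$Ad_m, mch, truth$Ad_r, rch, x1,
      truth$Sg, subject$G0, SiGb[seg + 1L],
      truth$Bz_basal, truth$Bz_bolus,
      ba_idx, if (length(ba_idx)) basal_dose else numeric(0),
      as.integer(pend_bolus_t[bi] - a), pend_bolus_u[bi],
      as.integer(all_meal_t[mi] - a), all_meal_g[mi] * 1000,
      truth$gm, subject$meal$kq1, subject$meal$kq2,
      truth$gr, subject$rescue$kq1, subject$rescue$kq2,
      treat_u_day[seg + 1L], treat_on, scenario$treat_grams * 1000,
      as.integer(a), as.integer(refract), 0L, 360L)
    true_g[seg + 1L] <- out$G
    if (length(out$events)) treatments <- c(treatments, out$events + a + 1L)
    z <- out$z; mch <- out$m; rch <- out$r; x1 <- out$x1
    refract <- out$refract
    if (b < 1440L) {
      # a bolus is due at minute b: dose from the latest completed CGM sample
      ks <- (b - 1L) %/% 5L
      g_cgm <- true_g[ks * 5L + 1L] + cgm_noise_day[ks + 1L]
      due <- which(pmin(meals$time + meals$delay, 1439L) == b)
      for (j in due) {
        ub <- bolus_mult *
          compute_bolus(meals$counted[j], g_cgm, subject,
                        target = scenario$bolus_target)
        if (ub > 0) {
          pend_bolus_t <- c(pend_bolus_t, b)
          pend_bolus_u <- c(pend_bolus_u, ub)
          boluses <- rbind(boluses, data.frame(time = b, units = ub))
        }
      }
    }
  }
  cgm_idx <- seq(1L, 1440L, by = 5L)
  cgm <- true_g[cgm_idx] + cgm_noise_day
  # fasting SMBG on waking (06:00), before any rescue treatment is possible
  smbg_min <- 360L
  smbg <- true_g[smbg_min + 1L] * (1 + scenario$smbg_cv * smbg_z_day)
  list(true_g = true_g, cgm = cgm, smbg = smbg, boluses = boluses,
       treatments = treatments,
       state = list(z = z, m = mch, r = rch, x1 = x1, refract = refract),
       basal_total = basal_dose, bolus_total = sum(boluses$units),
       carbs_total = sum(all_meal_g) +
         scenario$treat_grams * length(treatments))
}

#' Run one arm of the in-silico titration trial
#'
#' Simulates the cohort day by day under the given scenario and applies
#' the arm's titration algorithm every `cfg$cycle_days` days. Starting
#' basal doses are altered from the steady-state requirement by +50
#' percent for the first half of the cohort and -50 percent for the
#' second half, with the meal boluses altered by -25/+25 percent
#' respectively. Behaviour and noise streams are drawn per subject from
#' the trial seed only, so arms run with identical streams.
#'
#' Arms: `"CTR"` (no titration), `"SMBG-Rule"` (control-to-range),
#' `"SMBG-ILC"` (control-to-reference), `"CGM-Opt"` (model-based titration
#' with carbohydrates reconstructed from boluses), `"CGM-Opt-Carb"` (same,
#' but the optimizer receives the subject-counted carbohydrates).
#'
#' @param cohort a `virtual_cohort`
#' @param scenario a `scenario_config`
#' @param arm treatment arm label
#' @param days number of simulated days (multiple of `cfg$cycle_days`)
#' @param seed trial seed (behaviour streams; shared across arms)
#' @param cfg [titration_config()]
#' @param params population defaults used by the titration algorithm
#' @param priors [prior_spec()]
#' @param lambda deconvolution weight
#' @param maxit,restarts daily-fit optimizer schedule
#' @param progress print per-subject progress
#' @return an object of class `trial_result`
#' @export
run_trial <- function(cohort, scenario, arm = c("CTR", "SMBG-Rule",
                                                "SMBG-ILC", "CGM-Opt",
                                                "CGM-Opt-Carb"),
                      days = 60, seed = 1, cfg = titration_config(),
                      params = default_parameters(), priors = prior_spec(),
                      lambda = 250, maxit = 60, restarts = 3,
                      progress = FALSE) {
  arm <- match.arg(arm)
  if (days %% cfg$cycle_days != 0)
    stop("run_trial: days must be a multiple of the cycle length")
  n <- length(cohort)
  set.seed(seed)
  stream_seeds <- sample.int(2147483646L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subject <- cohort[[i]]
    truth <- subject_truth(subject)
    beh <- generate_behavior(subject, scenario, days, stream_seeds[i])
    up <- i <= ceiling(n / 2)
    start_dose <- round_to(subject$Ubasal_ss * (if (up) 1.5 else 0.5), 0.5)
    bolus_mult <- if (up) 0.75 else 1.25
    x0 <- steady_state_init(subject_model(subject), start_dose,
                            subject$t_basal, t_0 = 0)
    state <- list(z = x0[2:7], m = x0[8:9], r = c(0, 0), x1 = x0[1],
                  refract = 0L)
    cur_dose <- start_dose
    cgm <- matrix(NA_real_, days, 288)
    trueg <- matrix(NA_real_, days, 288)
    smbg <- numeric(days)
    dose_by_day <- numeric(days)
    bolus_by_day <- numeric(days)
    carbs_by_day <- numeric(days)
    treat_by_day <- integer(days)
    bolus_log <- NULL
    cycles <- NULL
    ilc_history <- numeric(0)
    for (d in seq_len(days)) {
      day <- simulate_day(subject, truth, scenario, beh$days[[d]],
                          beh$cgm_noise[d, ], beh$treat_u[d, ],
                          beh$smbg_z[d], state, cur_dose, bolus_mult)
      state <- day$state
      cgm[d, ] <- day$cgm
      trueg[d, ] <- day$true_g[seq(1, 1440, by = 5)]
      smbg[d] <- day$smbg
      dose_by_day[d] <- cur_dose
      bolus_by_day[d] <- day$bolus_total
      carbs_by_day[d] <- day$carbs_total
      treat_by_day[d] <- length(day$treatments)
      if (nrow(day$boluses))
        bolus_log <- rbind(bolus_log,
                           data.frame(time = (d - 1) * 1440 + day$boluses$time,
                                      units = day$boluses$units))
      if (d %% cfg$cycle_days == 0) {
        cyc <- d %/% cfg$cycle_days
        B_c <- cur_dose
        rec <- switch(
          arm,
          "CTR" = NULL,
          "SMBG-Rule" = {
            vals <- smbg[(d - cfg$cycle_days + 1):d]
            list(B_opt = titrate_control_to_range(vals, B_c))
          },
          "SMBG-ILC" = {
            ilc_history <- c(ilc_history,
                             mean(smbg[(d - cfg$cycle_days + 1):d]))
            list(B_opt = titrate_ilc(ilc_history, B_c, subject$BW))
          },
          {
            d0 <- max(1, d - cfg$cycle_days)
            drange <- d0:d
            gi <- as.vector(t(cgm[drange, , drop = FALSE]))
            gt <- rep((drange - 1) * 1440, each = 288) +
              rep(seq(0, 1435, by = 5), length(drange))
            gs <- glucose_series(gt, gi, source = "cgm")
            bas_t <- (drange - 1) * 1440 + subject$t_basal
            nb <- if (is.null(bolus_log)) 0L else nrow(bolus_log)
            ev <- data.frame(time = c(bas_t, bolus_log$time),
                             units = c(dose_by_day[drange], bolus_log$units),
                             kind = c(rep("basal", length(drange)),
                                      rep("bolus", nb)))
            ev <- ev[ev$time >= (d0 - 1) * 1440 & ev$time < d * 1440, ]
            de <- dose_events(ev$time, ev$units, ev$kind)
            counted <- NULL
            if (arm == "CGM-Opt-Carb") {
              cc <- NULL
              # include the day before the cycle: its dinner falls inside
              # the 6-hour head of the first identification window
              for (dd in max(1, d - cfg$cycle_days):d) {
                mm <- beh$days[[dd]]$meals
                cc <- rbind(cc, data.frame(time = (dd - 1) * 1440 + mm$time,
                                           grams = mm$counted))
              }
              counted <- cc
            }
            therapy <- therapy_parameters(TDI = subject$TDI,
                                          Gb = subject$Gb)
            rb <- recommend_basal_dose(
              gs, de, B_c, therapy,
              days = (d - cfg$cycle_days):(d - 1), params = params,
              cfg = cfg, priors = priors, t_b = subject$t_basal,
              counted_carbs = counted, lambda = lambda, maxit = maxit,
              restarts = restarts)
            list(B_opt = rb$B_opt, per_day = rb$per_day)
          })
        if (!is.null(rec)) {
          B_next <- run_to_run_update(B_c, rec$B_opt, cfg)
          cycles <- rbind(cycles,
                          data.frame(cycle = cyc, day_end = d, B_c = B_c,
                                     B_opt = rec$B_opt, B_next = B_next))
          cur_dose <- B_next
        } else {
          cycles <- rbind(cycles,
                          data.frame(cycle = cyc, day_end = d, B_c = B_c,
                                     B_opt = B_c, B_next = B_c))
        }
      }
    }
    subjects[[i]] <- list(id = subject$id, start_dose = start_dose,
                          alteration = if (up) 0.5 else -0.5,
                          bolus_mult = bolus_mult, cgm = cgm, true = trueg,
                          smbg = smbg, dose = dose_by_day,
                          bolus = bolus_by_day, carbs = carbs_by_day,
                          treatments = treat_by_day, cycles = cycles)
    if (progress)
      message(sprintf("subject %d/%d done (arm %s)", i, n, arm))
  }
  structure(list(arm = arm, scenario = scenario$kind, seed = seed,
                 days = days, cycle_days = cfg$cycle_days, cohort = cohort,
                 subjects = subjects, cfg = cfg),
            class = "trial_result")
}
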