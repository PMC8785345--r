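ln_jitter <- function(x, cv, n = 1) x * exp(rnorm(n, 0, cv_to_sdlog(cv)))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic virtual cohort
#'
#' Draws virtual subjects with type 1 diabetes on MDI therapy by log-normal
#' multiplicative jitter around the population parameter values. Each
#' subject carries a basal glucose `Gb`, a zero-insulin fasting intercept
#' `G0`, and the steady-state basal requirement `Ubasal_ss` solved from the
#' periodic steady state so that the daily-mean fasting glucose at
#' `Ubasal_ss` equals `Gb` exactly. Therapy parameters follow the 50
#' percent basal rule (`TDI = 2 Ubasal_ss`) and the 500/1800 rules. Basal
#' dosing time alternates between morning (07:00, taken with breakfast)
#' and bedtime (22:00) by subject id. Draws violating the invariants
#' (requirement outside 8-60 U, fasting ripple above 2 mg/dL) are redrawn
#' a bounded number of times. The cohort is deterministic given the seed.
#'
#' @param n number of subjects
#' @param seed RNG seed
#' @param params population defaults from [default_parameters()]
#' @return an object of class `virtual_cohort` (list of `virtual_subject`)
#' @export
generate_cohort <- function(n, seed, params = default_parameters()) {
  stopifnot(n >= 1)
  set.seed(seed)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- NULL
    for (try in 1:25) {
      BW <- clip(ln_jitter(params$pop$BW, 0.15), 45, 120)
      Gb <- clip(rnorm(1, 115, 8), 100, 135)
      G0 <- clip(rnorm(1, 225, 25), 180, 280)
      pop <- population_parameters(
        Sg = ln_jitter(params$pop$Sg, 0.15), Gb = Gb,
        Vg = params$pop$Vg, BW = BW,
        p2 = ln_jitter(params$pop$p2, 0.15),
        Vi = ln_jitter(params$pop$Vi, 0.10),
        Si = ln_jitter(params$pop$Si, 0.25),
        kc1 = ln_jitter(params$pop$kc1, 0.15),
        kc12 = ln_jitter(params$pop$kc12, 0.15),
        kc2 = ln_jitter(params$pop$kc2, 0.15),
        kcl = ln_jitter(params$pop$kcl, 0.15))
      basal <- basal_pk_parameters(
        F = clip(ln_jitter(params$basal$F, 0.10), 0.4, 1),
        precip_fraction = params$basal$precip_fraction,
        ksp = ln_jitter(params$basal$ksp, 0.10),
        ka = ln_jitter(params$basal$ka, 0.10))
      meal <- meal_absorption_parameters(
        f = clip(ln_jitter(params$meal$f, 0.15), 0.5, 1.15),
        kq1 = ln_jitter(params$meal$kq1, 0.25),
        kq2 = ln_jitter(params$meal$kq2, 0.25),
        kq12 = ln_jitter(params$meal$kq12, 0.25))
      t_basal <- if (i %% 2 == 1) 420 else 1320
      model <- build_continuous_model(pop, basal, meal, output_offset = 0)
      md <- discretize(model, 5)
      nday <- 288L
      ub <- numeric(nday)
      ub[as.integer(t_basal / 5) + 1L] <- 1
      x0u <- steady_state_init(model, 1, t_basal, t_0 = 0)
      prof_u <- simulate_glucose(md, x0u, u_basal = ub)  # x1 per unit dose
      m1 <- mean(prof_u)
      if (m1 >= 0) next
      U_ss <- (Gb - G0) / m1
      if (U_ss < 8 || U_ss > 60) next
      ripple <- max(abs(prof_u * U_ss - m1 * U_ss))
      if (ripple > 2) next
      TDI <- 2 * U_ss
      subj <- structure(list(
        id = i, pop = pop, basal = basal, meal = meal,
        rescue = params$rescue, Gb = Gb, G0 = G0, Ubasal_ss = U_ss,
        TDI = TDI, CR = 500 / TDI, ISF = 1800 / TDI,
        t_basal = t_basal, BW = BW), class = "virtual_subject")
      break
    }
    if (is.null(subj))
      stop("generate_cohort: could not draw a valid subject after 25 tries")
    cohort[[i]] <- subj
  }
  structure(cohort, seed = seed, class = "virtual_cohort")
}

#' True glucoregulatory model of a virtual subject
#'
#' The subject's 9-state model with the output offset fixed at the
#' subject's zero-insulin intercept `G0`, so that fasting simulation at
#' `Ubasal_ss` averages the subject's basal glucose.
#'
#' @param subject a `virtual_subject`
#' @return a `state_space_model`
#' @export
subject_model <- function(subject) {
  build_continuous_model(subject$pop, subject$basal, subject$meal,
                         output_offset = subject$G0)
}
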