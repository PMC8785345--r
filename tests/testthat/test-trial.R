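# Synthetic cohort, behaviour scenarios and the trial loop.

test_that("cohorts are deterministic and satisfy their construction invariants", {
  c1 <- generate_cohort(6, 99)
  c2 <- generate_cohort(6, 99)
  expect_identical(c1, c2)
  for (s in c1) {
    # basal share of the total daily dose is one half by construction
    expect_equal(s$Ubasal_ss / s$TDI, 0.5)
    expect_equal(s$CR, 500 / s$TDI)
    expect_equal(s$ISF, 1800 / s$TDI)
    # fasting simulation at the steady-state requirement holds basal glucose
    m <- subject_model(s)
    md <- discretize(m, 5)
    ub <- numeric(288); ub[s$t_basal / 5 + 1] <- s$Ubasal_ss
    tr <- simulate_glucose(md, steady_state_init(m, s$Ubasal_ss, s$t_basal, 0),
                           u_basal = ub)
    expect_lt(max(abs(tr - s$Gb)), 2 + 1e-6)
  }
})

test_that("bolus calculator applies carbohydrate, correction and flooring", {
  th <- therapy_parameters(TDI = 50, Gb = 115, CR = 10, ISF = 50)
  expect_equal(compute_bolus(50, 110, th), 5)
  expect_equal(compute_bolus(50, 160, th), 6)
  expect_equal(compute_bolus(0, 60, th), 0)
})

test_that("rescue policy spares the night and obeys the refractory period", {
  g <- rep(60, 1440)
  # glucose at or above 70: nothing happens
  expect_equal(nrow(hypo_treatment_policy(rep(75, 500))), 0)
  # a hypo entirely between 00:00 and 06:00 is never treated
  gn <- rep(100, 1440); gn[31:330] <- 55
  set.seed(8)
  expect_equal(nrow(hypo_treatment_policy(gn)), 0)
  # daytime hypo with forced hits: refractory spacing at least 30 min
  u <- rep(0, 600)  # every eligible minute would treat
  tr <- hypo_treatment_policy(rep(50, 600), clock = 600 + seq_len(600) - 1,
                              u = u)
  expect_gte(min(diff(tr$minute)), 31)
})

test_that("nominal scenario serves the fixed 50/75/75 g schedule", {
  sc <- scenario_config("nominal")
  s <- generate_cohort(1, 3)[[1]]
  beh <- basalopt:::generate_behavior(s, sc, 5, 77)
  for (d in 1:5) {
    m <- beh$days[[d]]$meals
    expect_equal(m$time, c(420, 780, 1140))
    expect_equal(m$grams, c(50, 75, 75))
    expect_equal(m$counted, m$grams)
    expect_equal(m$delay, c(0, 0, 0))
    expect_equal(nrow(beh$days[[d]]$snacks), 0)
  }
})

test_that("variance scenario honours its behavioural constraints", {
  sc <- scenario_config("variance")
  s <- generate_cohort(1, 3)[[1]]
  beh <- basalopt:::generate_behavior(s, sc, 150, 78)
  for (d in seq_len(150)) {
    day <- beh$days[[d]]
    total <- sum(day$meals$grams) + sum(day$snacks$grams)
    expect_gte(total, 200)
    expect_lte(total, 300)
    expect_true(all(day$meals$grams > 30))
    if (nrow(day$snacks)) expect_true(all(day$snacks$grams < 40))
    err <- abs(day$meals$counted - day$meals$grams) / day$meals$grams
    expect_true(all(err <= 0.4 + 1e-9))
    expect_true(all(day$meals$delay <= 60))
  }
})

test_that("fasting day at the steady-state dose stays near basal glucose", {
  s <- generate_cohort(2, 12)[[1]]
  sc <- scenario_config("nominal")
  truth <- basalopt:::subject_truth(s)
  beh <- basalopt:::generate_behavior(s, sc, 1, 5)
  beh$days[[1]]$meals <- beh$days[[1]]$meals[0, ]
  x0 <- steady_state_init(subject_model(s), s$Ubasal_ss, s$t_basal, 0)
  st <- list(z = x0[2:7], m = x0[8:9], r = c(0, 0), x1 = x0[1], refract = 0L)
  day <- simulate_day(s, truth, sc, beh$days[[1]], beh$cgm_noise[1, ] * 0,
                      beh$treat_u[1, ], 0, st, s$Ubasal_ss, 1)
  expect_lt(max(abs(day$cgm - s$Gb)), 3)
  expect_equal(length(day$treatments), 0)
})

test_that("paired arms share behaviour streams and differ only by titration", {
  co <- generate_cohort(2, 31)
  sc <- scenario_config("nominal")
  a <- suppressWarnings(run_trial(co, sc, "CTR", days = 6, seed = 17))
  b <- suppressWarnings(run_trial(co, sc, "SMBG-Rule", days = 6, seed = 17))
  # identical streams: day 1 (before any titration divergence) matches
  expect_identical(a$subjects[[1]]$cgm[1, ], b$subjects[[1]]$cgm[1, ])
  expect_identical(a$subjects[[1]]$smbg[1:3], b$subjects[[1]]$smbg[1:3])
  # CTR never changes the dose
  expect_true(all(a$subjects[[1]]$dose == a$subjects[[1]]$start_dose))
  expect_true(all(a$subjects[[2]]$dose == a$subjects[[2]]$start_dose))
})

test_that("doses change only at cycle boundaries and within the update cap", {
  co <- generate_cohort(2, 31)
  sc <- scenario_config("nominal")
  res <- suppressWarnings(run_trial(co, sc, "SMBG-ILC", days = 12, seed = 17))
  for (s in res$subjects) {
    d <- s$dose
    ch <- which(diff(d) != 0)
    expect_true(all(ch %% res$cycle_days == 0))
    for (cyc in seq_len(nrow(s$cycles))) {
      step <- abs(s$cycles$B_next[cyc] - s$cycles$B_c[cyc])
      expect_lte(step, max(1, 0.05 * s$cycles$B_c[cyc]) + 0.25 + 1e-9)
    }
  }
})
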