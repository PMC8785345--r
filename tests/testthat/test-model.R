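p <- fx_params

test_that("continuous matrix has the printed structure and mass balance", {
  m <- build_continuous_model(p$pop, p$basal, p$meal)
  A <- m$Ac
  expect_equal(A[1, 1], -p$pop$Sg)
  expect_equal(A[1, 2], -p$pop$Si * p$pop$Gb)
  expect_equal(A[1, 8], p$meal$f * p$meal$kq1 / (p$pop$Vg * p$pop$BW))
  expect_equal(A[1, 9], p$meal$f * p$meal$kq2 / (p$pop$Vg * p$pop$BW))
  # insulin sub-chain columns: mass leaves only through plasma clearance
  ins <- 3:7
  cs <- colSums(A[ins, ins])
  expect_equal(cs, c(0, 0, 0, 0, -p$pop$kcl),
               ignore_attr = TRUE, tolerance = 1e-12)

  # basal input split between the depots by the precipitate fraction
  b1 <- basal_pk_parameters(F = 0.8, precip_fraction = 1,
                            ksp = 3e-4, ka = 5e-4)
  m1 <- build_continuous_model(p$pop, b1, p$meal)
  expect_equal(m1$Bc_basal[3], 0.8)
  expect_equal(m1$Bc_basal[4], 0)
  b0 <- basal_pk_parameters(F = 0.8, precip_fraction = 0,
                            ksp = 3e-4, ka = 5e-4)
  m0 <- build_continuous_model(p$pop, b0, p$meal)
  expect_equal(m0$Bc_basal[3], 0)
  expect_equal(m0$Bc_basal[4], 0.8)

  expect_error(population_parameters(Sg = -0.01, Gb = 115, Vg = 1.6,
                                     BW = 70, p2 = 0.012, Vi = 120, Si = 700,
                                     kc1 = 0.002, kc12 = 0.02, kc2 = 0.02,
                                     kcl = 0.1),
               "positive")
})

test_that("discretization satisfies Taylor and semigroup identities", {
  m <- build_continuous_model(p$pop, p$basal, p$meal)
  err_at <- function(h) {
    md <- discretize(m, h)
    norm((md$Ad - diag(9)) / h - m$Ac, "F") / norm(m$Ac, "F")
  }
  expect_lt(err_at(0.01), 1e-3)
  # first-order convergence: halving the step halves the error
  expect_equal(err_at(0.01) / err_at(0.005), 2, tolerance = 0.05)
  A5 <- discretize(m, 5)$Ad
  A10 <- discretize(m, 10)$Ad
  expect_equal(A10, A5 %*% A5, tolerance = 1e-10)
  # spectral radius below one for a stable continuous matrix
  expect_lt(max(Mod(eigen(A5, only.values = TRUE)$values)), 1)
})

test_that("simulation is affine in its inputs and respects the offset", {
  m <- build_continuous_model(p$pop, p$basal, p$meal,
                              output_offset = p$pop$Gb)
  md <- discretize(m, 5)
  n <- 288
  y0 <- simulate_glucose(md, rep(0, 9), u_basal = numeric(n))
  expect_equal(y0, rep(p$pop$Gb, n))

  set.seed(2)
  u1 <- list(b = numeric(n), l = numeric(n), m = numeric(n))
  u2 <- list(b = numeric(n), l = numeric(n), m = numeric(n))
  u1$b[sample(n, 2)] <- c(10, 12)
  u1$m[sample(n, 3)] <- c(40, 60, 30)
  u2$l[sample(n, 3)] <- c(4, 6, 2)
  u2$m[sample(n, 2)] <- c(50, 20)
  y1 <- simulate_glucose(md, rep(0, 9), u1$b, u1$l, u1$m)
  y2 <- simulate_glucose(md, rep(0, 9), u2$b, u2$l, u2$m)
  y12 <- simulate_glucose(md, rep(0, 9), u1$b + u2$b, u1$l + u2$l,
                          u1$m + u2$m)
  expect_equal(y12 + y0, y1 + y2, tolerance = 1e-9)
})

test_that("basal bioavailability is conserved: F*D reaches plasma", {
  m <- build_continuous_model(p$pop, p$basal, p$meal)
  md <- discretize(m, 5)
  D <- 20
  n <- 288 * 60  # long enough for the slow depot to drain completely
  ub <- numeric(n); ub[1] <- D
  y <- simulate_glucose(md, rep(0, 9), u_basal = ub, return_states = TRUE)
  X <- attr(y, "states")
  # flux into plasma integrated over time approaches F*D
  absorbed <- p$basal$ka * sum(X[4, ]) * 5
  expect_lt(abs(absorbed - p$basal$F * D) / (p$basal$F * D), 0.001)
})

test_that("periodic steady state matches repeated dosing and is linear in dose", {
  m <- build_continuous_model(p$pop, p$basal, p$meal)
  md <- discretize(m, 5)
  expect_equal(steady_state_init(m, 0, 420, 0), rep(0, 9))
  x1 <- steady_state_init(m, 10, 420, 0)
  x2 <- steady_state_init(m, 20, 420, 0)
  expect_equal(x2, 2 * x1, tolerance = 1e-12)

  # closed form equals brute-force simulation of 100 daily doses
  n <- 288 * 100
  ub <- numeric(n); ub[seq(420 / 5 + 1, n, by = 288)] <- 20
  y <- simulate_glucose(md, rep(0, 9), u_basal = ub, return_states = TRUE)
  Xend <- attr(y, "states")[, n]          # 23:55 of day 100
  xss <- steady_state_init(m, 20, 420, t_0 = 1435)
  expect_lt(max(abs(Xend - xss)) / max(abs(xss)), 1e-6)
})

test_that("unstable dynamics are rejected at construction and inversion", {
  pop_bad <- p$pop
  A_ok <- build_continuous_model(p$pop, p$basal, p$meal)$Ac
  # force a zero eigenvalue through a degenerate hand-built matrix
  expect_error({
    m <- build_continuous_model(p$pop, p$basal, p$meal)
    m$Ac[3, 3] <- 0  # precipitate no longer drains
    steady_state_init(m, 10, 420, 0)
  }, "singular|stable")
})

test_that("offset calibration pins the fasting mean at Gb", {
  m <- build_continuous_model(p$pop, p$basal, p$meal)
  mc <- calibrate_output_offset(m, 22, 420)
  md <- discretize(mc, 5)
  ub <- numeric(288); ub[420 / 5 + 1] <- 22
  tr <- simulate_glucose(md, steady_state_init(mc, 22, 420, 0), u_basal = ub)
  expect_equal(mean(tr), p$pop$Gb, tolerance = 1e-8)
  expect_lt(max(abs(tr - mean(tr))), 2)  # peak-less basal profile
})
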