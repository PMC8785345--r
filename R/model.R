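#' Build the continuous-time glucoregulatory model
#'
#' Assembles the 9-state linearized subcutaneous oral glucose minimal model
#' augmented with a long-acting insulin absorption chain. State ordering
#' (used consistently everywhere in the package):
#' \enumerate{
#'   \item glucose deviation (mg/dL); the measured output is
#'     `x1 + output_offset`
#'   \item insulin action (plasma insulin concentration surrogate, U/mL)
#'   \item long-acting precipitate depot (U)
#'   \item long-acting soluble depot (U)
#'   \item rapid-acting subcutaneous compartment 1 (U)
#'   \item rapid-acting subcutaneous compartment 2 (U)
#'   \item plasma insulin mass (U)
#'   \item stomach carbohydrate (mg)
#'   \item gut carbohydrate (mg)
#' }
#' The glucose balance couples \eqn{-S_g} on itself, \eqn{-S_i G_b} on the
#' insulin action, and the parallel absorption gains
#' \eqn{f k_{q1}/(V_g BW)} and \eqn{f k_{q2}/(V_g BW)} on the stomach and
#' gut states. The basal dose splits `precip_fraction * F` into the
#' precipitate depot and `(1 - precip_fraction) * F` into the soluble depot.
#' Carbohydrate inputs are supplied in grams and converted to mg by the
#' meal input vector. The residual metabolic signal enters the glucose
#' balance directly (mg/dL/min).
#'
#' @param pop [population_parameters()]
#' @param basal [basal_pk_parameters()]
#' @param meal [meal_absorption_parameters()]
#' @param output_offset affine output term (mg/dL); the model output is
#'   `x1 + output_offset`. Defaults to `pop$Gb` and is normally re-calibrated
#'   with [calibrate_output_offset()].
#' @return an object of class `state_space_model` with the continuous
#'   matrices (`Ac`, `Bc_basal`, `Bc_bolus`, `Bc_meal`, `Bc_omega`, `C`)
#' @export
build_continuous_model <- function(pop, basal, meal,
                                   output_offset = pop$Gb) {
  s <- 9L
  A <- matrix(0, s, s)
  VgBW <- pop$Vg * pop$BW
  A[1, 1] <- -pop$Sg
  A[1, 2] <- -pop$Si * pop$Gb
  A[1, 8] <- meal$f * meal$kq1 / VgBW
  A[1, 9] <- meal$f * meal$kq2 / VgBW
  A[2, 2] <- -pop$p2
  A[2, 7] <- pop$p2 / (pop$Vi * pop$BW)
  A[3, 3] <- -basal$ksp
  A[4, 3] <- basal$ksp
  A[4, 4] <- -basal$ka
  A[5, 5] <- -(pop$kc1 + pop$kc12)
  A[6, 5] <- pop$kc12
  A[6, 6] <- -pop$kc2
  A[7, 4] <- basal$ka
  A[7, 5] <- pop$kc1
  A[7, 6] <- pop$kc2
  A[7, 7] <- -pop$kcl
  A[8, 8] <- -(meal$kq1 + meal$kq12)
  A[9, 8] <- meal$kq12
  A[9, 9] <- -meal$kq2
  if (any(Re(eigen(A, only.values = TRUE)$values) >= 0))
    stop("build_continuous_model: unstable continuous matrix ",
         "(eigenvalue with nonnegative real part)")
  k <- basal$precip_fraction
  Bb <- c(0, 0, k * basal$F, (1 - k) * basal$F, 0, 0, 0, 0, 0)
  Bl <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  # meal input in grams; states carried in mg
  Bm <- c(0, 0, 0, 0, 0, 0, 0, 1000, 0)
  Bw <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  Cd <- matrix(c(1, rep(0, s - 1)), nrow = 1)
  structure(list(Ac = A, Bc_basal = Bb, Bc_bolus = Bl, Bc_meal = Bm,
                 Bc_omega = Bw, C = Cd, output_offset = output_offset,
                 pop = pop, basal = basal, meal = meal,
                 dt = NULL, Ad = NULL, Bd_omega = NULL),
            class = "state_space_model")
}

#' Discretize the model at a fixed sampling interval
#'
#' Zero-order-hold discretization by matrix exponential: the state
#' transition is `Ad = expm(Ac dt)`. Dose and carbohydrate inputs are
#' treated as impulses (state injections with the continuous input
#' vectors), while the residual-signal channel is a flux held constant over
#' each step and is integrated exactly via an augmented matrix exponential.
#'
#' @param model a `state_space_model`
#' @param dt sampling interval (minutes)
#' @return the model with `Ad`, `Bd_omega` and `dt` populated
#' @export
discretize <- function(model, dt) {
  stopifnot(inherits(model, "state_space_model"), dt > 0)
  s <- nrow(model$Ac)
  model$Ad <- cpp_expm(model$Ac * dt)
  aug <- rbind(cbind(model$Ac, model$Bc_omega), 0)
  model$Bd_omega <- cpp_expm(aug * dt)[seq_len(s), s + 1]
  model$dt <- dt
  model
}

#' Simulate the glucose trace
#'
#' Forward-simulates the discretized model under impulse trains of basal
#' doses (U), bolus doses (U) and meals (grams), and a residual metabolic
#' signal held constant over each step (mg/dL/min). An input logged at
#' sample `k` affects the state from sample `k + 1` onward. Returns the
#' output `Y(k) = C X(k) + output_offset`.
#'
#' @param model a discretized `state_space_model`
#' @param x0 initial state (length 9); see [steady_state_init()]
#' @param u_basal,u_bolus,u_meal,omega input arrays of common length `n`
#'   (missing channels may be `NULL`)
#' @param return_states return the full state matrix as attribute `"states"`
#' @return numeric vector of glucose (mg/dL), length `n`
#' @export
simulate_glucose <- function(model, x0, u_basal = NULL, u_bolus = NULL,
                             u_meal = NULL, omega = NULL,
                             return_states = FALSE) {
  stopifnot(inherits(model, "state_space_model"))
  if (is.null(model$Ad)) stop("simulate_glucose: model is not discretized")
  n <- max(length(u_basal), length(u_bolus), length(u_meal), length(omega))
  if (n == 0) stop("simulate_glucose: no inputs supplied")
  zeros <- numeric(n)
  pick <- function(u) {
    if (is.null(u)) return(zeros)
    if (length(u) != n) stop("simulate_glucose: input lengths differ")
    u
  }
  U <- rbind(pick(u_basal), pick(u_bolus), pick(u_meal))
  B <- cbind(model$Bc_basal, model$Bc_bolus, model$Bc_meal)
  W <- matrix(pick(omega), nrow = 1)
  if (!all(is.finite(x0))) stop("simulate_glucose: non-finite initial state")
  X <- cpp_sim_lti(model$Ad, B, U, x0, matrix(model$Bd_omega, ncol = 1), W)
  if (any(!is.finite(X))) {
    bad <- which(colSums(!is.finite(X)) > 0)[1]
    stop("simulate_glucose: non-finite state at step ", bad)
  }
  y <- as.numeric(model$C %*% X) + model$output_offset
  if (return_states) attr(y, "states") <- X
  y
}

#' Periodic steady state under once-daily dosing
#'
#' Closed-form initial state for a train of once-daily basal impulses of
#' size `dose` given at clock time `t_b`, evaluated at clock time `t_0`:
#' `X = expm(Ac e) (I - expm(Ac T))^{-1} Bc_basal dose`, with
#' `e = (t_0 - t_b) mod T`.
#'
#' @param model a `state_space_model`
#' @param dose basal dose (U)
#' @param t_b dosing clock time (minutes after midnight)
#' @param t_0 evaluation clock time (minutes after midnight)
#' @param period dosing period (minutes), default one day
#' @return state vector (length 9)
#' @export
steady_state_init <- function(model, dose, t_b, t_0 = 0, period = 1440) {
  stopifnot(inherits(model, "state_space_model"), dose >= 0)
  elapsed <- (t_0 - t_b) %% period
  s <- nrow(model$Ac)
  eT <- cpp_expm(model$Ac * period)
  M <- diag(s) - eT
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-14)
    stop("steady_state_init: (I - expm(Ac T)) is singular; ",
         "the continuous matrix is not strictly stable")
  v <- solve(M, model$Bc_basal)
  as.numeric(cpp_expm(model$Ac * elapsed) %*% v) * dose
}

#' Calibrate the affine output term
#'
#' Sets the output offset so that, at the given steady-state basal dose and
#' with no meals or boluses, the daily mean of the fasting output equals
#' `Gb`. This pins the operating point of the linearization.
#'
#' @param model a `state_space_model`
#' @param dose steady-state basal dose (U)
#' @param t_b dosing clock time (minutes)
#' @param Gb target fasting glucose (mg/dL); defaults to the model's `Gb`
#' @param dt simulation step (minutes)
#' @return the model with `output_offset` replaced
#' @export
calibrate_output_offset <- function(model, dose, t_b, Gb = model$pop$Gb,
                                    dt = 5) {
  md <- discretize(model, dt)
  n <- as.integer(1440 / dt)
  x0 <- steady_state_init(model, dose, t_b, t_0 = 0)
  ub <- numeric(n)
  ub[as.integer(t_b / dt) + 1L] <- dose
  md$output_offset <- 0
  x1 <- simulate_glucose(md, x0, u_basal = ub)
  model$output_offset <- Gb - mean(x1)
  model
}
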