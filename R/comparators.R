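#' Control-to-range titration configuration
#'
#' @param G_min lower bound of the fasting range (mg/dL)
#' @param G_max upper bound of the fasting range (mg/dL)
#' @param dec_frac decrement as a fraction of the current dose
#' @param dec_min minimum decrement (U)
#' @param inc_step increment step (U) per `inc_per` mg/dL above `G_max`
#' @param inc_per glucose excess per increment step (mg/dL)
#' @param inc_max maximum increment (U)
#' @return an object of class `ctr_config`
#' @export
control_to_range_config <- function(G_min = 80, G_max = 130, dec_frac = 0.10,
                                    dec_min = 1, inc_step = 0.5,
                                    inc_per = 20, inc_max = 5) {
  if (G_min >= G_max) stop("control_to_range_config: need G_min < G_max")
  structure(list(G_min = G_min, G_max = G_max, dec_frac = dec_frac,
                 dec_min = dec_min, inc_step = inc_step, inc_per = inc_per,
                 inc_max = inc_max), class = "ctr_config")
}

#' Control-to-range SMBG titration
#'
#' Heuristic fasting-SMBG rule: if the cycle's minimum fasting value is
#' below `G_min`, decrease the dose by 10 percent of the current dose (at
#' least 1 U); if the cycle mean exceeds `G_max`, increase by 0.5 U per
#' 20 mg/dL of excess (0.5 to 5 U); otherwise keep the dose. The returned
#' optimal dose is meant to go through the shared [run_to_run_update()].
#'
#' @param smbg fasting SMBG values of the cycle (mg/dL)
#' @param B_c current basal dose (U)
#' @param cfg [control_to_range_config()]
#' @return optimal dose `B_opt` (U)
#' @export
titrate_control_to_range <- function(smbg, B_c, cfg = control_to_range_config()) {
  if (length(smbg) == 0) stop("titrate_control_to_range: no SMBG values")
  if (min(smbg) < cfg$G_min) {
    db <- max(cfg$dec_min, cfg$dec_frac * B_c)
    return(B_c - db)
  }
  m <- mean(smbg)
  if (m > cfg$G_max) {
    db <- cfg$inc_step * ceiling((m - cfg$G_max) / cfg$inc_per)
    db <- min(max(db, cfg$inc_step), cfg$inc_max)
    return(B_c + db)
  }
  B_c
}

#' Iterative-learning-control titration configuration
#'
#' @param gamma learning gain
#' @param G_target fasting reference (mg/dL)
#' @param pole pole of the first-order discrete filter `F(q)`
#' @param dc_gain DC gain of the filter in U per mg/dL; `NULL` uses the
#'   per-subject individualization `3/BW`
#' @return an object of class `ilc_config`
#' @export
ilc_config <- function(gamma = 1, G_target = 110, pole = 0.5,
                       dc_gain = NULL) {
  if (gamma < 0) stop("ilc_config: gamma must be nonnegative")
  if (pole < 0 || pole >= 1) stop("ilc_config: pole outside [0, 1)")
  structure(list(gamma = gamma, G_target = G_target, pole = pole,
                 dc_gain = dc_gain), class = "ilc_config")
}

#' Control-to-reference (ILC) SMBG titration
#'
#' Drives the cycle-mean fasting SMBG toward the reference through a
#' first-order discrete filter whose DC gain magnitude is individualized
#' to `3/BW` U per mg/dL:
#' `B_opt = B_c + gamma * F(q) (G_target - mean(SMBG))`.
#' Because insulin lowers glucose (negative plant gain), a convergent
#' learning law must increase the dose when fasting glucose sits above the
#' reference; the filter therefore carries a negative sign, equivalent to
#' `B_opt = B_c + gamma * |F(q)| (mean(SMBG) - G_target)`. The filter
#' state is reconstructed deterministically from the full per-cycle
#' history, so the function is stateless.
#'
#' @param smbg_history per-cycle fasting SMBG means (mg/dL), oldest first,
#'   ending with the current cycle
#' @param B_c current basal dose (U)
#' @param BW body weight (kg)
#' @param cfg [ilc_config()]
#' @return optimal dose `B_opt` (U)
#' @export
titrate_ilc <- function(smbg_history, B_c, BW, cfg = ilc_config()) {
  if (length(smbg_history) == 0) stop("titrate_ilc: empty history")
  if (BW <= 0) stop("titrate_ilc: BW must be positive")
  K <- cfg$dc_gain %||% (3 / BW)
  err <- smbg_history - cfg$G_target
  w <- 0
  for (e in err) w <- cfg$pole * w + (1 - cfg$pole) * K * e
  B_c + cfg$gamma * w
}
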