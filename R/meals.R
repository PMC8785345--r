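#' Therapy parameters
#'
#' Standard insulin-therapy quantities: total daily insulin dose `TDI`,
#' carbohydrate ratio `CR` (g/U) and insulin sensitivity factor `ISF`
#' (mg/dL per U). When not supplied, `CR` and `ISF` follow the 500- and
#' 1800-rules.
#'
#' @param TDI total daily insulin dose (U)
#' @param Gb basal glucose (mg/dL)
#' @param CR carbohydrate ratio (g/U); default `500/TDI`
#' @param ISF insulin sensitivity factor (mg/dL per U); default `1800/TDI`
#' @return an object of class `therapy_parameters`
#' @export
therapy_parameters <- function(TDI, Gb, CR = 500 / TDI, ISF = 1800 / TDI) {
  if (TDI <= 0) stop("therapy_parameters: TDI must be positive")
  structure(list(TDI = TDI, Gb = Gb, CR = CR, ISF = ISF),
            class = "therapy_parameters")
}

#' Reconstruct carbohydrate inputs from bolus records
#'
#' Inverts the patient's dosing rule to recover the carbohydrate amount
#' covered by each recorded bolus:
#' `U_meal(k) = max( (500/TDI) * (U_bolus(k) - (G(k) - Gb)/(1800/TDI)), 0 )`.
#' The reconstruction is nonzero only where a bolus was logged; negative
#' values (pure correction boluses) are clipped to zero. Masked glucose
#' samples fall back to `Gb` (no correction term can be inferred).
#'
#' @param G glucose array (mg/dL, `NA` where masked)
#' @param u_bolus bolus impulse array (U)
#' @param therapy [therapy_parameters()]
#' @return carbohydrate impulse array (grams)
#' @export
reconstruct_meals <- function(G, u_bolus, therapy) {
  if (therapy$TDI <= 0) stop("reconstruct_meals: TDI must be positive")
  if (length(G) != length(u_bolus))
    stop("reconstruct_meals: arrays must share length")
  g <- ifelse(is.na(G), therapy$Gb, G)
  cr <- 500 / therapy$TDI
  isf <- 1800 / therapy$TDI
  u <- pmax(cr * (u_bolus - (g - therapy$Gb) / isf), 0)
  u[u_bolus <= 0] <- 0
  u
}

#' Detect unbolused carbohydrate intakes
#'
#' Heuristic rise detector for meals (or rescue carbohydrates) that were
#' eaten without a bolus: a detection is flagged when the 30-minute CGM
#' slope exceeds `slope_thresh` sustained for at least `sustain_min`
#' minutes, outside an `exclusion_min` window after any recorded bolus or
#' any already-known carbohydrate input (so the tail of a recorded meal is
#' not re-detected as a new intake).
#' The initial size guess converts the rise amplitude back to grams via
#' the glucose distribution volume; sizes are deliberately coarse, since
#' absorption parameters are re-estimated per meal downstream.
#'
#' @param G glucose array (mg/dL, `NA` allowed)
#' @param dt grid step (minutes)
#' @param u_bolus bolus impulse array (U)
#' @param u_meal optional array of already-known carbohydrate impulses (g);
#'   rises inside their exclusion window are not re-detected
#' @param meal_exclusion_min exclusion window after a known meal (minutes);
#'   long enough (240) to cover the absorption tail, where the waning of
#'   the bolus can produce a genuine second rise
#' @param slope_thresh slope threshold (mg/dL/min), default 1.0 (calibrated
#'   so that meals of 40 g and above are caught with the default absorption
#'   rates while sensor noise alone stays below the false-positive budget)
#' @param sustain_min minimum sustained duration (minutes), default 25
#'   (meal absorption sustains the rise for 45+ minutes; autocorrelated
#'   sensor noise rarely does)
#' @param exclusion_min post-bolus exclusion window (minutes), default 120
#' @param Vg,BW,f glucose volume (dL/kg), body weight (kg) and
#'   carbohydrate bioavailability used for the size guess
#' @return data frame with columns `index` (grid sample of the onset) and
#'   `grams`; zero rows when nothing is detected
#' @export
detect_unbolused_meals <- function(G, dt, u_bolus, u_meal = NULL,
                                   slope_thresh = 1.0,
                                   sustain_min = 25, exclusion_min = 120,
                                   meal_exclusion_min = 240,
                                   Vg = 1.6, BW = 70, f = 0.9) {
  n <- length(G)
  lag <- max(1L, as.integer(round(30 / dt)))
  slope <- rep(NA_real_, n)
  ks <- seq.int(lag + 1L, n)
  slope[ks] <- (G[ks] - G[ks - lag]) / (lag * dt)
  hot <- !is.na(slope) & slope >= slope_thresh
  excl <- rep(FALSE, n)
  for (j in which(u_bolus > 0)) {
    to <- min(n, j + as.integer(ceiling(exclusion_min / dt)))
    excl[j:to] <- TRUE
  }
  if (!is.null(u_meal)) {
    for (j in which(u_meal > 0)) {
      to <- min(n, j + as.integer(ceiling(meal_exclusion_min / dt)))
      excl[j:to] <- TRUE
    }
  }
  need <- max(1L, as.integer(ceiling(sustain_min / dt)))
  out <- NULL
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= need)) {
    onset <- max(1L, starts[i] - lag)
    if (excl[onset] || excl[starts[i]]) next
    upto <- min(n, onset + as.integer(round(120 / dt)))
    seg <- G[onset:upto]
    rise <- max(seg, na.rm = TRUE) - G[onset]
    # rise amplitude underestimates total appearance (clearance during the
    # rise); the factor 3 is a coarse first-order correction
    grams <- min(max(3 * rise * Vg * BW / (1000 * f), 10), 100)
    out <- rbind(out, data.frame(index = onset, grams = grams))
  }
  if (is.null(out)) return(data.frame(index = integer(0), grams = numeric(0)))
  # merge detections closer than 60 min; keep the earliest onset
  keep <- c(TRUE, diff(out$index) * dt >= 60)
  out[keep, , drop = FALSE]
}
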