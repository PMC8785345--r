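#' Glycemic outcome metrics
#'
#' Percent time in ranges with the consensus boundary convention (the
#' in-range side is inclusive): time in range counts `70 <= g <= 180`
#' (tight range `70 <= g <= 140`), time below range counts `g < 70`
#' (`g < 54`), time above range counts `g > 180` (`g > 250`). The
#' partition TBR + TIR + TAR is exactly 100 percent.
#'
#' @param values glucose samples (mg/dL); `NA` samples are dropped
#' @param clock optional clock minutes per sample, needed for the night
#'   stratification
#' @param night night clock window `c(start, end)` minutes, default
#'   00:00-06:00
#' @return a list with elements `overall` and (when `clock` is given)
#'   `night`, each a one-row data frame of class `glycemic_metrics`
#' @export
glycemic_metrics <- function(values, clock = NULL, night = c(0, 360)) {
  if (length(values) == 0 || all(is.na(values)))
    stop("glycemic_metrics: empty window")
  one <- function(g) {
    g <- g[!is.na(g)]
    n <- length(g)
    out <- data.frame(
      tir_70_180 = 100 * sum(g >= 70 & g <= 180) / n,
      tir_70_140 = 100 * sum(g >= 70 & g <= 140) / n,
      tbr_70 = 100 * sum(g < 70) / n,
      tbr_54 = 100 * sum(g < 54) / n,
      tar_180 = 100 * sum(g > 180) / n,
      tar_250 = 100 * sum(g > 250) / n,
      mean = mean(g), sd = stats::sd(g), n = n)
    class(out) <- c("glycemic_metrics", "data.frame")
    out
  }
  res <- list(overall = one(values))
  if (!is.null(clock)) {
    ck <- clock %% 1440
    nmask <- if (night[1] <= night[2]) ck >= night[1] & ck < night[2]
             else ck >= night[1] | ck < night[2]
    res$night <- one(values[nmask])
  }
  res
}

subject_period_metrics <- function(subj, days_idx, use = c("cgm", "true")) {
  use <- match.arg(use)
  g <- as.vector(t(subj[[use]][days_idx, , drop = FALSE]))
  clock <- rep(seq(0, 1435, by = 5), length(days_idx))
  gm <- glycemic_metrics(g, clock)
  ov <- unlist(gm$overall[1, 1:8])
  ni <- unlist(gm$night[1, 1:8])
  names(ni) <- paste0("night_", names(ni))
  c(ov, ni,
    basal_u = mean(subj$dose[days_idx]),
    bolus_u = mean(subj$bolus[days_idx]),
    total_u = mean(subj$dose[days_idx] + subj$bolus[days_idx]),
    smbg = mean(subj$smbg[days_idx]))
}

#' Summarize a trial in 15-day periods
#'
#' Computes the glycemic and insulin metrics per subject for each
#' consecutive period and reports the cohort mean and standard deviation,
#' plus the change from the baseline period (when the result contains one)
#' with a normal-approximation confidence interval.
#'
#' @param result a `trial_result`
#' @param period period length in days (must divide the trial length)
#' @param baseline_days leading days to treat as the baseline period
#'   (0 for none)
#' @param use evaluate on `"cgm"` (what a deployment observes) or
#'   `"true"` glucose
#' @return a data frame: one row per period and metric with cohort
#'   `mean`, `sd`, and (if a baseline exists) `change`, `ci_lo`, `ci_hi`
#' @export
summarize_trial <- function(result, period = 15, baseline_days = 0,
                            use = "cgm") {
  D <- result$days
  if ((D - baseline_days) %% period != 0)
    stop("summarize_trial: period must divide the post-baseline length")
  starts <- seq(baseline_days + 1, D, by = period)
  base <- NULL
  if (baseline_days > 0) {
    base <- t(vapply(result$subjects, subject_period_metrics,
                     numeric(20), days_idx = seq_len(baseline_days),
                     use = use))
  }
  rows <- NULL
  for (p in seq_along(starts)) {
    idx <- starts[p]:(starts[p] + period - 1)
    vals <- t(vapply(result$subjects, subject_period_metrics,
                     numeric(20), days_idx = idx, use = use))
    for (j in seq_len(ncol(vals))) {
      row <- data.frame(period = p, day_start = idx[1], day_end = idx[period],
                        metric = colnames(vals)[j],
                        mean = mean(vals[, j]), sd = stats::sd(vals[, j]))
      if (!is.null(base)) {
        ch <- vals[, j] - base[, j]
        se <- stats::sd(ch) / sqrt(length(ch))
        row$change <- mean(ch)
        row$ci_lo <- mean(ch) - 1.96 * se
        row$ci_hi <- mean(ch) + 1.96 * se
      }
      rows <- rbind(rows, row)
    }
  }
  rows
}

#' Deviation of the final basal dose from the steady-state requirement
#'
#' Compares the mean administered basal dose over the last `window` days
#' to each subject's theoretical steady-state requirement, stratified by
#' the sign of the initial dose alteration.
#'
#' @param result a `trial_result`
#' @param window number of trailing days (default 15)
#' @return data frame with one row per stratum: mean and sd of the
#'   deviation in U and in percent of the requirement
#' @export
dose_deviation_summary <- function(result, window = 15) {
  D <- result$days
  idx <- (D - window + 1):D
  dev_u <- vapply(seq_along(result$subjects), function(i) {
    mean(result$subjects[[i]]$dose[idx]) - result$cohort[[i]]$Ubasal_ss
  }, numeric(1))
  dev_pct <- 100 * dev_u /
    vapply(result$cohort, function(s) s$Ubasal_ss, numeric(1))
  alt <- vapply(result$subjects, function(s) s$alteration, numeric(1))
  out <- NULL
  for (a in c(0.5, -0.5)) {
    sel <- alt == a
    out <- rbind(out, data.frame(
      group = if (a > 0) "higher start" else "lower start", n = sum(sel),
      dev_u_mean = mean(dev_u[sel]), dev_u_sd = stats::sd(dev_u[sel]),
      dev_pct_mean = mean(dev_pct[sel]), dev_pct_sd = stats::sd(dev_pct[sel])))
  }
  out
}

#' Sensitivity of the optimizer to carbohydrate information
#'
#' Compares the per-cycle optimal doses of two paired arms (same cohort,
#' same seed and behaviour streams; typically carbohydrate-reconstructing
#' versus carbohydrate-informed optimization) by the absolute difference
#' in `B_opt` at every titration change, averaged per subject and per
#' change.
#'
#' @param arm_a,arm_b paired `trial_result` objects
#' @return list with data frames `per_subject` and `per_change`, each with
#'   mean, sd, min and max of the absolute dose differences
#' @export
carb_sensitivity_report <- function(arm_a, arm_b) {
  if (arm_a$seed != arm_b$seed ||
      length(arm_a$subjects) != length(arm_b$subjects) ||
      arm_a$days != arm_b$days)
    stop("carb_sensitivity_report: arms are not paired")
  ns <- length(arm_a$subjects)
  diffs <- NULL
  for (i in seq_len(ns)) {
    ca <- arm_a$subjects[[i]]$cycles
    cb <- arm_b$subjects[[i]]$cycles
    m <- merge(ca[c("cycle", "B_opt")], cb[c("cycle", "B_opt")],
               by = "cycle", suffixes = c("_a", "_b"))
    diffs <- rbind(diffs, data.frame(subject = i, cycle = m$cycle,
                                     d = abs(m$B_opt_a - m$B_opt_b)))
  }
  per_subject <- tapply(diffs$d, diffs$subject, mean)
  per_change <- tapply(diffs$d, diffs$cycle, mean)
  sumrow <- function(x) data.frame(mean = mean(x), sd = stats::sd(x),
                                   min = min(x), max = max(x))
  list(per_subject = sumrow(as.numeric(per_subject)),
       per_change = sumrow(as.numeric(per_change)),
       diffs = diffs)
}

#' Titration cycles until the dose reaches the requirement
#'
#' For each subject, the first titration cycle after which the
#' administered dose lies within the dead-zone tolerance of the subject's
#' steady-state requirement.
#'
#' @param result a `trial_result`
#' @param tol tolerance (U); default `max(x_min, 0.5)` from the trial's
#'   titration configuration
#' @return integer vector per subject (`NA` when never reached)
#' @export
cycles_to_deadzone <- function(result, tol = NULL) {
  tol <- tol %||% max(result$cfg$x_min, 0.5)
  vapply(seq_along(result$subjects), function(i) {
    cyc <- result$subjects[[i]]$cycles
    target <- result$cohort[[i]]$Ubasal_ss
    hit <- which(abs(cyc$B_next - target) < tol)
    if (length(hit)) cyc$cycle[hit[1]] else NA_integer_
  }, numeric(1))
}
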