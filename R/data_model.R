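#' Glucose time series
#'
#' @param time_min timestamps in minutes since the reference midnight
#' @param glucose_mgdl glucose concentrations (mg/dL)
#' @param source `"cgm"` or `"smbg"`
#' @param t0 optional reference midnight (POSIXct), kept as an attribute so
#'   that series loaded from different files can be aligned
#' @return a `glucose_series` data frame with columns `time`, `glucose`,
#'   `valid` (readings outside (10, 1000) mg/dL are flagged invalid)
#' @export
glucose_series <- function(time_min, glucose_mgdl,
                           source = c("cgm", "smbg"), t0 = NULL) {
  source <- match.arg(source)
  o <- order(time_min)
  time_min <- time_min[o]
  glucose_mgdl <- glucose_mgdl[o]
  if (anyDuplicated(time_min)) {
    keep <- !duplicated(time_min, fromLast = TRUE)
    time_min <- time_min[keep]
    glucose_mgdl <- glucose_mgdl[keep]
  }
  x <- data.frame(time = time_min, glucose = glucose_mgdl,
                  valid = is.finite(glucose_mgdl) &
                    glucose_mgdl > 10 & glucose_mgdl < 1000)
  structure(x, source = source, t0 = t0,
            class = c("glucose_series", "data.frame"))
}

#' Insulin dose events
#'
#' @param time_min timestamps in minutes since the reference midnight
#' @param units dose sizes (U), nonnegative
#' @param kind `"basal"` or `"bolus"` per event
#' @param t0 optional reference midnight (POSIXct)
#' @return a `dose_events` data frame with columns `time`, `units`, `kind`
#' @export
dose_events <- function(time_min, units, kind, t0 = NULL) {
  if (any(units < 0)) stop("dose_events: doses must be nonnegative")
  if (!all(kind %in% c("basal", "bolus")))
    stop("dose_events: kind must be 'basal' or 'bolus'")
  o <- order(time_min)
  x <- data.frame(time = time_min[o], units = units[o], kind = kind[o])
  if (anyDuplicated(x[c("time", "kind")]))
    x <- x[!duplicated(x[c("time", "kind")], fromLast = TRUE), ]
  day <- floor(x$time / 1440)
  nb <- table(day[x$kind == "basal"])
  if (length(nb) && max(nb) > 2)
    stop("dose_events: more than two basal doses in one calendar day")
  structure(x, t0 = t0, class = c("dose_events", "data.frame"))
}

#' Load a CGM or pen CSV file
#'
#' Reads the plain CSV dialects used by the package: CGM files with header
#' `timestamp,glucose_mgdl` and pen files with `timestamp,units,kind`
#' (`kind` in basal/bolus). Timestamps are ISO-8601; times are converted to
#' minutes since the midnight preceding the earliest record (kept as
#' attribute `t0`). Rows are time-sorted; duplicate timestamps keep the
#' last record (pens re-send corrected entries). A malformed row raises an
#' error naming its line number; an empty file yields an empty container.
#'
#' @param path CSV file path
#' @param schema `"cgm"` or `"pen"`
#' @param t0 optional reference midnight (POSIXct) to align with a
#'   previously loaded series
#' @return a [glucose_series()] or [dose_events()]
#' @export
load_series <- function(path, schema = c("cgm", "pen"), t0 = NULL) {
  schema <- match.arg(schema)
  x <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- if (schema == "cgm") c("timestamp", "glucose_mgdl")
          else c("timestamp", "units", "kind")
  if (!all(need %in% names(x)))
    stop("load_series: expected columns ", paste(need, collapse = ", "))
  if (nrow(x) == 0) {
    return(if (schema == "cgm") glucose_series(numeric(0), numeric(0), t0 = t0)
           else dose_events(numeric(0), numeric(0), character(0), t0 = t0))
  }
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- rep(as.POSIXct(NA), nrow(x))
  for (fmt in fmts) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(x$timestamp[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad))
    stop("load_series: malformed timestamp at line ", bad[1] + 1L)
  if (is.null(t0)) t0 <- trunc(min(ts), units = "days")
  tm <- as.numeric(difftime(ts, t0, units = "mins"))
  if (schema == "cgm") {
    g <- suppressWarnings(as.numeric(x$glucose_mgdl))
    bad <- which(is.na(g))
    if (length(bad))
      stop("load_series: malformed glucose value at line ", bad[1] + 1L)
    glucose_series(tm, g, source = "cgm", t0 = t0)
  } else {
    u <- suppressWarnings(as.numeric(x$units))
    bad <- which(is.na(u) | u < 0)
    if (length(bad))
      stop("load_series: malformed or negative dose at line ", bad[1] + 1L)
    bad <- which(!x$kind %in% c("basal", "bolus"))
    if (length(bad))
      stop("load_series: unknown dose kind at line ", bad[1] + 1L)
    dose_events(tm, u, x$kind, t0 = t0)
  }
}

#' Write a series back to CSV
#'
#' Emits the same schema that [load_series()] reads.
#'
#' @param x a `glucose_series` or `dose_events`
#' @param path output file
#' @export
write_series <- function(x, path) {
  t0 <- attr(x, "t0")
  if (is.null(t0)) t0 <- as.POSIXct("2000-01-01", tz = "UTC")
  ts <- format(t0 + x$time * 60, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out <- if (inherits(x, "glucose_series"))
    data.frame(timestamp = ts, glucose_mgdl = x$glucose)
  else
    data.frame(timestamp = ts, units = x$units, kind = x$kind)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Resample glucose and doses onto the algorithm's fixed grid
#'
#' Builds the patient record on a uniform grid of step `dt` over the
#' half-open window `[t_a, t_b)`. Each grid sample takes the nearest-in-time
#' CGM value within `dt/2` (otherwise it is masked as missing); each dose is
#' assigned as an impulse to the nearest grid sample, so the total dose is
#' conserved exactly. Resampling an already-gridded record at the same `dt`
#' is the identity.
#'
#' @param glucose a [glucose_series()]
#' @param doses a [dose_events()] (may be `NULL`)
#' @param dt grid step (minutes); must divide the window length
#' @param window numeric `c(t_a, t_b)` in minutes
#' @return an object of class `data_bundle`: arrays `G` (with `NA` where
#'   masked), `u_basal`, `u_bolus`, `u_meal` (initially zero), the grid
#'   `time`, `dt`, `t_start` (clock minutes of the first sample) and `n`
#' @export
resample_bundle <- function(glucose, doses, dt = 5, window) {
  ta <- window[1]; tb <- window[2]
  if (tb <= ta) stop("resample_bundle: empty window")
  if (abs((tb - ta) / dt - round((tb - ta) / dt)) > 1e-9)
    stop("resample_bundle: dt must divide the window length")
  grid <- seq(ta, tb - dt, by = dt)
  n <- length(grid)
  gs <- glucose[glucose$valid & glucose$time >= ta - dt / 2 &
                  glucose$time < tb - dt / 2, , drop = FALSE]
  if (nrow(gs) == 0) stop("resample_bundle: empty record")
  G <- rep(NA_real_, n)
  idx <- round((gs$time - ta) / dt) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  off <- abs(gs$time - grid[idx])
  ok <- off <= dt / 2 + 1e-9
  # nearest wins: process in decreasing distance so closest overwrites
  o <- order(-off)
  G[idx[o][ok[o]]] <- gs$glucose[o][ok[o]]
  u_basal <- numeric(n); u_bolus <- numeric(n)
  if (!is.null(doses) && nrow(doses) > 0) {
    ds <- doses[doses$time >= ta - dt / 2 & doses$time < tb - dt / 2, ,
                drop = FALSE]
    if (nrow(ds) > 0) {
      di <- round((ds$time - ta) / dt) + 1L
      di[di < 1L] <- 1L
      di[di > n] <- n
      for (i in seq_len(nrow(ds))) {
        if (ds$kind[i] == "basal") u_basal[di[i]] <- u_basal[di[i]] + ds$units[i]
        else u_bolus[di[i]] <- u_bolus[di[i]] + ds$units[i]
      }
    }
  }
  structure(list(G = G, mask = !is.na(G), u_basal = u_basal,
                 u_bolus = u_bolus, u_meal = numeric(n), time = grid,
                 dt = dt, t_start = ta %% 1440, n = n),
            class = "data_bundle")
}
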