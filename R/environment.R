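# Deterministic models of the two environmental cycles transcript phases are
# compared against: solar elevation (low-precision NOAA-style formulas, no
# atmospheric refraction) and tidal height (harmonic constituent sum).

#' Default tidal constituent table (M2 only)
#'
#' The principal lunar semidiurnal constituent M2 (period 12.4206 h) with unit
#' amplitude. A pure harmonic toy standing in for gauge-derived constituents;
#' both study stations show semidiurnal (~12.4 h) tides, so M2 alone captures
#' the timing structure users need for coincidence labelling.
#'
#' @return A one-row constituents `data.frame`.
#' @export
m2_constituent <- function() {
  data.frame(name = "M2", period_h = 12.4206, amplitude_m = 1,
             phase_rad = 0, stringsAsFactors = FALSE)
}

#' Solar elevation angle
#'
#' Low-precision solar position: fractional-year Fourier series for the
#' declination and equation of time, then the hour angle at the observer's
#' longitude. Accurate to a few tenths of a degree for years 2000-2030, which
#' is enough to reproduce the diel shape and above/below-horizon status of the
#' sun at high latitude. No atmospheric refraction is applied.
#'
#' @param latitude_deg Latitude in degrees, `|lat| <= 90`.
#' @param longitude_deg Longitude in degrees (east positive).
#' @param timestamp_utc A `POSIXct` (UTC) vector, or a string parseable as
#'   `"%Y-%m-%dT%H:%M"`/`"%Y-%m-%d %H:%M:%S"` UTC.
#' @return Elevation above the horizon in degrees, in `[-90, 90]`.
#' @examples
#' # midnight sun at 74.5 N in late June: elevation stays positive
#' solar_elevation(74.5, 30, as.POSIXct("2018-06-30 00:00", tz = "UTC"))
#' @export
solar_elevation <- function(latitude_deg, longitude_deg, timestamp_utc) {
  if (abs(latitude_deg) > 90) stop("|latitude| must be <= 90")
  tt <- as_utc_time(timestamp_utc)
  lt <- as.POSIXlt(tt, tz = "UTC")
  doy <- lt$yday                       # 0-based day of year
  frac_h <- lt$hour + lt$min / 60 + lt$sec / 3600
  days_in_year <- ifelse((lt$year + 1900) %% 4 == 0, 366, 365)
  g <- 2 * pi / days_in_year * (doy + (frac_h - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
          0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
          0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  time_offset <- eqtime + 4 * longitude_deg          # minutes
  tst <- frac_h * 60 + time_offset                   # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180                   # hour angle, radians
  lat <- latitude_deg * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) * 180 / pi
}

as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "POSIXlt")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  for (f in fmts) {
    tt <- as.POSIXct(x, tz = "UTC", format = f)
    if (!anyNA(tt)) return(tt)
  }
  stop("invalid timestamp: ", x[1])
}

#' Tidal height from harmonic constituents
#'
#' `h(t) = z0 + sum_i A_i * cos(2*pi*t/T_i - phi_i)` over the supplied
#' constituents. Deterministic and bounded by `z0 +/- sum(A_i)`.
#'
#' @param time_h Numeric vector of times in hours.
#' @param constituents Constituents `data.frame` with columns `period_h`,
#'   `amplitude_m`, `phase_rad` (see [m2_constituent()], [read_constituents()]).
#' @param z0_m Datum offset in metres (default 0).
#' @return Tidal height in metres, same length as `time_h`.
#' @export
tidal_height <- function(time_h, constituents = m2_constituent(), z0_m = 0) {
  if (nrow(constituents) < 1) stop("at least one constituent required")
  if (any(constituents$period_h <= 0))
    stop("constituent period_h must be positive")
  h <- rep(z0_m, length(time_h))
  for (i in seq_len(nrow(constituents))) {
    h <- h + constituents$amplitude_m[i] *
      cos(2 * pi * time_h / constituents$period_h[i] -
          constituents$phase_rad[i])
  }
  h
}

#' Interior extrema of a sampled cycle
#'
#' Local maxima and minima found as sign changes of the first difference.
#' Plateaus (runs of equal values flanked by opposite slopes) are reported at
#' their midpoint time. The first and last points are never reported.
#'
#' @param times Strictly increasing numeric vector (>= 3 points).
#' @param values Numeric vector, same length.
#' @return A `data.frame` with columns `time_h` and `kind` (`"max"`/`"min"`),
#'   ordered by time; zero rows for monotone input.
#' @export
cycle_extrema <- function(times, values) {
  if (length(times) < 3) stop("at least 3 points required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(values) != length(times)) stop("times/values length mismatch")
  d <- diff(values)
  s <- sign(d)
  # collapse zero-runs: an extremum spans indices [i, j] where the value is
  # constant; report the midpoint of the plateau
  out_t <- numeric(0); out_k <- character(0)
  last_s <- 0; last_change <- 1
  for (i in seq_along(s)) {
    if (s[i] == 0) next
    if (last_s != 0 && s[i] != last_s) {
      # plateau (or single point) between last_change+? and i
      lo <- last_change + 1; hi <- i  # values[lo..hi] is the extremal plateau
      out_t <- c(out_t, (times[lo] + times[hi]) / 2)
      out_k <- c(out_k, if (last_s > 0) "max" else "min")
    }
    last_s <- s[i]
    last_change <- i
  }
  data.frame(time_h = out_t, kind = out_k, stringsAsFactors = FALSE)
}

#' Does the sun stay above the horizon all civil day?
#'
#' Scans the UTC civil day at 10-minute resolution and tests whether the
#' minimum solar elevation is positive (midnight sun).
#'
#' @param latitude_deg,longitude_deg Observer position in degrees.
#' @param date A `Date` or `"YYYY-MM-DD"` string.
#' @param step_min Scan resolution in minutes (default 10, the maximum
#'   resolution the check guarantees).
#' @return Logical.
#' @examples
#' midnight_sun(82.5, 30, "2018-06-18")  # TRUE
#' midnight_sun(0, 30, "2018-06-18")     # FALSE
#' @export
midnight_sun <- function(latitude_deg, longitude_deg, date, step_min = 10) {
  if (step_min > 10) stop("step_min must be <= 10 minutes")
  day0 <- as.POSIXct(paste(as.character(as.Date(date)), "00:00:00"),
                     tz = "UTC")
  tt <- day0 + seq(0, 24 * 3600, by = step_min * 60)
  min(solar_elevation(latitude_deg, longitude_deg, tt)) > 0
}

#' Build an environmental-cycle series with its extrema events
#'
#' Evaluates solar elevation and tidal height on a regular time grid starting
#' at `start_utc`, and locates the extrema of both: `solar_max` / `solar_min`
#' (upper and lower culminations) and `high_tide` / `low_tide`.
#'
#' @param latitude_deg,longitude_deg Observer position in degrees.
#' @param start_utc Start of the window (UTC timestamp or string).
#' @param hours Window length in hours (default 26, one day plus margin).
#' @param step_min Grid step in minutes (default 10).
#' @param constituents Tidal constituents table (default [m2_constituent()]).
#' @param z0_m Tidal datum offset in metres.
#' @param tide_phase_ref_h Hours added to the tidal phase clock so users can
#'   align a high tide with a chosen window time (default 0).
#' @param clock_offset_h Offset of local clock time from UTC (default +2, the
#'   study convention).
#' @return An object of class `env_cycle`: list with `series` (`data.frame`
#'   `time_h`, `clock_local`, `solar_elev_deg`, `tide_m`), `events`
#'   (`data.frame` `time_h`, `clock_local`, `kind`), and the call parameters.
#' @export
env_cycle <- function(latitude_deg, longitude_deg, start_utc,
                      hours = 26, step_min = 10,
                      constituents = m2_constituent(), z0_m = 0,
                      tide_phase_ref_h = 0, clock_offset_h = 2) {
  start <- as_utc_time(start_utc)
  time_h <- seq(0, hours, by = step_min / 60)
  tt <- start + time_h * 3600
  elev <- solar_elevation(latitude_deg, longitude_deg, tt)
  tide <- tidal_height(time_h + tide_phase_ref_h, constituents, z0_m)
  clock0 <- (as.POSIXlt(start, tz = "UTC")$hour +
             as.POSIXlt(start, tz = "UTC")$min / 60 + clock_offset_h) %% 24
  series <- data.frame(time_h = time_h,
                       clock_local = (clock0 + time_h) %% 24,
                       solar_elev_deg = elev, tide_m = tide)
  ev_sun <- cycle_extrema(time_h, elev)
  ev_tide <- cycle_extrema(time_h, tide)
  if (nrow(ev_sun))
    ev_sun$kind <- ifelse(ev_sun$kind == "max", "solar_max", "solar_min")
  if (nrow(ev_tide))
    ev_tide$kind <- ifelse(ev_tide$kind == "max", "high_tide", "low_tide")
  events <- rbind(ev_sun, ev_tide)
  events <- events[order(events$time_h), , drop = FALSE]
  events$clock_local <- (clock0 + events$time_h) %% 24
  rownames(events) <- NULL
  structure(list(series = series, events = events,
                 latitude_deg = latitude_deg, longitude_deg = longitude_deg,
                 start_utc = start, clock_offset_h = clock_offset_h),
            class = "env_cycle")
}

#' @export
print.env_cycle <- function(x, ...) {
  cat(sprintf("env_cycle at %.1f deg N, %.1f deg E from %s UTC (%.1f h)\n",
              x$latitude_deg, x$longitude_deg,
              format(x$start_utc, "%Y-%m-%d %H:%M"),
              max(x$series$time_h)))
  cat(sprintf("  solar elevation range: %.1f to %.1f deg\n",
              min(x$series$solar_elev_deg), max(x$series$solar_elev_deg)))
  print(x$events)
  invisible(x)
}

#' Write an environmental series as TSV
#'
#' Columns: `time_h`, `iso_time_local`, `solar_elev_deg`, `tide_m`.
#'
#' @param env An `env_cycle` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_env <- function(env, path) {
  local_time <- env$start_utc + (env$series$time_h + env$clock_offset_h) * 3600
  df <- data.frame(time_h = format_num12(env$series$time_h),
                   iso_time_local = format(local_time, "%Y-%m-%dT%H:%M",
                                           tz = "UTC"),
                   solar_elev_deg = format_num12(env$series$solar_elev_deg),
                   tide_m = format_num12(env$series$tide_m),
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comments = sprintf(
    "polarhythm environment; lat=%g lon=%g start_utc=%s",
    env$latitude_deg, env$longitude_deg,
    format(env$start_utc, "%Y-%m-%dT%H:%M")))
  invisible(path)
}
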