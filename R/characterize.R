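# Phase, amplitude and environment-coincidence characterization of rhythmic
# transcripts, on per-cycle-position median profiles of the folded data.

#' Per-cycle-position median profile
#'
#' Medians of all replicate values falling at each cycle position of a fold.
#'
#' @param values Numeric vector in sample order.
#' @param fold A `cycle_fold` from [fold_timepoints()].
#' @return Numeric vector, one median per cycle position.
#' @export
summarize_profile <- function(values, fold) {
  vapply(fold$groups, function(ix) stats::median(values[ix]), numeric(1))
}

#' Peak phase of a folded profile
#'
#' The cycle position of the profile maximum; ties are broken toward the
#' earliest position. Reported both as position within the cycle (`phase_h`)
#' and as the local clock hour of the corresponding sampling time
#' (`phase_clock_h`).
#'
#' @param profile Median profile from [summarize_profile()].
#' @param fold The `cycle_fold` the profile was computed on.
#' @return List with `phase_h` and `phase_clock_h`.
#' @export
estimate_phase <- function(profile, fold) {
  if (length(unique(profile)) == 1) stop("phase undefined (constant profile)")
  k <- which.max(profile)   # earliest position on ties
  list(phase_h = fold$positions[k], phase_clock_h = fold$clock_h[k])
}

#' Relative amplitude of a profile
#'
#' `A = (max - min) / min` after adding `pseudocount` to the profile: an
#' amplitude of 0.5 means the difference between the minimal and maximal
#' levels equals 0.5 times the minimal level.
#'
#' @param profile Numeric profile (typically per-position medians).
#' @param pseudocount Non-negative value added before the ratio (default 0;
#'   profiles whose shifted minimum is not positive are a hard error, forcing
#'   an explicit choice for zero-containing rows).
#' @return Amplitude `A >= 0`; 0 iff the profile is constant.
#' @examples
#' estimate_amplitude(c(2, 5))        # 1.5
#' estimate_amplitude(c(0, 4), pseudocount = 1)  # 4
#' @export
estimate_amplitude <- function(profile, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  p <- profile + pseudocount
  if (min(p) <= 0) stop("profile minimum plus pseudocount must be positive")
  (max(p) - min(p)) / min(p)
}

#' Amplitude bin label
#'
#' Bins used for the amplitude-distribution summaries: `[0, 0.5)`,
#' `[0.5, 1.5)`, `[1.5, 5]`, `(5, Inf)`.
#'
#' @param A Amplitude(s), non-negative.
#' @return Character vector of bin labels.
#' @export
amplitude_bin <- function(A) {
  if (any(A < 0)) stop("amplitude must be non-negative")
  ifelse(A < 0.5, "0-0.5",
         ifelse(A < 1.5, "0.5-1.5",
                ifelse(A <= 5, "1.5-5", ">5")))
}

#' Normalize a row to its median
#'
#' @param row Numeric vector with positive median.
#' @return `row / median(row)`; the normalized median is 1. Idempotent.
#' @export
median_normalize <- function(row) {
  md <- stats::median(row)
  if (md <= 0) stop("median must be positive")
  row / md
}

#' Label a phase by the nearest environmental event
#'
#' Finds the environmental extremum (solar culmination or tide turn) nearest
#' to the transcript's peak clock time on the 24 h clock circle. Within the
#' tolerance the event kind is returned, otherwise `"none"`. On exact
#' distance ties between a solar and a tidal event, tide events take
#' precedence for ultradian transcripts and solar events for daily ones.
#'
#' @param phase_clock_h Peak local clock hour.
#' @param events Events `data.frame` with columns `clock_local` and `kind`
#'   (from [env_cycle()]), or zero rows.
#' @param tolerance_h Maximum clock distance in hours (default 2, half the
#'   sampling interval).
#' @param period_range `"daily"` or `"ultradian"` (decides tie precedence).
#' @return One of `"solar_max"`, `"solar_min"`, `"high_tide"`, `"low_tide"`,
#'   `"none"`.
#' @export
coincidence_label <- function(phase_clock_h, events, tolerance_h = 2,
                              period_range = "daily") {
  if (is.null(events) || nrow(events) == 0) return("none")
  d <- abs(events$clock_local - phase_clock_h) %% 24
  d <- pmin(d, 24 - d)
  if (min(d) > tolerance_h) return("none")
  hit <- which(abs(d - min(d)) < 1e-9)
  if (length(hit) > 1) {
    tide <- grepl("tide", events$kind[hit])
    pref <- if (identical(period_range, "ultradian")) tide else !tide
    if (any(pref)) hit <- hit[pref]
  }
  events$kind[hit[1]]
}

#' Histogram of peak phases over sampling clock times
#'
#' Counts transcripts peaking at each sampling clock time; counts sum to the
#' number of transcripts with a defined phase.
#'
#' @param phase_clock_h Vector of peak clock hours (NA = undefined phase).
#' @param clock_times Clock hours of the design's sampling times (histogram
#'   support).
#' @return A `data.frame` with `clock_h` and `count`.
#' @export
phase_histogram <- function(phase_clock_h, clock_times) {
  clock_times <- sort(unique(clock_times))
  ph <- phase_clock_h[!is.na(phase_clock_h)]
  data.frame(clock_h = clock_times,
             count = vapply(clock_times, function(ct)
               sum(abs(ph - ct) < 1e-9), numeric(1)))
}

#' Characterize rhythmic transcripts: phase, amplitude, coincidence
#'
#' Fills the `phase_h`, `phase_clock_h`, `amplitude`, `amplitude_bin` and
#' `coincidence_label` columns of a [detect_rhythms()] scan for the
#' transcripts significant at `alpha`, using the median profile folded at
#' each transcript's assigned period. Transcripts with constant profiles keep
#' an undefined (NA) phase.
#'
#' @param scan A `rhythm_scan`.
#' @param x The expression data the scan was fitted on (`expr_data` or
#'   matrix in the scan's sample order).
#' @param alpha Adjusted-p cutoff selecting transcripts to characterize
#'   (default 0.001).
#' @param pseudocount Passed to [estimate_amplitude()].
#' @param env Optional [env_cycle()] covering the sampling window, used for
#'   coincidence labels.
#' @param tolerance_h Coincidence tolerance in hours (default 2).
#' @return The scan with characterization columns filled.
#' @export
characterize <- function(scan, x, alpha = 0.001, pseudocount = 0,
                         env = NULL, tolerance_h = 2) {
  mat <- if (inherits(x, "expr_data")) x$matrix else as.matrix(x)
  if (ncol(mat) != nrow(scan$samples))
    stop("matrix/scan dimension mismatch")
  res <- scan$results
  res$phase_clock_h <- NA_real_
  events <- if (!is.null(env)) env$events else NULL
  sel <- which(res$assigned_adj_p < alpha)
  for (i in sel) {
    fold <- scan$folds[[as.character(res$assigned_period_h[i])]]
    prof <- summarize_profile(mat[i, ], fold)
    amp <- tryCatch(estimate_amplitude(prof, pseudocount),
                    error = function(e) NA_real_)
    res$amplitude[i] <- amp
    res$amplitude_bin[i] <- if (is.na(amp)) NA_character_ else
      amplitude_bin(amp)
    ph <- tryCatch(estimate_phase(prof, fold), error = function(e) NULL)
    if (!is.null(ph)) {
      res$phase_h[i] <- ph$phase_h
      res$phase_clock_h[i] <- ph$phase_clock_h
      res$coincidence_label[i] <- if (is.null(events)) NA_character_ else
        coincidence_label(ph$phase_clock_h, events, tolerance_h,
                          res$period_range[i])
    }
  }
  scan$results <- res
  scan$characterized_alpha <- alpha
  scan
}
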