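# Synthetic expression matrices with planted rhythms. The generator emulates
# the study design: per station, 7 samplings at 4 h intervals over 24 h with 3
# replicate pools per time, rhythms at 24/20/16/12 h periods with chosen
# phases and amplitudes on an arrhythmic lognormal background.

#' Expected value of a planted rhythmic waveform
#'
#' `x(t) = b * (1 + (A/2) * (1 + cos(2*pi*(t - phi)/P)))`: a raised cosine
#' with baseline (trough) `b` at antiphase and peak `b * (1 + A)` at `t = phi`
#' (mod `P`), so that the relative amplitude `(max - min)/min` of the
#' noiseless waveform equals `A` exactly.
#'
#' @param t_h Time(s) in hours.
#' @param baseline Trough expression level `b > 0`.
#' @param amplitude Relative amplitude `A >= 0`.
#' @param period_h Period `P > 0` in hours.
#' @param phase_h Peak time `phi` in hours.
#' @return Expected expression value(s).
#' @examples
#' planted_waveform(8, baseline = 2, amplitude = 1.5, period_h = 24,
#'                  phase_h = 8)  # peak: 2 * (1 + 1.5) = 5
#' @export
planted_waveform <- function(t_h, baseline, amplitude, period_h, phase_h) {
  if (baseline <= 0) stop("baseline must be positive")
  if (period_h <= 0) stop("period_h must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  baseline * (1 + (amplitude / 2) *
                (1 + cos(2 * pi * (t_h - phase_h) / period_h)))
}

# von Mises sampler (Best & Fisher 1979 rejection method); returns angles in
# radians around mu. kappa = 0 degenerates to uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out + mu
}

draw_phases <- function(n, period_h, phase_mode, phase_center_h, phase_kappa) {
  if (phase_mode == "uniform") {
    stats::runif(n, 0, period_h)
  } else if (phase_mode == "vonmises") {
    ang <- rvonmises(n, 2 * pi * phase_center_h / period_h, phase_kappa)
    (ang * period_h / (2 * pi)) %% period_h
  } else if (phase_mode == "fixed") {
    rep(phase_center_h %% period_h, n)
  } else stop("unknown phase_mode: ", phase_mode)
}

#' Generate a synthetic expression matrix with planted rhythms
#'
#' Each rhythmic transcript follows [planted_waveform()] at its sampled times;
#' arrhythmic transcripts sit at their baseline. Noise is multiplicative
#' lognormal by default (`value = expectation * exp(rnorm(0, sigma))`), the
#' natural model for normalized expression consumed by a rank-based test; a
#' negative-binomial mode (`noise_model = "nb"`, with `dispersion`) is
#' available for count-level realism.
#'
#' @param design Sample table from [ts_design()].
#' @param classes A `data.frame` describing transcript classes, one row per
#'   class, with columns: `n` (number of transcripts), `period_h` (one of
#'   12/16/20/24, or `NA` for arrhythmic), `amplitude`, `baseline`, and
#'   optionally `phase_mode` (`"uniform"`, `"vonmises"`, `"fixed"`; default
#'   uniform), `phase_center_h`, `phase_kappa`.
#' @param noise_sigma Lognormal sigma (log scale) of the multiplicative noise.
#' @param noise_model `"lognormal"` (default) or `"nb"`.
#' @param dispersion Negative-binomial dispersion (1/size) when
#'   `noise_model = "nb"`.
#' @param seed Integer seed; the output is fully determined by it.
#' @param prefix Transcript id prefix.
#' @return A list of class `sim_data`: `matrix` (transcripts x samples),
#'   `samples` (the design), and `truth` (`data.frame` with `transcript_id`,
#'   `rhythmic`, `period_h`, `phase_h`, `amplitude`, `baseline`,
#'   `noise_sigma`), rows aligned 1:1 with the matrix.
#' @export
generate_matrix <- function(design, classes, noise_sigma = 0.2,
                            noise_model = c("lognormal", "nb"),
                            dispersion = 0.1, seed = 1L, prefix = "tx") {
  noise_model <- match.arg(noise_model)
  validate_samples(design)
  if (!is.data.frame(classes) || nrow(classes) == 0 || sum(classes$n) == 0)
    stop("classes must request at least one transcript")
  if (!all(is.na(classes$period_h) |
           classes$period_h %in% c(12, 16, 20, 24)))
    stop("period_h must be NA or one of 12, 16, 20, 24")
  set.seed(seed)
  n_tot <- sum(classes$n)
  ids <- sprintf("%s%05d", prefix, seq_len(n_tot))
  truth <- data.frame(transcript_id = ids, rhythmic = FALSE,
                      period_h = NA_real_, phase_h = NA_real_,
                      amplitude = NA_real_, baseline = NA_real_,
                      noise_sigma = noise_sigma, stringsAsFactors = FALSE)
  row0 <- 0L
  mat <- matrix(NA_real_, nrow = n_tot, ncol = nrow(design),
                dimnames = list(ids, design$sample_id))
  for (ci in seq_len(nrow(classes))) {
    cl <- classes[ci, ]
    idx <- row0 + seq_len(cl$n)
    row0 <- row0 + cl$n
    if (cl$n == 0) next
    b <- rep(cl$baseline, cl$n)
    truth$baseline[idx] <- b
    if (!is.na(cl$period_h)) {
      pm <- if (!is.null(cl$phase_mode) && !is.na(cl$phase_mode))
        cl$phase_mode else "uniform"
      pc <- if (!is.null(cl$phase_center_h) && !is.na(cl$phase_center_h))
        cl$phase_center_h else 0
      pk <- if (!is.null(cl$phase_kappa) && !is.na(cl$phase_kappa))
        cl$phase_kappa else 2
      ph <- draw_phases(cl$n, cl$period_h, pm, pc, pk)
      truth$rhythmic[idx] <- TRUE
      truth$period_h[idx] <- cl$period_h
      truth$phase_h[idx] <- ph
      truth$amplitude[idx] <- cl$amplitude
      expect <- outer(seq_len(cl$n), design$time_h, function(i, t)
        planted_waveform(t, cl$baseline, cl$amplitude, cl$period_h, ph[i]))
    } else {
      expect <- matrix(cl$baseline, nrow = cl$n, ncol = nrow(design))
    }
    if (noise_model == "lognormal") {
      eps <- if (noise_sigma > 0)
        exp(matrix(stats::rnorm(length(expect), 0, noise_sigma),
                   nrow = cl$n)) else 1
      mat[idx, ] <- expect * eps
    } else {
      mat[idx, ] <- matrix(
        stats::rnbinom(length(expect), mu = expect, size = 1 / dispersion),
        nrow = cl$n)
    }
  }
  structure(list(matrix = mat, samples = design, truth = truth),
            class = c("sim_data", "expr_data"))
}

#' Default class table mirroring a daily-dominated rhythmic transcriptome
#'
#' A desk-scale default (1,000 transcripts) with planted rhythms at all four
#' tested periods, amplitude 2 and baseline 100, on a 900-transcript
#' arrhythmic background.
#'
#' @param n_total Total transcripts (rhythmic classes are scaled
#'   proportionally; default 1000).
#' @return A `classes` data.frame for [generate_matrix()].
#' @export
default_classes <- function(n_total = 1000) {
  frac <- c(p24 = 0.05, p20 = 0.02, p16 = 0.02, p12 = 0.01)
  n <- round(n_total * frac)
  data.frame(
    n = c(n, n_total - sum(n)),
    period_h = c(24, 20, 16, 12, NA),
    amplitude = c(2, 2, 2, 2, NA),
    baseline = 100,
    phase_mode = "uniform",
    stringsAsFactors = FALSE
  )
}

#' Two-station scenario with a planted cross-station architecture
#'
#' Generates paired matrices emulating the South/North comparison: transcripts
#' rhythmic exclusively at station A, exclusively at B, at both with the same
#' period range, at both with a period-range switch, plus a shared arrhythmic
#' background. Category counts in the truth table are exactly as configured.
#'
#' @param counts Named list/vector of category sizes: `excl_A`, `excl_B`,
#'   `both_same_daily`, `both_same_ultradian`, `switch_daily_to_ultradian`,
#'   `switch_ultradian_to_daily`, `nonrhythmic`.
#' @param design_A,design_B Sample tables for the two stations (defaults: the
#'   study design, South clock start 14 h, North 10 h).
#' @param amplitude,baseline,noise_sigma Waveform parameters shared by all
#'   planted transcripts.
#' @param seed Integer seed.
#' @return A list of class `two_station_sim`: `A` and `B` (each a `sim_data`)
#'   and `truth` (per-transcript `category`, `period_A`, `period_B`).
#' @export
two_station_scenario <- function(
    counts = list(excl_A = 60, excl_B = 40, both_same_daily = 40,
                  both_same_ultradian = 20, switch_daily_to_ultradian = 25,
                  switch_ultradian_to_daily = 15, nonrhythmic = 800),
    design_A = ts_design(station = "South", clock_start = 14),
    design_B = ts_design(station = "North", clock_start = 10),
    amplitude = 2, baseline = 100, noise_sigma = 0.1, seed = 1L) {
  cats <- c("excl_A", "excl_B", "both_same_daily", "both_same_ultradian",
            "switch_daily_to_ultradian", "switch_ultradian_to_daily",
            "nonrhythmic")
  cnt <- vapply(cats, function(k)
    if (is.null(counts[[k]])) 0L else as.integer(counts[[k]]), integer(1))
  if (any(cnt < 0) || sum(cnt) == 0) stop("invalid category counts")
  set.seed(seed)
  n_tot <- sum(cnt)
  category <- rep(cats, cnt)
  # daily plants use 24 h, ultradian 12 h; excl_* alternate daily/ultradian
  pick <- function(range) ifelse(range == "daily", 24, 12)
  period_A <- rep(NA_real_, n_tot); period_B <- rep(NA_real_, n_tot)
  is_daily_excl <- stats::runif(n_tot) < 0.7   # daily-dominated architecture
  period_A[category == "excl_A"] <-
    pick(ifelse(is_daily_excl[category == "excl_A"], "daily", "ultradian"))
  period_B[category == "excl_B"] <-
    pick(ifelse(is_daily_excl[category == "excl_B"], "ultradian", "daily"))
  period_A[category == "both_same_daily"] <- 24
  period_B[category == "both_same_daily"] <- 24
  period_A[category == "both_same_ultradian"] <- 12
  period_B[category == "both_same_ultradian"] <- 12
  period_A[category == "switch_daily_to_ultradian"] <- 24
  period_B[category == "switch_daily_to_ultradian"] <- 12
  period_A[category == "switch_ultradian_to_daily"] <- 12
  period_B[category == "switch_ultradian_to_daily"] <- 24
  build <- function(design, periods, seed_st) {
    ord <- order(periods, na.last = TRUE)  # group into class blocks
    classes <- do.call(rbind, lapply(
      unique(periods[ord]), function(p) data.frame(
        n = sum(if (is.na(p)) is.na(periods) else
          !is.na(periods) & periods == p),
        period_h = p, amplitude = if (is.na(p)) NA else amplitude,
        baseline = baseline, phase_mode = "uniform",
        stringsAsFactors = FALSE)))
    sim <- generate_matrix(design, classes, noise_sigma = noise_sigma,
                           seed = seed_st, prefix = "tx")
    # generate_matrix lays transcripts out class-by-class; map back to the
    # scenario's transcript order
    sim$matrix <- sim$matrix[order(ord), , drop = FALSE]
    sim$truth <- sim$truth[order(ord), , drop = FALSE]
    ids <- sprintf("tx%05d", seq_len(n_tot))
    rownames(sim$matrix) <- ids
    sim$truth$transcript_id <- ids
    rownames(sim$truth) <- NULL
    sim
  }
  seeds <- stats::runif(2, 1, 2^30)
  sim_A <- build(design_A, period_A, as.integer(seeds[1]))
  sim_B <- build(design_B, period_B, as.integer(seeds[2]))
  truth <- data.frame(transcript_id = sim_A$truth$transcript_id,
                      category = category, period_A = period_A,
                      period_B = period_B, stringsAsFactors = FALSE)
  structure(list(A = sim_A, B = sim_B, truth = truth),
            class = "two_station_sim")
}

#' Write simulated data to TSV files
#'
#' Emits `<prefix>matrix.tsv`, `<prefix>samples.tsv`, `<prefix>truth.tsv`.
#'
#' @param sim A `sim_data` object from [generate_matrix()].
#' @param out_prefix Path prefix (directory must exist).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, out_prefix) {
  paths <- paste0(out_prefix, c("matrix.tsv", "samples.tsv", "truth.tsv"))
  write_expression(sim$matrix, paths[1], paths[2], samples = sim$samples)
  tr <- sim$truth
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], format_num12)
  write_tsv(tr, paths[3])
  invisible(paths)
}
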