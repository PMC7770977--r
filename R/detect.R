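#' Fold a sampling design at a candidate period
#'
#' Groups samples by their cycle position `time_h mod period_h` (positions
#' equal after rounding to one minute fold together). On the default design
#' (0..24 h by 4 h), the 24 h fold yields 6 groups with the t = 0 and t = 24 h
#' samplings folded together.
#'
#' @param design Sample table (see [ts_design()]).
#' @param period_h Candidate period in hours (> 0).
#' @return A list of class `cycle_fold`: `period_h`, `positions` (strictly
#'   increasing cycle positions in `[0, period)`), `groups` (sample-index
#'   lists per position), `sizes`, `m`, `clock_h` (local clock hour of the
#'   earliest sampling time at each position), plus precomputed `patterns`,
#'   `pairlists` and normal-approximation `moments` for [umbrella_test()].
#' @export
fold_timepoints <- function(design, period_h) {
  if (period_h <= 0) stop("period_h must be positive")
  validate_samples(design)
  pos <- round((design$time_h %% period_h) * 60) / 60
  positions <- sort(unique(pos))
  if (length(positions) < 3)
    stop(sprintf("period %gh untestable on this grid (fewer than 3 distinct cycle positions)",
                 period_h))
  groups <- lapply(positions, function(p) which(pos == p))
  sizes <- lengths(groups)
  clock_h <- vapply(positions, function(p)
    design$clock_local[which.min(ifelse(pos == p, design$time_h, Inf))],
    numeric(1))
  m <- length(positions)
  pats <- umbrella_patterns(m)
  pairlists <- lapply(seq_len(nrow(pats)), function(k)
    pattern_pairs(m, pats$peak[k], pats$r[k]))
  moments <- lapply(pairlists, function(prs)
    pattern_moment_weights(sizes, prs))
  structure(list(period_h = period_h, positions = positions, groups = groups,
                 sizes = sizes, m = m, clock_h = clock_h, patterns = pats,
                 pairlists = pairlists, moments = moments),
            class = "cycle_fold")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (with the usual monotonicity enforcement), as a
#' validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same order; `adj_p >= p` elementwise.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

period_range_of <- function(period_h) {
  ifelse(period_h %in% c(20, 24), "daily",
         ifelse(period_h %in% c(12, 16), "ultradian", NA_character_))
}

#' Detect rhythmic transcripts at a set of candidate periods
#'
#' The central fitting function. For every transcript and every candidate
#' period, the samples are folded at that period and scored with the
#' rank-based umbrella test ([umbrella_test()]); Benjamini-Hochberg adjustment
#' is applied jointly across the full transcript x period p-value vector;
#' each transcript is then assigned its most significant period (minimum
#' adjusted p; exact ties broken toward the longer period) and classified as
#' `daily` (20 or 24 h) or `ultradian` (12 or 16 h).
#'
#' @param x An `expr_data`/`sim_data` object, or a numeric matrix
#'   (transcripts x samples) with `samples` given separately.
#' @param samples Sample table when `x` is a bare matrix. Must describe a
#'   single station.
#' @param periods Candidate periods in hours, a subset of {12, 16, 20, 24}.
#' @param alphas Significance cutoffs on the adjusted p-values (default
#'   0.001, 0.01, 0.05).
#' @param normalize `"none"` (default) or `"cpm"` (counts-per-million library
#'   scaling before testing).
#' @param exact_n,exact_cap Exact permutation-null limits, see [pattern_p()].
#' @param verbose Log progress to stderr.
#' @return An object of class `rhythm_scan`; see Details. Its `results`
#'   data.frame has per-period `raw_p_<P>`/`adj_p_<P>` columns, the assigned
#'   period and adjusted p, the period-range class, and placeholders for the
#'   characterization columns filled by [characterize()].
#' @examples
#' sim <- generate_matrix(ts_design(), default_classes(60), seed = 1)
#' scan <- detect_rhythms(sim, periods = c(24, 12))
#' summary(scan)
#' @export
detect_rhythms <- function(x, samples = NULL, periods = c(24, 20, 16, 12),
                           alphas = c(0.001, 0.01, 0.05),
                           normalize = c("none", "cpm"),
                           exact_n = 12, exact_cap = 2e5, verbose = FALSE) {
  normalize <- match.arg(normalize)
  if (inherits(x, "expr_data")) {
    mat <- x$matrix; samples <- x$samples
  } else {
    mat <- as.matrix(x)
    if (is.null(samples)) stop("samples table required")
  }
  validate_samples(samples)
  if (length(unique(samples$station)) != 1)
    stop("detect_rhythms analyses one station at a time")
  if (!all(periods %in% c(12, 16, 20, 24)))
    stop("periods must be a subset of {12, 16, 20, 24}")
  if (ncol(mat) != nrow(samples)) stop("matrix/samples dimension mismatch")
  periods <- sort(unique(periods), decreasing = TRUE)
  alphas <- sort(alphas)
  if (normalize == "cpm") {
    libsize <- colSums(mat)
    if (any(libsize <= 0)) stop("cpm normalization needs positive column sums")
    mat <- sweep(mat, 2, libsize, "/") * 1e6
  }
  span <- max(samples$time_h) - min(samples$time_h)
  if (span < max(periods))
    warning("design span shorter than the longest tested period")
  folds <- lapply(periods, function(p) fold_timepoints(samples, p))
  names(folds) <- as.character(periods)
  n <- nrow(mat)
  rawp <- matrix(NA_real_, n, length(periods))
  bestpk <- matrix(NA_integer_, n, length(periods))
  bestr <- matrix(NA_integer_, n, length(periods))
  for (j in seq_along(periods)) {
    if (verbose)
      log_stage("detect", "period %gh: %d transcripts", periods[j], n)
    for (i in seq_len(n)) {
      ut <- umbrella_test(mat[i, ], folds[[j]],
                          exact_n = exact_n, exact_cap = exact_cap)
      rawp[i, j] <- ut$raw_p
      bestpk[i, j] <- ut$best_pattern$peak
      bestr[i, j] <- ut$best_pattern$r
    }
  }
  adjp <- matrix(bh_adjust(as.vector(rawp)), n, length(periods))
  # assignment: min adjusted p; exact ties toward the longer period (periods
  # are sorted decreasing, so the first minimum wins)
  assigned_idx <- apply(adjp, 1, which.min)
  assigned_period <- periods[assigned_idx]
  assigned_adj <- adjp[cbind(seq_len(n), assigned_idx)]
  res <- data.frame(transcript_id = rownames(mat) %||%
                      sprintf("row%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_along(periods)) {
    res[[paste0("raw_p_", periods[j])]] <- rawp[, j]
    res[[paste0("adj_p_", periods[j])]] <- adjp[, j]
  }
  res$assigned_period_h <- assigned_period
  res$assigned_adj_p <- assigned_adj
  res$period_range <- period_range_of(assigned_period)
  res$phase_h <- NA_real_
  res$amplitude <- NA_real_
  res$amplitude_bin <- NA_character_
  res$coincidence_label <- NA_character_
  best <- data.frame(transcript_id = res$transcript_id,
                     stringsAsFactors = FALSE)
  for (j in seq_along(periods)) {
    best[[paste0("peak_", periods[j])]] <- bestpk[, j]
    best[[paste0("r_", periods[j])]] <- bestr[, j]
  }
  structure(list(results = res, periods = periods, alphas = alphas,
                 samples = samples, folds = folds, best_patterns = best,
                 n_transcripts = n, normalize = normalize),
            class = "rhythm_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cutoffs at which each transcript's assignment is significant
#'
#' @param scan A `rhythm_scan`.
#' @return A list (one element per transcript) of the alpha cutoffs passed.
#' @export
significant_at <- function(scan) {
  lapply(scan$results$assigned_adj_p, function(p)
    scan$alphas[p < scan$alphas])
}

#' @export
print.rhythm_scan <- function(x, ...) {
  cat(sprintf("rhythm_scan: %d transcripts, station %s, periods %s h\n",
              x$n_transcripts, unique(x$samples$station),
              paste(x$periods, collapse = "/")))
  for (a in x$alphas)
    cat(sprintf("  rhythmic at adj-p < %g: %d (%.1f%%)\n", a,
                sum(x$results$assigned_adj_p < a),
                100 * mean(x$results$assigned_adj_p < a)))
  invisible(x)
}

#' @export
summary.rhythm_scan <- function(object, n_total = object$n_transcripts, ...) {
  cutoff_summary(object, alphas = object$alphas, n_total = n_total)
}

#' @export
plot.rhythm_scan <- function(x, period_range = c("daily", "ultradian"), ...) {
  ph <- x$results$phase_h
  if (all(is.na(ph))) {
    graphics::hist(x$results$assigned_adj_p, breaks = 20,
                   main = "Assigned adjusted p-values", xlab = "adjusted p")
  } else {
    period_range <- match.arg(period_range)
    keep <- !is.na(ph) & x$results$period_range == period_range
    graphics::hist(ph[keep], breaks = seq(0, 24, by = 2),
                   main = sprintf("Peak phases (%s)", period_range),
                   xlab = "phase (h in cycle)")
  }
  invisible(x)
}

#' @export
as.data.frame.rhythm_scan <- function(x, ...) x$results
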