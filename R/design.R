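#' Build a one-day sampling design
#'
#' Constructs the sample table for a single station sampled repeatedly over
#' one day: a grid of sampling times (hours since the first sample) crossed
#' with biological replicates (pools of animals, so each time x replicate is an
#' independent cross-sectional sample, not a longitudinal series).
#'
#' Times are stored twice: `time_h` (hours since the first sample, used for
#' period folding) and `clock_local` (local clock hour, UTC+2 convention, used
#' to report phases against solar and tidal cycles).
#'
#' @param timepoints_h Numeric vector of sampling times in hours since the
#'   first sample. Default `seq(0, 24, by = 4)`: seven samplings at 4 h
#'   intervals covering a full 24 h cycle.
#' @param replicates Number of replicate pools per sampling time (default 3).
#' @param station Station label, e.g. `"South"` or `"North"`.
#' @param clock_start Local clock hour (0-24) of the first sampling.
#' @return A `data.frame` of sample records with columns `sample_id`,
#'   `station`, `time_h`, `clock_local`, `replicate`.
#' @examples
#' d <- ts_design(station = "South", clock_start = 14)
#' nrow(d)  # 7 timepoints x 3 replicates = 21
#' @export
ts_design <- function(timepoints_h = seq(0, 24, by = 4), replicates = 3L,
                      station = "S", clock_start = 0) {
  if (length(timepoints_h) < 3L || any(diff(timepoints_h) <= 0))
    stop("timepoints_h must be strictly increasing with at least 3 values")
  if (any(timepoints_h < 0)) stop("timepoints_h must be non-negative")
  if (replicates < 1L) stop("replicates must be a positive integer")
  df <- expand.grid(replicate = seq_len(replicates), time_h = timepoints_h,
                    KEEP.OUT.ATTRS = FALSE)
  df <- df[order(df$time_h, df$replicate), , drop = FALSE]
  out <- data.frame(
    sample_id = sprintf("%s_t%02g_r%d", station, df$time_h, df$replicate),
    station = station,
    time_h = df$time_h,
    clock_local = (clock_start + df$time_h) %% 24,
    replicate = as.integer(df$replicate),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_samples(out)
  out
}

#' Validate a sample table
#'
#' Checks the invariants of the sample-record contract: required columns,
#' non-negative times, clock hours in `[0, 24)`, positive integer replicates,
#' and uniqueness of (station, time_h, replicate).
#'
#' @param samples A sample `data.frame` as produced by [ts_design()] or read
#'   from a samples TSV.
#' @return The validated table, invisibly.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "station", "time_h", "clock_local", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples table")
  if (any(!is.finite(samples$time_h)) || any(samples$time_h < 0))
    stop("time_h must be finite and non-negative")
  if (any(samples$clock_local < 0 | samples$clock_local >= 24))
    stop("clock_local must lie in [0, 24)")
  if (any(samples$replicate < 1) ||
      any(samples$replicate != round(samples$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(samples$station, samples$time_h, samples$replicate)
  if (anyDuplicated(key))
    stop("(station, time_h, replicate) must be unique")
  invisible(samples)
}
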