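# Tabular IO. One dialect everywhere: TSV, UTF-8, Unix newlines, no quoting,
# '.' decimal separator. Results files carry '#' comment headers with the run
# configuration; readers skip them.

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is a TSV whose header row names the samples and whose first
#' column (`transcript_id`) names the transcripts; all values must be
#' non-negative finite reals. The samples file must annotate every matrix
#' column (see [validate_samples()] for the required columns).
#'
#' @param matrix_path Path to the expression TSV.
#' @param samples_path Path to the sample-annotation TSV.
#' @return An object of class `expr_data`: a list with `matrix` (numeric
#'   matrix, transcripts x samples, rownames = transcript ids) and `samples`
#'   (annotation `data.frame` in matrix column order).
#' @export
read_expression <- function(matrix_path, samples_path) {
  mat_df <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                              check.names = FALSE, comment.char = "#",
                              stringsAsFactors = FALSE)
  if (names(mat_df)[1] != "transcript_id")
    stop("first column of the matrix file must be 'transcript_id'")
  ids <- as.character(mat_df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate transcript_id: ", paste(unique(dup), collapse = ", "))
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid expression value at transcript '%s', sample '%s' (must be a non-negative finite real)",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  samples <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                               check.names = FALSE, comment.char = "#",
                               stringsAsFactors = FALSE)
  validate_samples(samples)
  unann <- setdiff(colnames(mat), samples$sample_id)
  if (length(unann))
    stop("unannotated sample ", paste(unann, collapse = ", "))
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(matrix = mat, samples = samples), class = "expr_data")
}

#' @export
print.expr_data <- function(x, ...) {
  cat(sprintf("expr_data: %d transcripts x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  for (st in unique(x$samples$station)) {
    s <- x$samples[x$samples$station == st, ]
    cat(sprintf("  station %s: %d timepoints x up to %d replicates\n",
                st, length(unique(s$time_h)), max(s$replicate)))
  }
  invisible(x)
}

#' Write an expression matrix and samples table as TSV
#'
#' @param x An `expr_data` object, or a numeric matrix when `samples` is given
#'   separately.
#' @param matrix_path,samples_path Output paths.
#' @param samples Sample table (only when `x` is a bare matrix).
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(x, matrix_path, samples_path, samples = NULL) {
  if (inherits(x, "expr_data")) {
    mat <- x$matrix; samples <- x$samples
  } else {
    mat <- x
    if (is.null(samples)) stop("samples table required")
  }
  df <- data.frame(transcript_id = rownames(mat),
                   apply(mat, 2, format_num12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("transcript_id", colnames(mat))
  write_tsv(df, matrix_path)
  write_tsv(samples, samples_path)
  invisible(c(matrix_path, samples_path))
}

# 12 significant digits: lossless enough for round-trip identity checks while
# keeping files diffable.
format_num12 <- function(x) {
  out <- sprintf("%.12g", as.numeric(x))
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wb")  # "wb": Unix newlines on every platform
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

#' Canonical column order of a results table
#'
#' `transcript_id`, then `raw_p_<P>` and `adj_p_<P>` for each tested period in
#' the scan's period order, then the assignment and characterization columns.
#'
#' @param periods Tested periods in hours.
#' @return Character vector of column names.
#' @export
results_columns <- function(periods) {
  c("transcript_id",
    as.vector(rbind(paste0("raw_p_", periods), paste0("adj_p_", periods))),
    "assigned_period_h", "assigned_adj_p", "period_range",
    "phase_h", "amplitude", "amplitude_bin", "coincidence_label")
}

#' Write a rhythm-results table
#'
#' Writes the canonical results TSV (see [results_columns()]). Numeric values
#' are written with 12 significant digits, so [read_results()] round-trips the
#' table losslessly at that precision. A `#` comment header records the tested
#' periods and any extra configuration notes.
#'
#' @param results A `rhythm_scan` object or its results `data.frame`.
#' @param path Output path.
#' @param notes Optional character vector of extra comment-header lines.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, notes = character()) {
  if (inherits(results, "rhythm_scan")) {
    periods <- results$periods
    df <- results$results
  } else {
    df <- results
    pcols <- grep("^raw_p_", names(df), value = TRUE)
    periods <- as.numeric(sub("^raw_p_", "", pcols))
  }
  cols <- results_columns(periods)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
  df <- df[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_num12)
  comments <- c(sprintf("polarhythm results; periods_h=%s",
                        paste(periods, collapse = ",")), notes)
  write_tsv(df, path, comments = comments)
  invisible(path)
}

#' Read back a rhythm-results table
#'
#' @param path Path to a TSV written by [write_results()].
#' @return A `data.frame` with numeric p-value/phase/amplitude columns and
#'   character label columns.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  chr <- c("transcript_id", "period_range", "amplitude_bin",
           "coincidence_label")
  for (cl in setdiff(names(df), chr)) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read a flat gene-to-term annotation table
#'
#' Two-column TSV `gene_id <tab> term_id`, one row per membership.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` with columns `gene_id`, `term_id`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation must have columns gene_id, term_id")
  df[, c("gene_id", "term_id")]
}

#' Read tidal harmonic constituents from YAML
#'
#' Expected schema: a top-level `z0_m` (datum offset, metres; default 0) and a
#' `constituents` list of `{name, period_h, amplitude_m, phase_rad}` entries.
#'
#' @param path Path to the YAML file.
#' @return A list with `z0_m` and a constituents `data.frame`.
#' @export
read_constituents <- function(path) {
  y <- yaml::read_yaml(path)
  cons <- do.call(rbind, lapply(y$constituents, function(cc) {
    data.frame(name = cc$name, period_h = cc$period_h,
               amplitude_m = cc$amplitude_m, phase_rad = cc$phase_rad,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cons) || nrow(cons) < 1) stop("at least one constituent required")
  if (any(cons$period_h <= 0)) stop("constituent period_h must be positive")
  list(z0_m = if (is.null(y$z0_m)) 0 else y$z0_m, constituents = cons)
}

#' Read a run configuration from YAML
#'
#' Fills defaults for missing fields and validates the invariants: tested
#' periods a subset of {12, 16, 20, 24}, alpha cutoffs strictly increasing in
#' (0, 1), non-negative pseudocount, positive coincidence tolerance.
#'
#' @param path Path to a YAML run configuration.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list(
    tested_periods_h = if (is.null(y$tested_periods_h)) c(24, 20, 16, 12)
                       else as.numeric(y$tested_periods_h),
    alpha_levels = if (is.null(y$alpha_levels)) c(0.001, 0.01, 0.05)
                   else as.numeric(y$alpha_levels),
    pseudocount = if (is.null(y$pseudocount)) 0 else as.numeric(y$pseudocount),
    coincidence_tolerance_h = if (is.null(y$coincidence_tolerance_h)) 2
                              else as.numeric(y$coincidence_tolerance_h),
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed)
  )
  if (!all(cfg$tested_periods_h %in% c(12, 16, 20, 24)))
    stop("tested_periods_h must be a subset of {12, 16, 20, 24}")
  a <- sort(cfg$alpha_levels)
  if (any(a <= 0) || any(a >= 1) || any(diff(a) <= 0))
    stop("alpha_levels must be distinct values in (0, 1)")
  cfg$alpha_levels <- a
  if (cfg$pseudocount < 0) stop("pseudocount must be non-negative")
  if (cfg$coincidence_tolerance_h <= 0)
    stop("coincidence_tolerance_h must be positive")
  class(cfg) <- "run_config"
  cfg
}

# stderr progress logging used by the pipeline stages
log_stage <- function(stage, ...) {
  message(sprintf("[polarhythm %s] %s", stage, sprintf(...)))
}
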