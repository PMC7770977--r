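# Cross-station rhythm-architecture comparison and the multi-cutoff count
# tables (per-period counts with percentages of the transcript universe).

#' Rhythm status of a transcript at a cutoff
#'
#' `daily` or `ultradian` (per the assigned period) when the assigned
#' adjusted p is below `alpha`, else `none`.
#'
#' @param assigned_adj_p Adjusted p-value(s) of the assignment.
#' @param period_range Period-range class(es) (`"daily"`/`"ultradian"`).
#' @param alpha Cutoff.
#' @return Character vector in `{none, daily, ultradian}`.
#' @export
rhythm_status <- function(assigned_adj_p, period_range, alpha) {
  ifelse(assigned_adj_p < alpha, period_range, "none")
}

#' Cross-station category of a transcript
#'
#' Pure function of the two station statuses: exclusive rhythmicity at either
#' station, shared rhythmicity with the same period range, a period-range
#' switch (in either direction), or no rhythmicity. The seven categories
#' partition all transcripts.
#'
#' @param status_A,status_B Statuses from [rhythm_status()].
#' @return Character vector of categories.
#' @export
categorize <- function(status_A, status_B) {
  ok <- c("none", "daily", "ultradian")
  if (!all(status_A %in% ok) || !all(status_B %in% ok))
    stop("statuses must be none/daily/ultradian")
  out <- character(length(status_A))
  out[status_A != "none" & status_B == "none"] <- "excl_A"
  out[status_A == "none" & status_B != "none"] <- "excl_B"
  out[status_A == "daily" & status_B == "daily"] <- "both_same_daily"
  out[status_A == "ultradian" & status_B == "ultradian"] <-
    "both_same_ultradian"
  out[status_A == "daily" & status_B == "ultradian"] <-
    "switch_daily_to_ultradian"
  out[status_A == "ultradian" & status_B == "daily"] <-
    "switch_ultradian_to_daily"
  out[status_A == "none" & status_B == "none"] <- "nonrhythmic"
  out
}

comparison_categories <- c("excl_A", "excl_B", "both_same_daily",
                           "both_same_ultradian", "switch_daily_to_ultradian",
                           "switch_ultradian_to_daily", "nonrhythmic")

#' Multi-cutoff summary table of a rhythm scan
#'
#' For each adjusted-p cutoff, the number (and percentage of the transcript
#' universe) of transcripts assigned to each period, the daily (24 + 20 h) and
#' ultradian (16 + 12 h) subtotals, and the all-rhythmic total. Each
#' transcript is counted once, at its assigned period.
#'
#' @param scan A `rhythm_scan` (or its results `data.frame`).
#' @param alphas Cutoffs (default: the scan's).
#' @param n_total Size of the transcript universe the percentages refer to
#'   (default: number of scanned transcripts).
#' @return A `data.frame` with one row per cutoff x column-group, columns
#'   `alpha`, `group` (period or subtotal), `count`, `percent`.
#' @export
cutoff_summary <- function(scan, alphas = NULL, n_total = NULL) {
  if (inherits(scan, "rhythm_scan")) {
    res <- scan$results
    if (is.null(alphas)) alphas <- scan$alphas
    periods <- scan$periods
  } else {
    res <- scan
    if (is.null(alphas)) alphas <- c(0.001, 0.01, 0.05)
    pcols <- grep("^raw_p_", names(res), value = TRUE)
    periods <- sort(as.numeric(sub("^raw_p_", "", pcols)), decreasing = TRUE)
  }
  if (is.null(n_total)) n_total <- nrow(res)
  if (n_total < nrow(res)) stop("n_total smaller than the results table")
  rows <- list()
  for (a in sort(alphas)) {
    sig <- res$assigned_adj_p < a
    cnt <- vapply(periods, function(p)
      sum(sig & res$assigned_period_h == p), numeric(1))
    daily <- sum(cnt[periods %in% c(20, 24)])
    ultra <- sum(cnt[periods %in% c(12, 16)])
    groups <- c(paste0(periods, "h"), "daily", "ultradian", "all_rhythmic")
    counts <- c(cnt, daily, ultra, daily + ultra)
    rows[[length(rows) + 1]] <- data.frame(
      alpha = a, group = groups, count = counts,
      percent = 100 * counts / n_total, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare rhythm architecture between two stations
#'
#' Joins two per-station scans over a common transcript universe, assigns
#' each transcript its cross-station category at the chosen cutoff, and
#' tabulates category counts. When a gene-to-set annotation is supplied, a
#' per-set breakdown is added: for each set, the four-way split (exclusive at
#' A / exclusive at B / both with the same range / both with a range switch),
#' each split by period range, with switching transcripts classified by their
#' range at station B.
#'
#' @param scan_A,scan_B `rhythm_scan` objects (or results data.frames) for
#'   the two stations, indexed by the same transcript universe.
#' @param alpha Adjusted-p cutoff (default 0.001).
#' @param annotation Optional `data.frame` with `gene_id`, `term_id`.
#' @return A list of class `station_comparison`: `records` (per-transcript
#'   `status_A`, `status_B`, `category`), `counts` (category count table),
#'   `set_breakdown` (or NULL), `alpha`.
#' @export
comparison_summary <- function(scan_A, scan_B, alpha = 0.001,
                               annotation = NULL) {
  res_A <- if (inherits(scan_A, "rhythm_scan")) scan_A$results else scan_A
  res_B <- if (inherits(scan_B, "rhythm_scan")) scan_B$results else scan_B
  sdiff <- length(setdiff(res_A$transcript_id, res_B$transcript_id)) +
    length(setdiff(res_B$transcript_id, res_A$transcript_id))
  if (sdiff > 0)
    stop(sprintf("transcript universes differ (symmetric difference: %d ids)",
                 sdiff))
  res_B <- res_B[match(res_A$transcript_id, res_B$transcript_id), ,
                 drop = FALSE]
  st_A <- rhythm_status(res_A$assigned_adj_p, res_A$period_range, alpha)
  st_B <- rhythm_status(res_B$assigned_adj_p, res_B$period_range, alpha)
  records <- data.frame(transcript_id = res_A$transcript_id,
                        status_A = st_A, status_B = st_B,
                        category = categorize(st_A, st_B),
                        stringsAsFactors = FALSE)
  counts <- vapply(comparison_categories, function(k)
    sum(records$category == k), numeric(1))
  set_breakdown <- NULL
  if (!is.null(annotation)) {
    ann <- annotation[annotation$gene_id %in% records$transcript_id, ,
                      drop = FALSE]
    rec <- records[match(ann$gene_id, records$transcript_id), ]
    cat4 <- ifelse(rec$category == "excl_A", "excl_A",
            ifelse(rec$category == "excl_B", "excl_B",
            ifelse(rec$category %in% c("both_same_daily",
                                       "both_same_ultradian"), "both_same",
            ifelse(rec$category %in% c("switch_daily_to_ultradian",
                                       "switch_ultradian_to_daily"),
                   "both_switch", NA_character_))))
    # range shown: at A for excl_A; at B for excl_B and switches (the
    # switching transcripts are displayed as expressed at station B);
    # both_same share one range
    range4 <- ifelse(cat4 == "excl_A", rec$status_A, rec$status_B)
    keep <- !is.na(cat4)
    tab <- table(set = ann$term_id[keep], category = cat4[keep],
                 period_range = range4[keep])
    set_breakdown <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(set_breakdown) <- c("set", "category", "period_range", "count")
  }
  structure(list(records = records, counts = counts,
                 set_breakdown = set_breakdown, alpha = alpha),
            class = "station_comparison")
}

#' @export
print.station_comparison <- function(x, ...) {
  cat(sprintf("station comparison at adj-p < %g (universe: %d)\n",
              x$alpha, nrow(x$records)))
  print(x$counts)
  invisible(x)
}

#' Write a station comparison as TSV
#'
#' Writes `<path>` with the per-transcript records and, alongside it,
#' `<path base>_summary.tsv` keyed by category (and by set when a breakdown
#' is present).
#'
#' @param cmp A `station_comparison`.
#' @param path Output path for the records table.
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(cmp, path) {
  write_tsv(cmp$records, path,
            comments = sprintf("polarhythm comparison; alpha=%g", cmp$alpha))
  spath <- sub("(\\.tsv)?$", "_summary.tsv", path)
  summ <- data.frame(category = names(cmp$counts),
                     count = as.numeric(cmp$counts),
                     stringsAsFactors = FALSE)
  if (!is.null(cmp$set_breakdown)) {
    sb <- cmp$set_breakdown
    summ <- rbind(summ,
                  data.frame(category = paste(sb$set, sb$category,
                                              sb$period_range, sep = "|"),
                             count = sb$count, stringsAsFactors = FALSE))
  }
  write_tsv(summ, spath,
            comments = sprintf("polarhythm comparison summary; alpha=%g",
                               cmp$alpha))
  invisible(c(path, spath))
}
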