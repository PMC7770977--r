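# Flat over-representation analysis: one-sided hypergeometric tests per term
# with Benjamini-Hochberg adjustment across terms. Term sets are flat (no
# ontology propagation); the universe is the set of transcripts tested for
# rhythmicity.

#' Upper tail of the hypergeometric distribution
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are selected from a universe
#' of `N` containing `K` annotated ones.
#'
#' @param k Observed overlap (selected and annotated).
#' @param K Term size within the universe.
#' @param n Selection size.
#' @param N Universe size.
#' @return Exact tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene selection
#'
#' Tests every term with at least `min_term_size` genes in the universe for
#' over-representation in the selection, with BH adjustment across terms.
#'
#' @param selected_ids Character vector of selected gene ids (must be a
#'   subset of the universe; empty selection is an error).
#' @param annotation `data.frame` with `gene_id`, `term_id` memberships.
#' @param universe_ids Character vector: the tested universe.
#' @param min_term_size Smallest term size tested (default 5).
#' @return A `data.frame` sorted by adjusted p with columns `term_id`, `k`,
#'   `K`, `n`, `N`, `odds_ratio`, `p`, `adj_p`.
#' @export
ora <- function(selected_ids, annotation, universe_ids, min_term_size = 5) {
  selected_ids <- unique(as.character(selected_ids))
  universe_ids <- unique(as.character(universe_ids))
  if (length(selected_ids) == 0) stop("empty selection")
  off <- setdiff(selected_ids, universe_ids)
  if (length(off))
    stop("selected ids outside the universe: ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) sprintf(" (and %d more)", length(off) - 5))
  ann <- unique(annotation[annotation$gene_id %in% universe_ids,
                           c("gene_id", "term_id")])
  ann <- ann[order(ann$term_id, ann$gene_id), , drop = FALSE]
  N <- length(universe_ids)
  n <- length(selected_ids)
  terms <- sort(unique(ann$term_id))
  rows <- lapply(terms, function(tm) {
    genes <- ann$gene_id[ann$term_id == tm]
    K <- length(genes)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(genes, selected_ids))
    orat <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(term_id = tm, k = k, K = K, n = n, N = N,
               odds_ratio = orat, p = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term_id = character(0), k = numeric(0), K = numeric(0),
                      n = numeric(0), N = numeric(0), odds_ratio = numeric(0),
                      p = numeric(0), adj_p = numeric(0)))
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$adj_p, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param enr Result of [ora()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(enr, path) {
  df <- enr
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_num12)
  write_tsv(df, path, comments = "polarhythm enrichment")
  invisible(path)
}
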