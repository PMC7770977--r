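# Independent oracles used by the tests. These deliberately re-derive
# quantities from first principles, by different algorithms than the package
# (brute-force enumeration, log-factorial summation), so agreement is a real
# cross-check and not a tautology.

# Brute-force permutation p-value of the umbrella JT statistic: enumerate
# every distinct assignment of the pooled values to the group sizes by
# walking all index partitions, computing U directly from its definition
# (double loop over the rise/fall chains).
oracle_u <- function(groups, peak, r) {
  m <- length(groups)
  trough <- (peak - r) %% m
  rise <- ((trough + 0:r) %% m) + 1
  fall <- ((peak + 0:(m - r - 1)) %% m) + 1
  count_pair <- function(lo, hi) {
    cmp <- outer(lo, hi, "<") + 0.5 * outer(lo, hi, "==")
    sum(cmp)
  }
  u <- 0
  for (i in seq_along(rise)) for (j in seq_along(rise)) if (i < j)
    u <- u + count_pair(groups[[rise[i]]], groups[[rise[j]]])
  for (i in seq_along(fall)) for (j in seq_along(fall)) if (i < j)
    u <- u + count_pair(groups[[fall[j]]], groups[[fall[i]]])
  u
}

oracle_pattern_p <- function(groups, peak, r) {
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  u_obs <- oracle_u(groups, peak, r)
  hits <- 0; total <- 0
  recurse <- function(remaining, assigned) {
    g <- length(assigned) + 1
    if (g == length(sizes)) {
      gl <- c(assigned, list(remaining))
      gl <- lapply(gl, function(ix) values[ix])
      u <- oracle_u(gl, peak, r)
      total <<- total + 1
      if (u >= u_obs - 1e-9) hits <<- hits + 1
      return(invisible(NULL))
    }
    for (cb in utils::combn(remaining, sizes[g], simplify = FALSE))
      recurse(setdiff(remaining, cb), c(assigned, list(cb)))
  }
  recurse(seq_along(values), list())
  hits / total
}

# Exact hypergeometric upper tail by explicit log-binomial pmf summation.
oracle_hyper_tail <- function(k, K, n, N) {
  lo <- k:min(K, n)
  sum(exp(lchoose(K, lo) + lchoose(N - K, n - lo) - lchoose(N, n)))
}

# Small helper: a toy expression matrix + samples written to temp files.
write_toy_expression <- function(mat, samples,
                                 dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  sp <- file.path(dir, "samples.tsv")
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(samples, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, samples = sp)
}
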