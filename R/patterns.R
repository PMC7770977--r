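# Rank-based rhythm testing. A candidate period folds the samples into m
# cycle-position groups; the alternative hypotheses are cyclic umbrella
# orderings (rise to a peak, fall back), scored with Jonckheere-Terpstra
# statistics. The null is the permutation distribution of the pooled values
# over the group sizes: exact by full enumeration on small designs, otherwise
# a normal approximation whose mean and variance are computed exactly from
# the pooled tie structure (so the approximation is "tie-corrected" by
# construction).

#' Enumerate cyclic umbrella patterns
#'
#' A pattern is a peak position (0-based cycle-group index) plus a rise length
#' `r` in `1..m-1`: expression rises over `r` steps up to the peak, then falls
#' over the remaining `m - r` steps, wrapped around the cycle. There are
#' `m * (m - 1)` patterns for `m` groups.
#'
#' @param m Number of cycle-position groups (>= 2).
#' @return A `data.frame` with columns `peak` and `r`, ordered by peak then r
#'   (the tie-break order used by [umbrella_test()]).
#' @export
umbrella_patterns <- function(m) {
  if (m < 2) stop("need at least 2 groups")
  data.frame(peak = rep(0:(m - 1), each = m - 1),
             r = rep(seq_len(m - 1), m))
}

# Ordered group pairs (1-based) implied by a pattern: (a, b) means the
# alternative expects values in group a below values in group b, so the pair
# contributes #{x in a < y in b} + ties/2 to the statistic. Rise chain:
# trough..peak; fall chain: peak..(trough-1), orientation reversed.
pattern_pairs <- function(m, peak, r) {
  if (peak < 0 || peak >= m) stop("peak must be in 0..m-1")
  if (r < 1 || r >= m) stop("r must be in 1..m-1")
  trough <- (peak - r) %% m
  rise <- ((trough + 0:r) %% m) + 1L
  fall <- ((peak + 0:(m - r - 1)) %% m) + 1L
  pr <- list()
  k <- 1L
  n_r <- length(rise)
  for (i in seq_len(n_r - 1)) for (j in (i + 1):n_r) {
    pr[[k]] <- c(rise[i], rise[j]); k <- k + 1L
  }
  n_f <- length(fall)
  if (n_f >= 2) for (i in seq_len(n_f - 1)) for (j in (i + 1):n_f) {
    pr[[k]] <- c(fall[j], fall[i]); k <- k + 1L
  }
  do.call(rbind, pr)
}

# Mann-Whitney-type count for one ordered group pair, with the half-tie
# convention: U_ab = #{x in a < y in b} + 0.5 * #{x == y}.
pair_u <- function(xa, xb) {
  sum(outer(xa, xb, "<")) + 0.5 * sum(outer(xa, xb, "=="))
}

#' Jonckheere-Terpstra statistic along an umbrella pattern
#'
#' Sums Mann-Whitney counts (with the half-tie convention) over all group
#' pairs within the pattern's rise chain, plus all pairs within the fall
#' chain with reversed orientation.
#'
#' @param groups List of numeric vectors, one per cycle-position group (in
#'   cycle order), all non-empty.
#' @param pattern A list/row with elements `peak` (0-based) and `r`.
#' @return The statistic `U` (integer, or half-integer under ties).
#' @examples
#' jt_statistic(list(c(1, 2), c(3, 4)), list(peak = 1, r = 1))  # 4
#' @export
jt_statistic <- function(groups, pattern) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  prs <- pattern_pairs(length(groups), pattern$peak, pattern$r)
  sum(apply(prs, 1, function(p) pair_u(groups[[p[1]]], groups[[p[2]]])))
}

# ---- exact permutation moments (arbitrary tie structure) -------------------
#
# U = sum over pattern pairs (a,b) of U_ab. Under random assignment of the
# pooled values to the groups, E[U] and Var[U] follow from pair-overlap
# combinatorics. Writing a(u,v) = 1/0.5/0 for value u below/tied/above value
# v, the only value-dependent quantities are six aggregate sums over index
# pairs/triples/quadruples (A2, AB, C1, C2, C3, Q below); their weights
# depend only on the group sizes and the pattern, so they are precomputed
# once per fold.

# Aggregates of the pooled values' tie structure.
value_aggregates <- function(v) {
  n <- length(v)
  tab <- table(v)
  tu <- as.numeric(tab[match(as.character(v), names(tab))])  # multiplicity
  r <- rank(v)                 # midranks
  E <- tu - 1
  L <- r - (E + 2) / 2         # #{values strictly below}
  G <- n - 1 - L - E
  R <- L + E / 2               # sum_u a(v, u) incoming
  S <- G + E / 2               # outgoing
  T2 <- sum(E) / 2             # unordered tied pairs
  D <- n * (n - 1) / 2 - T2
  A2 <- D + T2 / 2
  AB <- T2 / 2
  C1 <- sum(R^2 - L - E / 4)
  C2 <- sum(S^2 - G - E / 4)
  C3 <- sum(R * S - E / 4)
  S1 <- n * (n - 1) / 2
  Q <- S1^2 - A2 - AB - C1 - C2 - 2 * C3
  c(A2 = A2, AB = AB, C1 = C1, C2 = C2, C3 = C3, Q = Q)
}

# Weights multiplying the value aggregates in E[U^2], as a function of group
# sizes and the pattern's ordered pair set. Also returns the null mean and
# the maximum of U along the ordering.
pattern_moment_weights <- function(sizes, pairs) {
  N <- sum(sizes)
  n2 <- N * (N - 1)
  n3 <- n2 * (N - 2)
  n4 <- n3 * (N - 3)
  k <- nrow(pairs)
  w <- c(A2 = 0, AB = 0, C1 = 0, C2 = 0, C3 = 0, Q = 0)
  for (p1 in seq_len(k)) {
    a <- pairs[p1, 1]; b <- pairs[p1, 2]
    for (p2 in seq_len(k)) {
      cc <- pairs[p2, 1]; d <- pairs[p2, 2]
      if (a == cc && b == d)
        w["A2"] <- w["A2"] + sizes[a] * sizes[b] / n2
      if (a == d && b == cc)
        w["AB"] <- w["AB"] + sizes[a] * sizes[b] / n2
      if (a == cc)            # shared low-side index
        w["C2"] <- w["C2"] + sizes[a] *
          (if (b == d) sizes[b] * (sizes[b] - 1) else sizes[b] * sizes[d]) / n3
      if (b == d)             # shared high-side index
        w["C1"] <- w["C1"] + sizes[b] *
          (if (a == cc) sizes[a] * (sizes[a] - 1) else
             sizes[a] * sizes[cc]) / n3
      if (a == d)             # chain through the shared index
        w["C3"] <- w["C3"] + sizes[a] * sizes[b] *
          (sizes[cc] - (b == cc)) / n3
      if (b == cc)
        w["C3"] <- w["C3"] + sizes[b] * sizes[a] *
          (sizes[d] - (a == d)) / n3
      # all four indices distinct: falling-factorial product over the group
      # multiset of the four slots
      slots <- c(a, b, cc, d)
      prod4 <- 1
      for (g in unique(slots)) {
        kg <- sum(slots == g)
        prod4 <- prod4 * prod(sizes[g] - 0:(kg - 1))
      }
      w["Q"] <- w["Q"] + prod4 / n4
    }
  }
  mu <- 0.5 * sum(sizes[pairs[, 1]] * sizes[pairs[, 2]])
  list(w = w, mu = mu,
       max_u = sum(sizes[pairs[, 1]] * sizes[pairs[, 2]]))
}

# Number of distinct assignments of N items to groups of the given sizes.
n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# Full enumeration of the permutation null for all patterns at once.
# Returns, for each pattern, the right-tail count P[U* >= u_obs - eps] and
# the total number of assignments. Values assigned by index, so tied values
# are handled automatically (uniform over index assignments).
enumerate_null <- function(values, sizes, pairlists, u_obs) {
  m <- length(sizes)
  npat <- length(pairlists)
  counts <- numeric(npat)
  total <- 0
  eps <- 1e-9
  # unordered group pairs needed by any pattern
  rec <- function(remaining, gidx, assigned) {
    if (gidx > m) {
      umat <- matrix(NA_real_, m, m)
      for (i in seq_len(m - 1)) for (j in (i + 1):m)
        umat[i, j] <- pair_u(values[assigned[[i]]], values[assigned[[j]]])
      for (i in seq_len(m - 1)) for (j in (i + 1):m)
        umat[j, i] <- sizes[i] * sizes[j] - umat[i, j]
      for (pp in seq_len(npat)) {
        prs <- pairlists[[pp]]
        u <- sum(umat[prs])
        if (u >= u_obs[pp] - eps) counts[pp] <<- counts[pp] + 1
      }
      total <<- total + 1
      return(invisible(NULL))
    }
    if (gidx == m) {
      rec(integer(0), m + 1L, c(assigned, list(remaining)))
    } else {
      combs <- utils::combn(remaining, sizes[gidx], simplify = FALSE)
      for (cb in combs)
        rec(setdiff(remaining, cb), gidx + 1L, c(assigned, list(cb)))
    }
  }
  rec(seq_along(values), 1L, list())
  list(counts = counts, total = total)
}

#' Permutation p-value of an umbrella-pattern statistic
#'
#' Right-tail probability `P[U* >= U]` of the observed [jt_statistic()] under
#' random assignment of the pooled values to groups of the observed sizes.
#' Three paths, all deterministic: (1) full enumeration when the pooled size
#' is at most `exact_n` and the number of distinct assignments is at most
#' `exact_cap` (exact for arbitrary ties); (2) for larger tie-free samples,
#' the exact null distribution by a counting dynamic program (the generic
#' case for continuous expression values); (3) for larger samples with ties,
#' a normal approximation with continuity correction using the exact
#' permutation mean and variance (tie-corrected by construction).
#'
#' @param groups List of numeric vectors (cycle-position groups).
#' @param pattern List/row with `peak` (0-based) and `r`.
#' @param exact_n Largest pooled sample size for the exact path (default 12).
#' @param exact_cap Largest assignment count for the exact path (default 2e5).
#' @return A p-value in `(0, 1]`.
#' @examples
#' pattern_p(list(c(1, 2), c(3, 4)), list(peak = 1, r = 1))  # 1/6
#' @export
pattern_p <- function(groups, pattern, exact_n = 12, exact_cap = 2e5) {
  if (any(lengths(groups) == 0)) stop("empty group")
  sizes <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  prs <- pattern_pairs(length(groups), pattern$peak, pattern$r)
  u <- jt_statistic(groups, pattern)
  if (length(values) <= exact_n && n_assignments(sizes) <= exact_cap) {
    en <- enumerate_null(values, sizes, list(prs), u)
    return(en$counts[1] / en$total)
  }
  if (!anyDuplicated(values)) {
    tail <- exact_null_tail(sizes, prs)
    return(tail[round(u) + 1])
  }
  mom <- pattern_moment_weights(sizes, prs)
  aggs <- value_aggregates(values)
  e2 <- sum(mom$w * aggs)
  v <- e2 - mom$mu^2
  normal_tail_p(u, mom$mu, v)
}

# ---- exact no-ties null by dynamic programming ----------------------------
#
# For tie-free pooled values the null distribution of U depends only on the
# group sizes and the pattern, not on the values: insert the values in
# decreasing order, tracking how many have landed in each group; placing the
# next (smaller) value into group g adds, for every pattern pair (g, b), the
# count already in the high-side partner b. A counting DP over the occupancy
# lattice gives the full distribution exactly (path counts stay below 2^53
# for the designs this package targets). Results are memoized per
# (sizes, pattern) for the session.

.null_cache <- new.env(parent = emptyenv())

# Exact right-tail function of U for tie-free values: returns a numeric
# vector `tail` with tail[u + 1] = P[U* >= u], u = 0..max_u.
exact_null_tail <- function(sizes, pairs) {
  key <- paste(c(sizes, 0L, t(pairs)), collapse = ",")
  hit <- get0(key, envir = .null_cache)
  if (!is.null(hit)) return(hit)
  m <- length(sizes)
  radix <- cumprod(c(1, sizes[-m] + 1))
  grid <- as.matrix(expand.grid(lapply(sizes, function(n) 0:n)))
  idx_of <- as.vector(grid %*% radix) + 1L        # state index
  ord <- order(rowSums(grid))                     # process by total count
  # high-side partners of each group
  partners <- lapply(seq_len(m), function(g) pairs[pairs[, 1] == g, 2])
  max_u <- sum(sizes[pairs[, 1]] * sizes[pairs[, 2]])
  D <- matrix(0, nrow = prod(sizes + 1), ncol = max_u + 1)
  D[1, 1] <- 1
  for (st in ord) {
    row <- D[idx_of[st], ]
    if (!any(row != 0)) next
    k <- grid[st, ]
    for (g in seq_len(m)) {
      if (k[g] >= sizes[g]) next
      inc <- sum(k[partners[[g]]])
      tgt <- idx_of[st] + radix[g]
      if (inc == 0) D[tgt, ] <- D[tgt, ] + row
      else D[tgt, (1 + inc):(max_u + 1)] <- D[tgt, (1 + inc):(max_u + 1)] +
          row[1:(max_u + 1 - inc)]
    }
  }
  dist <- D[idx_of[which(rowSums(grid) == sum(sizes))], ]
  tail <- rev(cumsum(rev(dist))) / sum(dist)
  assign(key, tail, envir = .null_cache)
  tail
}

normal_tail_p <- function(u, mu, v) {
  if (v <= 1e-12) return(1)   # degenerate null (e.g. all values tied)
  z <- (u - 0.5 - mu) / sqrt(v)
  min(1, max(stats::pnorm(z, lower.tail = FALSE), .Machine$double.xmin))
}

#' Umbrella rhythm test for one transcript at one folded period
#'
#' Tests all `m * (m - 1)` cyclic umbrella patterns on the folded groups and
#' Bonferroni-corrects over them: `raw_p = min(1, m * (m - 1) * min(p))`.
#' The best pattern is the argmin, ties broken toward the lowest peak index,
#' then the lowest rise length.
#'
#' @param values Numeric vector of the transcript's values, in sample order.
#' @param fold A `cycle_fold` from [fold_timepoints()].
#' @param exact_n,exact_cap Exact-path limits, see [pattern_p()].
#' @return A list with `raw_p`, `best_pattern` (list `peak`, `r`), `p_each`
#'   (per-pattern p-values), `u_each`.
#' @export
umbrella_test <- function(values, fold, exact_n = 12, exact_cap = 2e5) {
  groups <- lapply(fold$groups, function(ix) values[ix])
  m <- length(groups)
  pats <- fold$patterns
  npat <- nrow(pats)
  sizes <- lengths(groups)
  N <- sum(sizes)
  # observed statistics from the pairwise U matrix
  umat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    umat[i, j] <- pair_u(groups[[i]], groups[[j]])
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    umat[j, i] <- sizes[i] * sizes[j] - umat[i, j]
  u_obs <- vapply(fold$pairlists, function(prs) sum(umat[prs]), numeric(1))
  if (N <= exact_n && n_assignments(sizes) <= exact_cap) {
    en <- enumerate_null(unlist(groups, use.names = FALSE), sizes,
                         fold$pairlists, u_obs)
    p_each <- en$counts / en$total
  } else if (!anyDuplicated(values)) {
    p_each <- vapply(seq_len(npat), function(k)
      exact_null_tail(sizes, fold$pairlists[[k]])[round(u_obs[k]) + 1],
      numeric(1))
  } else {
    aggs <- value_aggregates(unlist(groups, use.names = FALSE))
    p_each <- vapply(seq_len(npat), function(k) {
      mom <- fold$moments[[k]]
      v <- sum(mom$w * aggs) - mom$mu^2
      normal_tail_p(u_obs[k], mom$mu, v)
    }, numeric(1))
  }
  best <- which.min(p_each)   # patterns ordered by (peak, r): spec tie-break
  list(raw_p = min(1, npat * p_each[best]),
       best_pattern = list(peak = pats$peak[best], r = pats$r[best]),
       p_each = p_each, u_each = u_obs)
}
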