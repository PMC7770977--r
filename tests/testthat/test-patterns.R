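test_that("JT statistic follows the cyclic umbrella pair definition", {
  asc <- list(peak = 1, r = 1)
  expect_equal(jt_statistic(list(c(1, 2), c(3, 4)), asc), 4)
  expect_equal(jt_statistic(list(c(3, 4), c(1, 2)), asc), 0)
  expect_equal(jt_statistic(list(1, 2, 1), list(peak = 1, r = 1)), 2)
  expect_error(jt_statistic(list(numeric(0), 1), asc), "empty group")
  # half-tie convention
  expect_equal(jt_statistic(list(c(1, 1), c(1, 2)), asc), 2 + 2 * 0.5)
})

test_that("the pattern family has m*(m-1) members, ordered by peak then rise", {
  for (m in 2:6) {
    pats <- umbrella_patterns(m)
    expect_equal(nrow(pats), m * (m - 1))
    expect_false(is.unsorted(pats$peak))
  }
})

test_that("exact permutation p-values match hand enumeration and degenerate ties", {
  expect_equal(pattern_p(list(c(1, 2), c(3, 4)), list(peak = 1, r = 1)), 1 / 6)
  expect_equal(pattern_p(list(c(1, 1), c(1, 1, 1)), list(peak = 1, r = 1)), 1)
})

test_that("pattern_p agrees with a brute-force oracle on tied data (N = 9)", {
  set.seed(11)
  values <- sample(c(1, 1, 2, 2, 3, 4, 4, 5, 6))
  groups <- split(values, rep(1:3, c(3, 3, 3)))
  pats <- umbrella_patterns(3)
  for (k in seq_len(nrow(pats))) {
    p_pkg <- pattern_p(groups, list(peak = pats$peak[k], r = pats$r[k]))
    p_orc <- oracle_pattern_p(groups, pats$peak[k], pats$r[k])
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
})

test_that("the tie-free DP null equals full enumeration", {
  set.seed(21)
  for (sizes in list(c(3, 2, 2), c(2, 2, 2, 2), c(4, 3, 3))) {
    v <- sample(1000, sum(sizes))
    groups <- split(v, rep(seq_along(sizes), sizes))
    pats <- umbrella_patterns(length(sizes))
    for (k in seq_len(nrow(pats))) {
      pat <- list(peak = pats$peak[k], r = pats$r[k])
      prs <- polarhythm:::pattern_pairs(length(sizes), pat$peak, pat$r)
      u <- jt_statistic(groups, pat)
      p_dp <- polarhythm:::exact_null_tail(lengths(groups), prs)[round(u) + 1]
      p_enum <- pattern_p(groups, pat)  # N <= 12: enumeration path
      expect_equal(p_dp, p_enum, tolerance = 1e-12)
    }
  }
})

test_that("normal-approximation moments are the exact permutation moments", {
  # tied pooled values, 3 groups: enumerate the full null and compare
  values <- c(1, 2, 2, 3, 4, 4, 5)
  sizes <- c(3, 2, 2)
  groups <- split(values, rep(1:3, sizes))
  pats <- umbrella_patterns(3)
  for (k in seq_len(nrow(pats))) {
    prs <- polarhythm:::pattern_pairs(3, pats$peak[k], pats$r[k])
    us <- c()
    rec <- function(remaining, assigned) {
      if (length(assigned) == 2) {
        gl <- lapply(c(assigned, list(remaining)), function(ix) values[ix])
        us <<- c(us, jt_statistic(gl, list(peak = pats$peak[k],
                                           r = pats$r[k])))
        return(invisible(NULL))
      }
      for (cb in utils::combn(remaining, sizes[length(assigned) + 1],
                              simplify = FALSE))
        rec(setdiff(remaining, cb), c(assigned, list(cb)))
    }
    rec(seq_along(values), list())
    mom <- polarhythm:::pattern_moment_weights(sizes, prs)
    aggs <- polarhythm:::value_aggregates(values)
    expect_equal(mom$mu, mean(us), tolerance = 1e-12)
    expect_equal(sum(mom$w * aggs) - mom$mu^2, mean(us^2) - mean(us)^2,
                 tolerance = 1e-10)
  }
})

test_that("umbrella test is rank-invariant and handles constant rows", {
  d <- ts_design(station = "S", clock_start = 0)
  fold <- fold_timepoints(d, 24)
  expect_equal(umbrella_test(rep(3, 21), fold)$raw_p, 1)

  set.seed(31)
  v <- rnorm(21)
  ut1 <- umbrella_test(v, fold)
  ut2 <- umbrella_test(exp(v), fold)       # strictly increasing transform
  expect_identical(ut1$raw_p, ut2$raw_p)
  expect_identical(ut1$best_pattern, ut2$best_pattern)
})

test_that("rotating an exactly cyclic design shifts the best pattern's peak", {
  # 6 timepoints without the duplicated endpoint: an exactly cyclic design
  d <- ts_design(timepoints_h = seq(0, 20, by = 4), station = "S",
                 clock_start = 0)
  fold <- fold_timepoints(d, 24)
  set.seed(41)
  v <- as.vector(t(matrix(rnorm(18), nrow = 6)))  # grouped by timepoint
  v <- planted_waveform(d$time_h, 10, 2, 24, 3) * exp(0.05 * rnorm(18))
  ut <- umbrella_test(v, fold)
  # rotate by one sampling step: each sample's value moves to time + 4
  rot <- v[c(16:18, 1:15)]
  ut_rot <- umbrella_test(rot, fold)
  expect_equal(ut_rot$raw_p, ut$raw_p, tolerance = 1e-12)
  expect_equal(ut_rot$best_pattern$peak, (ut$best_pattern$peak + 1) %% 6)
  expect_equal(ut_rot$best_pattern$r, ut$best_pattern$r)
})

test_that("BH adjustment validates, preserves order and matches the step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1), 1)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(51)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})
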