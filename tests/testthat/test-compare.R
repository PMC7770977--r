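test_that("rhythm status and the seven-category mapping follow the rules", {
  expect_equal(rhythm_status(0.0005, "daily", 0.001), "daily")
  expect_equal(rhythm_status(0.0005, "ultradian", 0.001), "ultradian")
  expect_equal(rhythm_status(0.002, "daily", 0.001), "none")

  expect_equal(categorize("daily", "none"), "excl_A")
  expect_equal(categorize("none", "ultradian"), "excl_B")
  expect_equal(categorize("daily", "daily"), "both_same_daily")
  expect_equal(categorize("ultradian", "ultradian"), "both_same_ultradian")
  expect_equal(categorize("daily", "ultradian"), "switch_daily_to_ultradian")
  expect_equal(categorize("ultradian", "daily"), "switch_ultradian_to_daily")
  expect_equal(categorize("none", "none"), "nonrhythmic")
  expect_error(categorize("weekly", "none"), "none/daily/ultradian")

  # symmetry: swapping stations swaps the asymmetric categories
  st <- c("none", "daily", "ultradian")
  grid <- expand.grid(a = st, b = st, stringsAsFactors = FALSE)
  fwd <- categorize(grid$a, grid$b)
  rev <- categorize(grid$b, grid$a)
  swap <- c(excl_A = "excl_B", excl_B = "excl_A",
            both_same_daily = "both_same_daily",
            both_same_ultradian = "both_same_ultradian",
            switch_daily_to_ultradian = "switch_ultradian_to_daily",
            switch_ultradian_to_daily = "switch_daily_to_ultradian",
            nonrhythmic = "nonrhythmic")
  expect_equal(unname(swap[fwd]), rev)
})

test_that("cutoff summary counts once per transcript and nests across cutoffs", {
  res <- data.frame(transcript_id = sprintf("t%02d", 1:10),
                    raw_p_24 = c(rep(1e-5, 4), rep(0.9, 6)),
                    adj_p_24 = c(rep(1e-4, 4), rep(1, 6)),
                    assigned_period_h = 24,
                    assigned_adj_p = c(rep(1e-4, 4), rep(1, 6)),
                    period_range = "daily", stringsAsFactors = FALSE)
  cs <- cutoff_summary(res, alphas = c(0.001, 0.01, 0.05), n_total = 10)
  r1 <- cs[cs$alpha == 0.001, ]
  expect_equal(r1$count[r1$group == "24h"], 4)
  expect_equal(r1$count[r1$group == "all_rhythmic"], 4)
  expect_equal(r1$percent[r1$group == "all_rhythmic"], 40)

  # nesting and conservation on a synthetic scan
  d <- ts_design(station = "S", clock_start = 0)
  sim <- generate_matrix(d, default_classes(300), noise_sigma = 0.15,
                         seed = 12)
  scan <- detect_rhythms(sim)
  cs2 <- cutoff_summary(scan)
  for (g in unique(cs2$group)) {
    cnt <- cs2$count[cs2$group == g][order(cs2$alpha[cs2$group == g])]
    expect_true(all(diff(cnt) >= 0))
  }
  for (a in unique(cs2$alpha)) {
    sub <- cs2[cs2$alpha == a, ]
    expect_equal(sub$count[sub$group == "daily"] +
                   sub$count[sub$group == "ultradian"],
                 sub$count[sub$group == "all_rhythmic"])
  }
})

test_that("comparison partitions the universe and respects symmetry", {
  sc <- two_station_scenario(seed = 13)
  scan_A <- detect_rhythms(sc$A)
  scan_B <- detect_rhythms(sc$B)
  cmp <- comparison_summary(scan_A, scan_B, alpha = 0.001)
  expect_equal(sum(cmp$counts), nrow(sc$truth))
  cmp_rev <- comparison_summary(scan_B, scan_A, alpha = 0.001)
  expect_equal(unname(cmp$counts["excl_A"]), unname(cmp_rev$counts["excl_B"]))
  expect_equal(unname(cmp$counts["switch_daily_to_ultradian"]),
               unname(cmp_rev$counts["switch_ultradian_to_daily"]))
  expect_equal(unname(cmp$counts["both_same_daily"]),
               unname(cmp_rev$counts["both_same_daily"]))

  # nesting of the rhythmic sets across cutoffs
  r <- scan_A$results
  sets <- lapply(c(0.001, 0.01, 0.05), function(a)
    r$transcript_id[r$assigned_adj_p < a])
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))

  # universe mismatch is a hard error reporting the symmetric difference
  res_B <- scan_B$results[-(1:3), ]
  expect_error(comparison_summary(scan_A$results, res_B, 0.001),
               "symmetric difference: 3")
})

test_that("per-set breakdown splits categories by period range at the right station", {
  records_A <- data.frame(transcript_id = c("g1", "g2", "g3", "g4"),
                          raw_p_24 = 1, adj_p_24 = 1,
                          assigned_period_h = c(24, 24, 12, 24),
                          assigned_adj_p = c(1e-4, 1e-4, 1e-4, 0.5),
                          period_range = c("daily", "daily", "ultradian",
                                           "daily"),
                          stringsAsFactors = FALSE)
  records_B <- data.frame(transcript_id = c("g1", "g2", "g3", "g4"),
                          raw_p_24 = 1, adj_p_24 = 1,
                          assigned_period_h = c(12, 24, 12, 24),
                          assigned_adj_p = c(1e-4, 0.5, 1e-4, 1e-4),
                          period_range = c("ultradian", "daily", "ultradian",
                                           "daily"),
                          stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    term_id = "GO:1", stringsAsFactors = FALSE)
  cmp <- comparison_summary(records_A, records_B, alpha = 0.001,
                            annotation = ann)
  sb <- cmp$set_breakdown
  get <- function(cat, rng)
    sb$count[sb$category == cat & sb$period_range == rng]
  # g1 switches daily->ultradian: shown as expressed at B (ultradian)
  expect_equal(get("both_switch", "ultradian"), 1)
  expect_equal(get("excl_A", "daily"), 1)       # g2 rhythmic only at A
  expect_equal(get("both_same", "ultradian"), 1)  # g3
  expect_equal(get("excl_B", "daily"), 1)       # g4
})
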