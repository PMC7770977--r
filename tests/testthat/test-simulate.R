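test_that("planted waveform hits its peak, trough and degenerate cases", {
  expect_equal(planted_waveform(8, 2, 1.5, 24, 8), 5)       # b * (1 + A)
  expect_equal(planted_waveform(8 + 12, 2, 1.5, 24, 8), 2)  # trough = b
  expect_equal(planted_waveform(0:23, 2, 0, 24, 0), rep(2, 24))
  expect_error(planted_waveform(0, -1, 1, 24, 0), "baseline")
  expect_error(planted_waveform(0, 1, 1, 0, 0), "period")
})

test_that("generation is seed-deterministic and exact at zero noise", {
  d <- ts_design(station = "S", clock_start = 0)
  cls <- data.frame(n = c(5, 100), period_h = c(24, NA), amplitude = c(2, NA),
                    baseline = 50, phase_mode = "uniform")
  s1 <- generate_matrix(d, cls, noise_sigma = 0.2, seed = 1)
  s2 <- generate_matrix(d, cls, noise_sigma = 0.2, seed = 1)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_matrix(d, cls, noise_sigma = 0.2, seed = 2)
  expect_false(identical(s1$matrix, s3$matrix))

  # zero noise: the matrix equals the waveform exactly
  cls0 <- data.frame(n = 1, period_h = 24, amplitude = 1.5, baseline = 2,
                     phase_mode = "fixed", phase_center_h = 8)
  s0 <- generate_matrix(d, cls0, noise_sigma = 0, seed = 1)
  expect_equal(as.vector(s0$matrix),
               planted_waveform(d$time_h, 2, 1.5, 24, 8))
  # truth rows align with matrix rows
  expect_identical(s0$truth$transcript_id, rownames(s0$matrix))
  expect_error(generate_matrix(d, cls0[0, ]), "at least one")
})

test_that("zero-noise parameter recovery over a phase sweep", {
  d <- ts_design(station = "S", clock_start = 0)
  f <- fold_timepoints(d, 24)
  for (phi in 0:23) {
    v <- planted_waveform(d$time_h, 10, 2, 24, phi)
    prof <- summarize_profile(v, f)
    amp <- estimate_amplitude(prof)
    if (phi %% 4 == 0) {
      # peak and trough both sampled: exact recovery
      expect_equal(amp, 2)
      expect_equal(estimate_phase(prof, f)$phase_h, phi %% 24)
    } else {
      # cosine sampling bound: recovered amplitude never exceeds planted
      expect_lte(amp, 2)
      ph <- estimate_phase(prof, f)$phase_h
      dd <- min(abs(ph - phi) %% 24, 24 - abs(ph - phi) %% 24)
      expect_lte(dd, 2)  # nearest grid point
    }
  }
})

test_that("negative-binomial mode produces integer counts at the right scale", {
  d <- ts_design(station = "S", clock_start = 0)
  cls <- data.frame(n = 200, period_h = NA, amplitude = NA, baseline = 100)
  s <- generate_matrix(d, cls, noise_model = "nb", dispersion = 0.05, seed = 3)
  expect_true(all(s$matrix == round(s$matrix)))
  expect_equal(mean(s$matrix), 100, tolerance = 0.05)
})

test_that("two-station scenario plants the configured architecture exactly", {
  sc <- two_station_scenario(counts = list(excl_A = 5, excl_B = 4,
                                           both_same_daily = 3,
                                           both_same_ultradian = 2,
                                           switch_daily_to_ultradian = 10,
                                           switch_ultradian_to_daily = 1,
                                           nonrhythmic = 20),
                             seed = 2)
  expect_equal(sum(sc$truth$category == "switch_daily_to_ultradian"), 10)
  expect_equal(nrow(sc$truth), 45)
  expect_identical(sc$A$truth$transcript_id, sc$B$truth$transcript_id)
  # category semantics are reflected in the per-station truths
  swd <- sc$truth$category == "switch_daily_to_ultradian"
  expect_true(all(sc$A$truth$period_h[swd] %in% c(20, 24)))
  expect_true(all(sc$B$truth$period_h[swd] %in% c(12, 16)))

  # zero overlap: no transcript rhythmic at both stations
  sc0 <- two_station_scenario(counts = list(excl_A = 5, excl_B = 5,
                                            nonrhythmic = 10), seed = 3)
  expect_equal(sum(sc0$A$truth$rhythmic & sc0$B$truth$rhythmic), 0)

  expect_error(two_station_scenario(counts = list(excl_A = -1)), "invalid")
})

test_that("truth/matrix misalignment is detectable by id checksum", {
  d <- ts_design(station = "S", clock_start = 0)
  cls <- data.frame(n = 20, period_h = 24, amplitude = 2, baseline = 10)
  s <- generate_matrix(d, cls, seed = 4)
  perm <- sample(nrow(s$matrix))
  shuffled <- s$matrix[perm, ]
  expect_false(identical(rownames(shuffled), s$truth$transcript_id))
})
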