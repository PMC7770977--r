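test_that("profile summaries, phases and amplitudes follow their contracts", {
  d <- ts_design(station = "S", clock_start = 0)
  f12 <- fold_timepoints(d, 12)
  expect_length(summarize_profile(rnorm(21), f12), 3)
  f24 <- fold_timepoints(d, 24)
  v <- rep(c(1, 2, 3), 7)   # per-timepoint replicates 1,2,3 -> median 2
  expect_equal(summarize_profile(v, f24), rep(2, 6))

  # phase: argmax, ties to the earliest position
  prof <- c(1, 5, 2, 1, 5, 1)
  expect_equal(estimate_phase(prof, f24)$phase_h, 4)
  expect_error(estimate_phase(rep(2, 6), f24), "phase undefined")

  # amplitude formula and pseudocount handling
  expect_equal(estimate_amplitude(c(2, 3, 5)), 1.5)
  expect_equal(estimate_amplitude(rep(4, 5)), 0)
  expect_equal(estimate_amplitude(c(0, 4), pseudocount = 1), 4)
  expect_error(estimate_amplitude(c(0, 4)), "positive")
  expect_error(estimate_amplitude(c(1, 2), pseudocount = -1), "non-negative")
})

test_that("amplitude bins use the documented boundaries", {
  expect_equal(amplitude_bin(c(0, 0.49, 0.5, 1.49, 1.5, 5, 5.0001, 80)),
               c("0-0.5", "0-0.5", "0.5-1.5", "0.5-1.5", "1.5-5", "1.5-5",
                 ">5", ">5"))
  expect_error(amplitude_bin(-0.1), "non-negative")
})

test_that("median normalization is exact, idempotent and leaves phase/amplitude fixed", {
  expect_equal(median_normalize(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(median_normalize(c(3, 3)), c(1, 1))
  v <- rexp(11) + 0.1
  expect_equal(median_normalize(median_normalize(v)), median_normalize(v))
  expect_error(median_normalize(c(-1, 0, 1)), "positive")

  d <- ts_design(station = "S", clock_start = 0)
  f <- fold_timepoints(d, 24)
  set.seed(9)
  row <- planted_waveform(d$time_h, 10, 2, 24, 8) * exp(rnorm(21, 0, 0.1))
  p1 <- summarize_profile(row, f)
  p2 <- summarize_profile(median_normalize(row), f)
  expect_equal(estimate_amplitude(p1), estimate_amplitude(p2))
  expect_equal(estimate_phase(p1, f), estimate_phase(p2, f))
})

test_that("coincidence labels pick the nearest event within tolerance", {
  ev <- data.frame(clock_local = c(0, 12, 4.5, 10.5, 16.7, 23.0),
                   kind = c("solar_min", "solar_max", "high_tide", "low_tide",
                            "high_tide", "low_tide"))
  expect_equal(coincidence_label(0.5, ev, 2, "daily"), "solar_min")
  expect_equal(coincidence_label(3, ev, 2, "ultradian"), "high_tide")
  expect_equal(coincidence_label(6.9, ev, 2, "daily"), "none")
  expect_equal(coincidence_label(5, NULL), "none")
  # tie between solar and tidal event: period range decides
  ev2 <- data.frame(clock_local = c(2, 6), kind = c("solar_min", "high_tide"))
  expect_equal(coincidence_label(4, ev2, 2, "ultradian"), "high_tide")
  expect_equal(coincidence_label(4, ev2, 2, "daily"), "solar_min")
})

test_that("phase histograms count transcripts at sampling clock times", {
  h <- phase_histogram(c(2, 2, 6), c(2, 6, 10))
  expect_equal(h$count, c(2, 1, 0))
  h0 <- phase_histogram(numeric(0), c(2, 6, 10))
  expect_equal(sum(h0$count), 0)
  expect_equal(sum(h$count), 3)  # conservation
})

test_that("characterize fills phases/amplitudes for significant transcripts", {
  d <- ts_design(station = "S", clock_start = 14)
  cls <- data.frame(n = c(10, 40), period_h = c(24, NA), amplitude = c(2, NA),
                    baseline = 100, phase_mode = "fixed", phase_center_h = 8)
  sim <- generate_matrix(d, cls, noise_sigma = 0.05, seed = 10)
  scan <- detect_rhythms(sim)
  env <- env_cycle(74.5, 30, "2018-06-30T12:00", hours = 26)
  scan <- characterize(scan, sim, alpha = 0.001, env = env)
  res <- scan$results
  sig <- res$assigned_adj_p < 0.001
  expect_true(any(sig))
  expect_true(all(!is.na(res$amplitude[sig])))
  expect_true(all(is.na(res$amplitude[!sig])))
  expect_true(all(res$amplitude_bin[sig] ==
                    amplitude_bin(res$amplitude[sig])))
  expect_true(all(res$phase_h[sig] < res$assigned_period_h[sig]))
  expect_true(all(res$coincidence_label[sig] %in%
                    c("solar_min", "solar_max", "high_tide", "low_tide",
                      "none")))
  # planted phase 8 on the grid: recovered exactly for detected 24h rows
  hit <- sig & sim$truth$rhythmic & res$assigned_period_h == 24
  expect_true(all(res$phase_h[hit] == 8))
  # clock mapping: design starts at 14h local, so phase 8 peaks at 22h clock
  expect_true(all(res$phase_clock_h[hit] == 22))
})
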