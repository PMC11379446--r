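test_that("EMG bandpass rejects DC and the notch removes 50 Hz", {
  fs <- 2048
  tt <- (seq_len(10 * fs) - 0.5) / fs

  const <- filter_emg(one_ch_rec(rep(1, 10 * fs)))
  expect_lt(mid_rms(const$signals[1, ]), 0.01)

  s50 <- filter_emg(one_ch_rec(sin(2 * pi * 50 * tt)))
  expect_lt(mid_rms(s50$signals[1, ]) / (1 / sqrt(2)), 0.05)

  s100 <- filter_emg(one_ch_rec(sin(2 * pi * 100 * tt)))
  expect_equal(mid_rms(s100$signals[1, ]), 1 / sqrt(2), tolerance = 0.05)

  expect_error(filter_emg(one_ch_rec(rnorm(fs), fs = 960),
                          filter_spec(band = c(20, 500))), "Nyquist")
})

test_that("filtering is zero-phase: in-band components are not time-shifted", {
  fs <- 2048
  tt <- (seq_len(10 * fs) - 0.5) / fs
  x <- sin(2 * pi * 80 * tt)
  y <- filter_emg(one_ch_rec(x))$signals[1, ]
  mid <- seq(2 * fs, 8 * fs)
  lags <- -5:5
  r <- vapply(lags, function(l) cor(x[mid], y[mid + l]), numeric(1))
  expect_equal(lags[which.max(r)], 0)
  expect_gt(max(r), 0.999)
})

test_that("torque low-pass keeps DC and 1 Hz, suppresses 40 Hz", {
  fs <- 512
  tt <- (seq_len(20 * fs) - 0.5) / fs

  const <- filter_torque(torque_trace(rep(60, 20 * fs), fs, 100))
  expect_equal(mid_rms(const$torque), 60, tolerance = 1e-3)

  s1 <- filter_torque(torque_trace(sin(2 * pi * 1 * tt), fs, 100))
  expect_equal(mid_rms(s1$torque), 1 / sqrt(2), tolerance = 0.02)

  s40 <- filter_torque(torque_trace(sin(2 * pi * 40 * tt), fs, 100))
  atten_db <- 20 * log10(mid_rms(s40$torque) / (1 / sqrt(2)))
  expect_lt(atten_db, -30)
})

test_that("SNR rule flags a dead channel; outlier fallback flags saturation", {
  set.seed(7)
  lay <- grid_layout(4, 4)
  fs <- 2048
  n <- 10 * fs
  tt <- (seq_len(n) - 0.5) / fs
  active <- as.numeric(tt > 4)           # quiet [0,3], hold [4,10]
  sig <- t(replicate(16, active * rnorm(n) + 0.02 * rnorm(n)))
  sig[6, ] <- 0.02 * rnorm(n)            # channel 6 never leaves the floor
  rec <- emg_recording(sig, fs, lay)
  bad <- detect_bad_channels(rec, snr_floor_db = 10,
                             hold_window = c(4, 10), quiet_window = c(0, 3))
  expect_equal(nrow(bad), 1)
  expect_equal(unname(bad[1, ]), unname(unlist(rec$map[6, c("row", "col")])))
  expect_false(attr(bad, "fallback"))

  # identical statistics, no quiet reference: nothing flagged, fallback used
  sig2 <- t(replicate(16, rnorm(n / 4)))
  rec2 <- emg_recording(sig2, fs, lay)
  none <- detect_bad_channels(rec2, quiet_window = NULL)
  expect_equal(nrow(none), 0)
  expect_true(attr(none, "fallback"))

  # one saturated channel trips the robust outlier rule
  sig2[11, ] <- 10 * sig2[11, ]
  rec3 <- emg_recording(sig2, fs, lay)
  sat <- detect_bad_channels(rec3, quiet_window = NULL)
  expect_equal(nrow(sat), 1)
  expect_equal(unname(sat[1, ]), unname(unlist(rec3$map[11, c("row", "col")])))
})

test_that("contraction segmentation recovers the transient marks", {
  cfg <- sim_config(fs = 1024, duration_s = 100, rest_s = 0, torque_ramp_s = 2,
                    failure_time_s = 92, seed = 9)
  tq <- filter_torque(simulate_torque(cfg))
  region <- segment_contraction(tq)
  expect_equal(region$start_s, 4, tolerance = 0.2)
  expect_equal(region$end_s, 90, tolerance = 0.1)
  segs <- region$segments
  expect_equal(mean(unlist(segs[segs$label == "T2", c("start_s", "end_s")])),
               47, tolerance = 0.2)
  expect_true(all(abs(segs$end_s - segs$start_s - 10) < 1e-9))
  expect_true(all(abs(apply(region$windows, 1, diff) - 4) < 1e-9))

  # manual marks take precedence and give an exact region
  rman <- segment_contraction(tq, marks = c(2, 92))
  expect_equal(rman$start_s, 4)
  expect_equal(rman$end_s, 90)

  expect_error(segment_contraction(torque_trace(rep(0, 5000), 100, 100)),
               "no contraction")
})

test_that("endurance time honours the sustain rule and censoring", {
  cfg <- sim_config(fs = 1024, duration_s = 100, rest_s = 0, torque_ramp_s = 2,
                    failure_time_s = 90, seed = 10)
  et <- endurance_time(filter_torque(simulate_torque(cfg)))
  expect_false(et$censored)
  expect_equal(et$endurance_s, 88, tolerance = 0.1)

  # a 1 s dip below threshold is ignored; sustained drop at 70 s is found
  fs <- 100
  tt <- (seq_len(80 * fs) - 0.5) / fs
  y <- ifelse(tt < 2, 30 * tt, 60)
  y[tt >= 20 & tt < 21] <- 40
  y[tt >= 70] <- 30
  et2 <- endurance_time(torque_trace(y, fs, 100))
  expect_equal(et2$failure_s, 70, tolerance = 2 / fs)

  # never dropping yields the censored flag
  et3 <- endurance_time(torque_trace(c(30 * tt[tt < 2], rep(60, 6000)), fs, 100))
  expect_true(et3$censored)

  tq_bad <- torque_trace(y, fs, 100)
  tq_bad$mvt <- 0
  expect_error(endurance_time(tq_bad), "mvt")
})

test_that("per-segment torque statistics use the population CoV", {
  region <- analysis_region(0, 30)

  tq <- torque_trace(rep(60, 3000), 100, 100)
  s <- torque_segment_stats(tq, region)
  expect_equal(s$torque_mean, rep(0.6, 3))
  expect_equal(s$torque_cov, rep(0, 3))

  tq2 <- torque_trace(rep(c(50, 70), 1500), 100, 100)
  s2 <- torque_segment_stats(tq2, region)
  expect_equal(s2$torque_mean, rep(0.6, 3))
  expect_equal(s2$torque_cov, rep(0.1 / 0.6, 3), tolerance = 1e-9)

  tq3 <- torque_trace(rep(0, 3000), 100, 100)
  expect_true(all(is.na(torque_segment_stats(tq3, region)$torque_cov)))
})
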