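# R-peak detection, tachogram statistics, HRV and SPR features.

test_that("detector finds every beat of clean synthetic ECG, any polarity", {
  src <- generate_ecg(300, rr_ms = 1000, fs_hz = 1000)
  tach <- detect_r_peaks(src)
  truth <- src$meta$r_peaks_s
  expect_equal(length(tach$peak_times_s), length(truth))
  expect_lt(max(abs(tach$peak_times_s - truth)), 0.010)

  # inverted polarity: squaring stage + absolute-value refinement
  inv <- spr_trace(-src$values, src$fs_hz, channel = "ECG1")
  tach_inv <- detect_r_peaks(inv)
  expect_equal(length(tach_inv$peak_times_s), length(truth))
  expect_lt(max(abs(tach_inv$peak_times_s - truth)), 0.010)

  expect_warning(empty <- detect_r_peaks(spr_trace(rep(0.1, 3000), 200)),
                 "flat")
  expect_length(empty$peak_times_s, 0)
  expect_error(detect_r_peaks(spr_trace(stats::rnorm(50), 200)), "10 s")
})

test_that("detector has zero miss / false alarm over the tested HR range", {
  for (hr in c(50, 80, 120)) {
    src <- generate_ecg(120, rr_ms = 60000 / hr, fs_hz = 1000)
    tach <- detect_r_peaks(src)
    truth <- src$meta$r_peaks_s
    expect_equal(length(tach$peak_times_s), length(truth),
                 label = sprintf("peaks at %d bpm", hr))
    expect_lt(max(abs(tach$peak_times_s - truth)), 0.010)
  }
})

test_that("RR through the 200 Hz chain stays within one sample of nominal", {
  src <- generate_ecg(120, rr_ms = 1000, clock_skew_ppm = 370)
  acq <- simulate_acquisition(ecg1 = src)
  tach <- detect_r_peaks(acq$input_referred$ECG1)
  expect_equal(length(tach$rr_ms) + 1L, length(src$meta$r_peaks_s))
  expect_lt(max(abs(tach$rr_ms - 1000.37)), 5 + 1e-9)
})

test_that("jitter statistics report deviations and the closed-form bound", {
  tach <- tachogram(seq(0, 60, by = 1))
  js <- jitter_stats(tach, nominal_rr_ms = 1000, fs_hz = 200)
  expect_equal(js$max_abs_dev_ms, 0)
  expect_equal(js$std_ms, 0)
  # T_s / sqrt(3): 2.89 ms at 200 Hz, the bench's printed 2.8 at one decimal
  expect_equal(js$theoretical_std_ms, 5 / sqrt(3))
  expect_equal(js$theoretical_std_ms, 2.887, tolerance = 1e-4)
  expect_error(jitter_stats(tachogram(seq(0, 5, by = 1)), 1000), "insufficient")
})

test_that("grid quantization of peak times never moves RR by more than T_s", {
  # direct quantization oracle at several incommensurate RR values
  for (rr in c(1000.37, 811.77, 1203.33)) {
    truth <- cumsum(rep(rr, 200)) / 1000
    det <- round(truth * 200) / 200        # nearest 5 ms grid instant
    err <- abs(diff(det) * 1000 - rr)
    expect_lt(max(err), 5)
  }
})

test_that("time-domain HRV features follow their standard formulas", {
  # constant RR
  h <- hrv_features(tachogram(seq(0.5, 299.5, by = 1)))
  expect_equal(h$mean_hr_bpm, 60)
  expect_equal(h$sdnn_ms, 0)
  expect_equal(h$rmssd_ms, 0)
  expect_equal(h$nn50_count, 0L)

  # alternating 950/1050: RMSSD exactly 100, SDNN ~ 50, pNN50 = 100
  rr <- rep(c(950, 1050), 150) / 1000
  tach <- tachogram(cumsum(c(0.5, rr)))
  h2 <- hrv_features(tach)
  expect_equal(h2$rmssd_ms, 100, tolerance = 1e-9)
  expect_equal(h2$sdnn_ms, 50, tolerance = 1e-2)
  expect_equal(h2$pnn50_pct, 100)
  expect_equal(h2$nn50_count, length(rr) - 1L)

  expect_error(hrv_features(tachogram(c(1))), "empty")
})

test_that("permutation/reversal invariances of the time-domain features", {
  set.seed(12)
  rr <- 1000 + stats::rnorm(240, 0, 40)
  fwd <- tachogram(cumsum(c(0, rr)) / 1000)
  rev_ <- tachogram(cumsum(c(0, rev(rr))) / 1000)
  hf <- hrv_features(fwd)
  hr <- hrv_features(rev_)
  expect_equal(hf$sdnn_ms, hr$sdnn_ms, tolerance = 1e-10)
  expect_equal(hf$rmssd_ms, hr$rmssd_ms, tolerance = 1e-10)
  expect_equal(hf$sdsd_ms, hr$sdsd_ms, tolerance = 1e-10)
})

test_that("sinusoidal RR modulation lands its power in the right band", {
  mk <- function(f_mod, amp) {
    n <- 360
    tk <- cumsum(rep(1, n))
    rr <- 1000 + amp * sin(2 * pi * f_mod * tk)
    tachogram(cumsum(rr) / 1000)
  }
  lf_dom <- hrv_features(mk(0.1, 30))
  expect_gt(lf_dom$lf_hf_ratio, 10)
  # Parseval: band power close to amplitude^2 / 2
  expect_equal(lf_dom$lf_ms2, 30^2 / 2, tolerance = 0.15)
  hf_dom <- hrv_features(mk(0.25, 30))
  expect_lt(hf_dom$lf_hf_ratio, 0.1)
  expect_equal(hf_dom$hf_ms2, 30^2 / 2, tolerance = 0.15)
})

test_that("total spectral power accounts for the tachogram variance", {
  set.seed(99)
  n <- 360
  rr <- 1000 + 30 * sin(2 * pi * 0.1 * seq_len(n)) +
    20 * sin(2 * pi * 0.25 * seq_len(n)) + stats::rnorm(n, 0, 5)
  h <- hrv_features(tachogram(cumsum(rr) / 1000))
  expect_equal(h$total_power_ms2, h$rr_variance_ms2, tolerance = 0.10)
})

test_that("moving-window SPR RMS matches closed forms", {
  # constant signal
  tr <- spr_trace(rep(-2e-3, 2000), 200)
  expect_equal(spr_rms(tr, 5)$values, rep(2e-3, 2000))
  # fast full-scale sine: interior RMS = A / sqrt(2)
  t <- (0:3999) / 200
  sine <- spr_trace(8e-3 * sin(2 * pi * 2 * t), 200)
  r <- spr_rms(sine, 5)
  interior <- r$values[600:3400]
  expect_equal(interior, rep(8e-3 / sqrt(2), length(interior)),
               tolerance = 1e-3)
  expect_error(spr_rms(spr_trace(1:10 / 100, 1), 20), "shorter")
})

test_that("scalar SPR features match closed forms and offset behaviour", {
  z <- spr_trace(rep(0, 100), 100)
  fz <- spr_scalar_features(z)
  expect_true(all(unlist(fz) == 0))

  t <- (0:99999) / 10000
  s <- spr_trace(sin(2 * pi * t), 10000)
  f <- spr_scalar_features(s)
  expect_equal(f$variance, 0.5, tolerance = 1e-3)
  expect_equal(f$mean_abs, 2 / pi, tolerance = 1e-3)
  expect_equal(f$max_abs_deriv, 2 * pi, tolerance = 1e-3)
  expect_equal(f$energy, 0.5 * 10, tolerance = 1e-3)  # A^2/2 * duration

  # adding an offset changes energy and mean|x| but not the others
  s_off <- spr_trace(s$values + 0.7, s$fs_hz)
  f_off <- spr_scalar_features(s_off)
  expect_equal(f_off$variance, f$variance, tolerance = 1e-9)
  expect_equal(f_off$mean_abs_deriv, f$mean_abs_deriv, tolerance = 1e-9)
  expect_equal(f_off$max_abs_deriv, f$max_abs_deriv, tolerance = 1e-9)
  expect_gt(f_off$energy, f$energy)
  expect_gt(f_off$mean_abs, f$mean_abs)
})

test_that("stress-like SPR pulses raise the mean moving RMS", {
  calm <- generate_spr(120, pulse_times_s = c(30, 80), pulse_amp_mv = 2)
  stress <- generate_spr(120, pulse_times_s = c(20, 45, 70, 95),
                         pulse_amp_mv = 6)
  expect_gt(mean(spr_rms(stress, 5)$values), 1.5 * mean(spr_rms(calm, 5)$values))
})
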