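# GUM uncertainty propagation, gain estimation, bandwidth and delays.

test_that("input uncertainty matches a Monte-Carlo propagation oracle", {
  at <- bench_attenuator("SPR")
  expect_equal(at$alpha, 5.568e-3)
  expect_equal(at$u_alpha, 8e-6)

  # zero input uncertainties -> zero output uncertainty
  expect_equal(input_uncertainty(uncertain(3.3, 0),
                                 attenuator_spec(0.5, 0))$u, 0)

  u <- input_uncertainty(uncertain(3.3, 1e-3), at)
  expect_equal(u$value, at$alpha * 3.3)
  mc <- with_seed(101, {
    vg <- stats::rnorm(1e5, 3.3, 1e-3)
    al <- stats::rnorm(1e5, at$alpha, at$u_alpha)
    stats::sd(vg * al)
  })
  expect_equal(u$u, mc, tolerance = 0.02)
  expect_error(input_uncertainty(uncertain(-1, 0), at), ">= 0")
})

test_that("output uncertainty combines type A and the ADC type-B model", {
  cfg <- frontend_config("SPR1")
  lsb <- adc_lsb(cfg)
  u_b <- sqrt(lsb^2 / 3 + lsb^2 / 12)
  # identical readings: pure type B
  o <- output_uncertainty(rep(1.2, 10), cfg)
  expect_equal(o$value, 1.2)
  expect_equal(o$u, u_b)
  # sampling-distribution oracle: mean type-A estimate ~ sigma/sqrt(10)
  sigma <- 5e-3
  ua <- with_seed(202, replicate(2000, {
    r <- stats::rnorm(10, 1, sigma)
    sqrt(max(output_uncertainty(r, cfg)$u^2 - u_b^2, 0))
  }))
  expect_equal(mean(ua), sigma / sqrt(10), tolerance = 0.05)
  expect_error(output_uncertainty(rep(1, 7), cfg), "10 readings")
})

# hand-built linearity run (bypasses the simulator) for estimator tests
fake_run <- function(gain = 141, n_amp = 50, noise_sd = 0, seed = 1,
                     cfg = frontend_config("SPR1", gain = gain),
                     distort = function(x) x) {
  amps <- seq(0, 3.3, length.out = n_amp)
  x <- bench_attenuator("SPR")$alpha * amps / (2 * sqrt(2))
  y <- gain * distort(x)
  rms <- with_seed(seed,
    matrix(rep(y, 10) + stats::rnorm(n_amp * 10, 0, noise_sd), n_amp, 10))
  structure(list(amplitudes_vpp = amps, rms_matrix = rms,
                 atten = bench_attenuator("SPR"), cfg = cfg,
                 u_vg_rel = 0.001, f_hz = 1),
            class = "linearity_run")
}

test_that("least-squares slope recovers a noiseless line to machine precision", {
  run <- fake_run(gain = 141)
  fit <- estimate_gain(run, correct_response = FALSE)
  expect_equal(fit$gain$value, 141, tolerance = 1e-12)
  # with no type-A scatter the uncertainty is driven by type B + inputs
  expect_gt(fit$gain$u, 0)
  # scale equivariance: scaling all outputs scales the gain
  run2 <- run
  run2$rms_matrix <- run$rms_matrix * 2.5
  expect_equal(estimate_gain(run2, correct_response = FALSE)$gain$value,
               2.5 * 141, tolerance = 1e-12)
  # degenerate design
  bad <- fake_run()
  bad$amplitudes_vpp[] <- 1
  expect_error(estimate_gain(bad), "degenerate")
})

test_that("analytic gain uncertainty matches Monte-Carlo perturbation", {
  run <- fake_run(gain = 378.3, noise_sd = 2e-3, seed = 33,
                  cfg = frontend_config("ECG1"))
  fit <- estimate_gain(run, correct_response = FALSE)
  x <- fit$x; ux <- fit$ux; y <- fit$y; uy <- fit$uy
  slope <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  mc <- with_seed(404, replicate(4000, {
    slope(x + stats::rnorm(length(x), 0, ux), y + stats::rnorm(length(y), 0, uy))
  }))
  expect_equal(fit$gain$u, stats::sd(mc), tolerance = 0.05)
})

test_that("nonlinearity profile is null for linear data and sees a cubic term", {
  run <- fake_run(gain = 141)
  prof <- nonlinearity_profile(run)
  expect_true(all(abs(prof$deviation_pct_fs) < prof$u_pct_fs + 1e-9))

  # inject a cubic 0.1%-FS distortion; the LS slope absorbs part of it, so
  # the expected profile is (d - c x) / (1 + c), c = cov(x, d) / var(x)
  fs_in <- 20e-3
  runc <- fake_run(gain = 141, distort = function(x)
    x + 0.001 * fs_in * (x / max(x))^3)
  profc <- nonlinearity_profile(runc)
  x <- sprecg:::.linearity_inputs(runc)$value
  d <- 0.001 * fs_in * (x / max(x))^3
  c_abs <- sum((x - mean(x)) * (d - mean(d))) / sum((x - mean(x))^2)
  dev_oracle <- 100 * (d - c_abs * x) / (1 + c_abs) / fs_in
  expect_equal(profc$deviation_pct_fs, dev_oracle, tolerance = 1e-6)
  expect_gt(max(abs(profc$deviation_pct_fs)), 0.02)
})

test_that("simulated linearity run recovers the measured-profile gains", {
  # reduced-size run (15 amplitudes x 3 readings) for speed; the full
  # 50 x 10 matrix is exercised in the acceptance suite
  run <- run_linearity(frontend_config("SPR1"), n_amp = 15, n_readings = 3)
  fit <- estimate_gain(run)
  expect_equal(fit$gain$value, 141.0, tolerance = 2e-3)
  # the raw slope is the 1 Hz response, below the amplifier gain
  expect_lt(fit$slope$value, fit$gain$value)
  # ideal chain stays far below the 0.15% FS hardware bound
  prof <- nonlinearity_profile(run, fit)
  expect_lt(max(abs(prof$deviation_pct_fs)), 0.15)
})

test_that("bandwidth sweep applies the coherent window rule and matches |H|", {
  cfg <- frontend_config("SPR1")
  run <- bandwidth_sweep(cfg, n_freq = 13, f_range = c(0.5, 30), settle_s = 20)
  # window: 10 periods below 10/3 Hz, 3 s above
  expect_equal(run$window_s,
               ifelse(run$freqs_hz < 10 / 3, 10 / run$freqs_hz, 3))
  # measured gain at ~1 Hz within 1% of the closed form
  i1 <- which.min(abs(run$freqs_hz - 1))
  expect_equal(run$gains[i1],
               Mod(frontend_response(cfg, run$freqs_hz[i1])),
               tolerance = 0.01)
  # interpolated upper cutoff near the model's 8.2 Hz
  cuts <- measured_cutoffs(run)
  expect_equal(cuts$upper_hz, upper_cutoff_hz(cfg), tolerance = 0.05)
  # high-pass behaviour: response at the low end below the passband max
  expect_lt(run$gains[1], max(run$gains))
})

test_that("bandwidth sweep refuses frequencies beyond the sensor Nyquist", {
  cfg <- frontend_config("SPR1")
  expect_warning(
    run <- bandwidth_sweep(cfg, n_freq = 5, f_range = c(50, 400), settle_s = 2),
    "Nyquist")
  expect_true(all(run$freqs_hz <= cfg$fs_hz / 2))
})

test_that("FFT-phase delay estimation recovers pure shifts", {
  fs <- 200
  t <- (0:(fs * 30 - 1)) / fs
  mk <- function(shift_s, ch) spr_trace(sin(2 * pi * 1 * (t - shift_s)),
                                        fs, channel = ch)
  traces <- list(SPR1 = mk(0.043, "SPR1"), ECG1 = mk(0, "ECG1"),
                 ECG2 = mk(0, "ECG2"))
  dm <- estimate_delays(traces, f0 = 1)
  # the 43 ms shift is recovered within half a sample
  expect_equal(dm["SPR1", "ECG1"], 0.043, tolerance = 0.0025 / 0.043)
  expect_equal(dm["ECG1", "ECG2"], 0, tolerance = 1e-9)
  # exact antisymmetry, zero diagonal
  expect_equal(unclass(dm) + t(unclass(dm)), matrix(0, 3, 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(diag(dm) == 0))
  # absent carrier
  noise <- with_seed(7, spr_trace(stats::rnorm(fs * 30, sd = 1e-6) + 42, fs))
  expect_error(estimate_delays(list(a = noise, b = noise), f0 = 1),
               "no carrier")
})

test_that("wrapping keeps delays in the principal interval", {
  fs <- 200
  t <- (0:(fs * 20 - 1)) / fs
  a <- spr_trace(sin(2 * pi * 1 * (t - 0.7)), fs)   # 0.7 s shift at 1 Hz
  b <- spr_trace(sin(2 * pi * 1 * t), fs)
  dm <- estimate_delays(list(a = a, b = b), f0 = 1)
  expect_equal(dm["a", "b"], -0.3, tolerance = 1e-6)  # wrapped to (-0.5, 0.5]
})
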