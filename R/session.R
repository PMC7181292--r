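# End-to-end orchestration: the four-channel acquisition pipeline
# (sources -> front ends -> ADC -> packets -> transport -> frames -> decoded
# traces) and the named characterization scenarios.

# small FNV-1a hash so result files can carry a configuration fingerprint
# without external dependencies
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Simulate a full four-channel acquisition
#'
#' Runs native-rate input traces through the complete chain: per-channel
#' analog front end, 200 Hz ADC, SPR packetization (8 samples / 40 ms),
#' simulated transport, ECG-box FIFO alignment into 5 ms frames, wire
#' encoding and decoding. SPR1 is carried by box A, SPR2 by box B.
#'
#' @param spr1,spr2,ecg1,ecg2 native-rate [spr_trace]s at the sensor inputs
#'   (volts). Any of the SPR traces may be `NULL` (a zero trace is used).
#' @param cfgs named list of [frontend_config]s (`SPR1`, `SPR2`, `ECG1`,
#'   `ECG2`); defaults to the measured profile.
#' @param transport a [transport_spec]; default lossless zero-latency.
#' @param frontend apply the analog front ends (`TRUE`, default) or sample
#'   the inputs directly around V_REF scaled to full range (`FALSE`; used to
#'   isolate the digital path when characterizing packetization delay).
#' @return list with `frames` (`frame_set`), `octets` (raw wire stream),
#'   `decoded` (named list of 200 Hz [spr_trace]s in ADC volts, stale flags
#'   set), `input_referred` (same traces referred to the sensor input),
#'   `readings` (raw `adc_reading`s), `loss` ([data_loss_report()]),
#'   `n_lost_packets`.
#' @export
simulate_acquisition <- function(spr1 = NULL, spr2 = NULL, ecg1, ecg2 = NULL,
                                 cfgs = NULL, transport = transport_spec(),
                                 frontend = TRUE) {
  if (is.null(cfgs))
    cfgs <- list(SPR1 = frontend_config("SPR1"), SPR2 = frontend_config("SPR2"),
                 ECG1 = frontend_config("ECG1"), ECG2 = frontend_config("ECG2"))
  dur <- trace_duration(ecg1)
  fs_native <- ecg1$fs_hz
  zero <- function(ch) spr_trace(numeric(round(dur * fs_native)),
                                 fs_hz = fs_native, channel = ch)
  if (is.null(spr1)) spr1 <- zero("SPR1")
  if (is.null(spr2)) spr2 <- zero("SPR2")
  if (is.null(ecg2)) ecg2 <- ecg1
  inputs <- list(SPR1 = spr1, SPR2 = spr2, ECG1 = ecg1, ECG2 = ecg2)
  readings <- lapply(names(inputs), function(ch) {
    cfg <- cfgs[[ch]]
    analog <- if (frontend) {
      apply_frontend(inputs[[ch]], cfg, method = "iir")
    } else {
      # direct sampling: map the input onto the ADC span around V_REF using
      # the nominal conversion gain supply/input_range (no filtering)
      v <- cfg$v_ref_V + inputs[[ch]]$values * (cfg$supply_V / cfg$input_range_V)
      spr_trace(v, fs_hz = inputs[[ch]]$fs_hz, t0_s = inputs[[ch]]$t0_s,
                channel = ch)
    }
    adc_sample(analog, cfg)
  })
  names(readings) <- names(inputs)
  fs <- cfgs$ECG1$fs_hz
  pkts_a <- spr_packetize(readings$SPR1$codes, "A", fs_hz = fs)
  pkts_b <- spr_packetize(readings$SPR2$codes, "B", fs_hz = fs)
  del_a <- simulate_transport(pkts_a, transport)
  del_b <- simulate_transport(pkts_b, transport)
  frames <- align_frames(readings$ECG1, readings$ECG2, del_a, del_b,
                         fs_hz = fs)
  octets <- encode_frames(frames)
  dec <- decode_frames(octets, fs_hz = fs)
  decoded <- list(
    SPR1 = dequantize(dec$spra, cfgs$SPR1, channel = "SPR1", stale = frames$stale_a),
    SPR2 = dequantize(dec$sprb, cfgs$SPR2, channel = "SPR2", stale = frames$stale_b),
    ECG1 = dequantize(dec$ecg1, cfgs$ECG1, channel = "ECG1"),
    ECG2 = dequantize(dec$ecg2, cfgs$ECG2, channel = "ECG2"))
  input_referred <- list(
    SPR1 = dequantize(dec$spra, cfgs$SPR1, TRUE, "SPR1", frames$stale_a),
    SPR2 = dequantize(dec$sprb, cfgs$SPR2, TRUE, "SPR2", frames$stale_b),
    ECG1 = dequantize(dec$ecg1, cfgs$ECG1, TRUE, "ECG1"),
    ECG2 = dequantize(dec$ecg2, cfgs$ECG2, TRUE, "ECG2"))
  list(frames = frames, octets = octets, decoded = decoded,
       input_referred = input_referred, readings = readings,
       loss = data_loss_report(frames),
       n_lost_packets = attr(del_a, "n_lost") + attr(del_b, "n_lost"))
}

#' Run a named characterization or application scenario
#'
#' Composes the generators, the acquisition chain and the requested analysis
#' end to end. Scenarios:
#' \describe{
#'   \item{`jitter`}{5-minute constant-RR synthesized ECG with a 370 ppm
#'     source clock skew (effective RR 1000.37 ms), acquired through the
#'     200 Hz chain; Pan-Tompkins tachogram and [jitter_stats()].}
#'   \item{`delay`}{identical 1 Hz sine on an SPR and an ECG channel,
#'     digitized identically and passed through packetization + FIFO
#'     alignment under the given transport; FFT-phase [estimate_delays()].}
#'   \item{`linearity`}{[run_linearity()] + [estimate_gain()] +
#'     [nonlinearity_profile()] for one channel.}
#'   \item{`bandwidth`}{[bandwidth_sweep()] + [measured_cutoffs()].}
#'   \item{`driving`}{two-condition (calm / stress) SPR + ECG synthesis and
#'     feature extraction: moving-window SPR RMS and HRV features.}
#' }
#'
#' @param scenario one of `"jitter"`, `"delay"`, `"linearity"`,
#'   `"bandwidth"`, `"driving"`.
#' @param seed integer seed; mandatory for stochastic scenarios.
#' @param duration_s scenario duration where applicable.
#' @param out_dir optional output directory: traces CSV, a binary frame
#'   capture when the chain ran, and a results JSON (with config hash and
#'   seed) are written there.
#' @param ... scenario-specific overrides: `rr_ms`, `clock_skew_ppm`,
#'   (`jitter`); `f0_hz`, `transport` (`delay`); `channel` (`linearity`,
#'   `bandwidth`); `n_amp`, `n_readings`, `n_freq` (characterization sizes).
#' @return A list with the scenario's artifacts; element `results` holds the
#'   scalar summary written to the results JSON.
#' @export
run_session <- function(scenario = c("jitter", "delay", "linearity",
                                     "bandwidth", "driving"),
                        seed = 1L, duration_s = NULL, out_dir = NULL, ...) {
  scenario <- match.arg(scenario)
  opts <- list(...)
  cfg_all <- list(scenario = scenario, seed = seed, duration_s = duration_s,
                  opts = opts)
  out <- switch(scenario,
    jitter = .scenario_jitter(seed, duration_s %||% 300,
                              opts$rr_ms %||% 1000,
                              opts$clock_skew_ppm %||% 370),
    delay = .scenario_delay(seed, duration_s %||% 64, opts$f0_hz %||% 1,
                            opts$transport %||% transport_spec()),
    linearity = .scenario_linearity(opts$channel %||% "ECG1",
                                    opts$n_amp %||% 50,
                                    opts$n_readings %||% 10),
    bandwidth = .scenario_bandwidth(opts$channel %||% "SPR1",
                                    opts$n_freq %||% 61),
    driving = .scenario_driving(seed, duration_s %||% 300))
  out$config <- cfg_all
  out$config_hash <- config_hash(cfg_all)
  if (!is.null(out_dir)) .write_session(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.scenario_jitter <- function(seed, duration_s, rr_ms, clock_skew_ppm) {
  src <- generate_ecg(duration_s, rr_ms = rr_ms, clock_skew_ppm = clock_skew_ppm,
                      channel = "ECG1")
  acq <- simulate_acquisition(ecg1 = src)
  tach <- detect_r_peaks(acq$input_referred$ECG1)
  nominal <- rr_ms * (1 + clock_skew_ppm * 1e-6)
  js <- jitter_stats(tach, nominal_rr_ms = nominal,
                     fs_hz = acq$input_referred$ECG1$fs_hz)
  list(source = src, acquisition = acq, tachogram = tach,
       truth_peaks_s = src$meta$r_peaks_s,
       results = list(nominal_rr_ms = nominal,
                      n_peaks = length(tach$peak_times_s),
                      max_rr_dev_ms = js$max_abs_dev_ms,
                      rr_std_ms = js$std_ms,
                      theoretical_std_ms = js$theoretical_std_ms))
}

.scenario_delay <- function(seed, duration_s, f0_hz, transport) {
  src <- generate_sine(1.0, f0_hz, atten = NULL, duration_s = duration_s,
                       fs_hz = 1000)
  # same stimulus scaled into each channel's input range (40% of full scale)
  mk <- function(ch, range_v) spr_trace(src$values * range_v * 0.4,
                                        fs_hz = src$fs_hz, channel = ch)
  acq <- simulate_acquisition(spr1 = mk("SPR1", 20e-3 / 2),
                              ecg1 = mk("ECG1", 10e-3 / 2),
                              transport = transport, frontend = FALSE)
  # drop the cold-start second and analyze an integer number of periods
  fs <- acq$decoded$SPR1$fs_hz
  skip <- round(2 * fs)
  trim <- function(tr) spr_trace(tr$values[-seq_len(skip)], fs_hz = fs,
                                 channel = tr$channel)
  dm <- estimate_delays(list(SPR1 = trim(acq$decoded$SPR1),
                             ECG1 = trim(acq$decoded$ECG1)), f0 = f0_hz)
  list(acquisition = acq, delays = dm,
       results = list(spr_ecg_delay_ms = dm["SPR1", "ECG1"] * 1000,
                      stale_fraction = acq$loss$fraction,
                      n_lost_packets = acq$n_lost_packets))
}

.scenario_linearity <- function(channel, n_amp, n_readings) {
  cfg <- frontend_config(channel)
  run <- run_linearity(cfg, n_amp = n_amp, n_readings = n_readings)
  fit <- estimate_gain(run)
  prof <- nonlinearity_profile(run, fit)
  list(run = run, fit = fit, profile = prof,
       results = list(channel = channel, gain = fit$gain$value,
                      u_gain = fit$gain$u,
                      max_nonlinearity_pct_fs = max(abs(prof$deviation_pct_fs))))
}

.scenario_bandwidth <- function(channel, n_freq) {
  cfg <- frontend_config(channel)
  run <- bandwidth_sweep(cfg, n_freq = n_freq)
  cuts <- measured_cutoffs(run)
  list(run = run, cutoffs = cuts,
       results = list(channel = channel,
                      measured_lower_hz = cuts$lower_hz,
                      measured_upper_hz = cuts$upper_hz,
                      model_lower_hz = lower_cutoff_hz(cfg),
                      model_upper_hz = upper_cutoff_hz(cfg)))
}

.scenario_driving <- function(seed, duration_s) {
  conditions <- list(
    calm = list(n_pulses = 4, amp_mv = c(1.5, 2.5), rr_ms = 800,
                lf_mod_ms = 20, hf_mod_ms = 15),
    stress = list(n_pulses = 8, amp_mv = c(3, 7), rr_ms = 780,
                  lf_mod_ms = 35, hf_mod_ms = 15))
  out <- list()
  for (nm in names(conditions)) {
    cn <- conditions[[nm]]
    s <- derive_seed(seed, match(nm, names(conditions)))
    pulses <- with_seed(s, sort(stats::runif(cn$n_pulses, 15, duration_s - 15)))
    amps <- with_seed(s + 1L, stats::runif(cn$n_pulses, cn$amp_mv[1], cn$amp_mv[2]))
    spr1 <- generate_spr(duration_s, pulses, amps, channel = "SPR1")
    spr2 <- generate_spr(duration_s, pulses, amps * 0.9, channel = "SPR2")
    n_rr <- ceiling(duration_s / (cn$rr_ms / 1000)) + 2
    k <- seq_len(n_rr)
    rr <- cn$rr_ms + cn$lf_mod_ms * sin(2 * pi * 0.1 * k * cn$rr_ms / 1000) +
      cn$hf_mod_ms * sin(2 * pi * 0.25 * k * cn$rr_ms / 1000)
    ecg <- generate_ecg(duration_s, rr_ms = rr, channel = "ECG1")
    acq <- simulate_acquisition(spr1 = spr1, spr2 = spr2, ecg1 = ecg)
    rms1 <- spr_rms(acq$input_referred$SPR1, 5)
    tach <- detect_r_peaks(acq$input_referred$ECG1)
    out[[nm]] <- list(acquisition = acq, spr_rms = rms1, tachogram = tach,
                      hrv = hrv_features(tach),
                      spr_features = spr_scalar_features(acq$input_referred$SPR1))
  }
  res <- list(
    spr_rms_mean_calm_mv = mean(out$calm$spr_rms$values) * 1000,
    spr_rms_mean_stress_mv = mean(out$stress$spr_rms$values) * 1000,
    hr_calm_bpm = out$calm$hrv$mean_hr_bpm,
    hr_stress_bpm = out$stress$hrv$mean_hr_bpm)
  c(out, list(results = res))
}

.write_session <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(written), add = TRUE)
  if (!is.null(out$acquisition)) {
    p <- file.path(out_dir, "traces.csv")
    write_trace(unname(out$acquisition$decoded), p)
    written <- c(written, p, paste0(p, ".json"))
    cp <- file.path(out_dir, "capture.bin")
    write_capture(out$acquisition$frames, cp, config_hash = out$config_hash)
    written <- c(written, cp, paste0(cp, ".json"))
  }
  rp <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    c(out$results, list(config_hash = out$config_hash,
                        seed = out$config$seed,
                        scenario = out$config$scenario)),
    rp, auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, rp)
  ok <- TRUE
  invisible(out_dir)
}

#' Compare HRV features between the sensor chain and a faster reference
#'
#' Generates one native-rate synthetic ECG whose RR process carries a slow
#' (LF, sympathetic-band) and a fast (HF, respiratory sinus arrhythmia)
#' sinusoidal modulation, acquires it once through the full 200 Hz sensor
#' chain and once by direct sampling at a reference rate (emulating a
#' higher-rate commercial recorder on the same subject), and compares the
#' HRV features extracted from the two tachograms.
#'
#' @param duration_s recording length (default 300 s, the usual short-term
#'   HRV duration).
#' @param rr_base_ms baseline RR interval.
#' @param lf_hz,lf_amp_ms LF modulation frequency and amplitude.
#' @param hf_hz,hf_amp_ms HF modulation frequency and amplitude.
#' @param ref_fs_hz reference sampling rate (default 512).
#' @param fs_native_hz master synthesis rate (default 2048).
#' @return list with `sensor` and `reference` [hrv_features], the per-feature
#'   relative deviations in percent (`deviation_pct`) over mean HR, SDNN,
#'   RMSSD, LF and HF, and `max_abs_deviation_pct`.
#' @export
hrv_rate_comparison <- function(duration_s = 300, rr_base_ms = 1000,
                                lf_hz = 0.1, lf_amp_ms = 30,
                                hf_hz = 0.25, hf_amp_ms = 20,
                                ref_fs_hz = 512, fs_native_hz = 2048) {
  n_rr <- ceiling(duration_s / (rr_base_ms / 1000)) + 2L
  tk <- seq_len(n_rr) * rr_base_ms / 1000
  rr <- rr_base_ms + lf_amp_ms * sin(2 * pi * lf_hz * tk) +
    hf_amp_ms * sin(2 * pi * hf_hz * tk)
  src <- generate_ecg(duration_s, rr_ms = rr, fs_hz = fs_native_hz,
                      channel = "ECG1")
  acq <- simulate_acquisition(ecg1 = src)
  tach_sensor <- detect_r_peaks(acq$input_referred$ECG1)
  ref <- spr_trace(interp_trace(src, (seq_len(round(duration_s * ref_fs_hz)) - 1) /
                                  ref_fs_hz),
                   fs_hz = ref_fs_hz, channel = "ECG1")
  tach_ref <- detect_r_peaks(ref)
  h_s <- hrv_features(tach_sensor)
  h_r <- hrv_features(tach_ref)
  keys <- c(mean_hr_bpm = "mean_hr_bpm", sdnn_ms = "sdnn_ms",
            rmssd_ms = "rmssd_ms", lf_ms2 = "lf_ms2", hf_ms2 = "hf_ms2")
  dev <- vapply(keys, function(k)
    100 * (h_s[[k]] - h_r[[k]]) / h_r[[k]], numeric(1))
  list(sensor = h_s, reference = h_r, deviation_pct = dev,
       max_abs_deviation_pct = max(abs(dev)),
       n_beats = length(tach_sensor$rr_ms))
}
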