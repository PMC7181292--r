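# Signal synthesis: calibration sinusoids behind a resistive attenuator,
# PQRST ECG with a configurable RR process, and SPR pulse trains. All
# generators run at a high "native" rate (default 1 kHz) so that the sensor
# chain (200 Hz) and the 512 Hz reference emulation can both resample one
# master signal.

#' Resistive attenuator specification
#'
#' A resistive divider placed between the calibration generator and the
#' sensor input; it emulates the source impedance of the skin. The SPR and
#' ECG bench values are `5.568e-3 (8e-6)` and `1.497e-3 (3e-6)` respectively
#' (value and standard uncertainty, set by 0.1%-tolerance resistors).
#'
#' @param alpha attenuation ratio, strictly in (0, 1).
#' @param u_alpha standard uncertainty of `alpha` (>= 0).
#' @param output_impedance_ohm informational output impedance.
#' @return An object of class `attenuator_spec`.
#' @export
attenuator_spec <- function(alpha, u_alpha = 0, output_impedance_ohm = 1e6) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  if (u_alpha < 0) stop("`u_alpha` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, u_alpha = u_alpha,
                 output_impedance_ohm = output_impedance_ohm),
            class = "attenuator_spec")
}

#' Bench attenuators for the SPR and ECG inputs
#' @param channel `"SPR"` or `"ECG"`.
#' @return An [attenuator_spec] with the bench value for that channel.
#' @export
bench_attenuator <- function(channel = c("SPR", "ECG")) {
  channel <- match.arg(channel)
  switch(channel,
         SPR = attenuator_spec(5.568e-3, 8e-6),
         ECG = attenuator_spec(1.497e-3, 3e-6))
}

#' Generate an attenuated calibration sinusoid
#'
#' Produces `alpha * (A/2) * sin(2*pi*f*t + phase)`: the generator is set in
#' volts peak-to-peak, so the attenuated peak amplitude is
#' `alpha * amplitude_vpp / 2`. With the 3.3 Vpp maximum setting and the SPR
#' attenuator the peak input is 9.19 mV, inside the +-10 mV SPR input range.
#'
#' @param amplitude_vpp generator amplitude, volts peak-to-peak (>= 0).
#' @param frequency_hz sine frequency in Hz (> 0).
#' @param atten an [attenuator_spec] (identity attenuation by default).
#' @param duration_s trace duration in seconds (> 0).
#' @param fs_hz sampling rate of the synthesized trace (> 0).
#' @param phase initial phase in radians (default 0).
#' @param t0_s start time.
#' @param channel channel label for the returned trace.
#' @return An [spr_trace] in volts at the sensor input.
#' @export
generate_sine <- function(amplitude_vpp, frequency_hz, atten = NULL,
                          duration_s, fs_hz = 1000, phase = 0, t0_s = 0,
                          channel = "GEN") {
  if (amplitude_vpp < 0) stop("`amplitude_vpp` must be >= 0", call. = FALSE)
  if (frequency_hz <= 0) stop("`frequency_hz` must be > 0", call. = FALSE)
  if (duration_s <= 0 || fs_hz <= 0)
    stop("`duration_s` and `fs_hz` must be > 0", call. = FALSE)
  alpha <- if (is.null(atten)) 1 else atten$alpha
  n <- round(duration_s * fs_hz)
  t <- t0_s + (seq_len(n) - 1L) / fs_hz
  v <- alpha * (amplitude_vpp / 2) * sin(2 * pi * frequency_hz * t + phase)
  spr_trace(v, fs_hz = fs_hz, t0_s = t0_s, channel = channel,
            meta = list(waveform = "sine", amplitude_vpp = amplitude_vpp,
                        frequency_hz = frequency_hz, alpha = alpha,
                        phase = phase))
}

# PQRST template: five Gaussian lobes. Q and S are symmetric about R so the
# template apex is exactly at the R centre and the generator's reported true
# R-peak times are exact. Amplitudes in millivolt, centres/widths in seconds.
.ecg_template <- function() {
  list(
    lobe  = c("P", "Q", "R", "S", "T"),
    amp_mv   = c(0.12, -0.15, 1.00, -0.15, 0.25),
    centre_s = c(-0.20, -0.035, 0.00, 0.035, 0.28),
    sigma_s  = c(0.025, 0.012, 0.011, 0.012, 0.045)
  )
}

#' Generate a synthetic PQRST ECG at the sensor input
#'
#' Each beat is a sum of five Gaussian lobes (P, Q, R, S, T) with a dominant
#' ~1 mV R lobe, repeated at the requested RR sequence. The true R-peak times
#' are stored in `meta$r_peaks_s` exactly (no detection involved), so
#' downstream detectors can be scored against ground truth. A relative clock
#' skew between the source and the lab timebase is modeled by stretching the
#' time base, `t -> t * (1 + ppm * 1e-6)`.
#'
#' @param duration_s trace duration in seconds.
#' @param rr_ms RR-interval process: either a single value (constant rate,
#'   recycled) or a vector of successive RR intervals in milliseconds. All
#'   values must exceed 200 ms.
#' @param fs_hz native synthesis rate; at least 1000 Hz.
#' @param amplitude_mv R-lobe amplitude at the sensor input in millivolt.
#' @param clock_skew_ppm relative clock offset of the source in parts per
#'   million; positive values slow the source down (longer effective RR).
#' @param t_first_s time of the first R peak.
#' @param channel channel label.
#' @return An [spr_trace] in volts with `meta$r_peaks_s` (true R times, lab
#'   timebase) and `meta$rr_ms` (effective RR intervals, lab timebase).
#' @export
generate_ecg <- function(duration_s, rr_ms = 1000, fs_hz = 1000,
                         amplitude_mv = 1, clock_skew_ppm = 0,
                         t_first_s = 0.5, channel = "ECG1") {
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (fs_hz < 1000)
    stop("native synthesis rate must be at least 1000 Hz", call. = FALSE)
  if (any(rr_ms <= 200))
    stop("all RR intervals must exceed 200 ms", call. = FALSE)
  scale <- 1 + clock_skew_ppm * 1e-6
  # build enough beats to cover the duration (plus one margin beat each side)
  n_needed <- ceiling(duration_s / (min(rr_ms) * scale / 1000)) + 2L
  rr_lab <- rep_len(rr_ms, n_needed) * scale / 1000     # seconds, lab timebase
  peaks <- t_first_s * scale + c(0, cumsum(rr_lab))
  peaks <- peaks[peaks < duration_s + 0.5]
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  tmpl <- .ecg_template()
  v <- numeric(n)
  for (pk in peaks) {
    for (k in seq_along(tmpl$amp_mv)) {
      c_k <- pk + tmpl$centre_s[k] * scale
      s_k <- tmpl$sigma_s[k] * scale
      lo <- max(1L, floor((c_k - 6 * s_k) * fs_hz) + 1L)
      hi <- min(n, ceiling((c_k + 6 * s_k) * fs_hz) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      v[idx] <- v[idx] +
        tmpl$amp_mv[k] * amplitude_mv * exp(-((t[idx] - c_k)^2) / (2 * s_k^2))
    }
  }
  inside <- peaks >= 0 & peaks <= (n - 1L) / fs_hz
  spr_trace(v * 1e-3, fs_hz = fs_hz, channel = channel,
            meta = list(waveform = "ecg_synth",
                        r_peaks_s = peaks[inside],
                        rr_ms = diff(peaks[inside]) * 1000,
                        clock_skew_ppm = clock_skew_ppm,
                        amplitude_mv = amplitude_mv))
}

# Smooth biphasic-capable pulse kernel: difference of exponentials with
# ~1 s rise and ~4 s decay (visible width roughly 10 s), normalized to a
# unit peak so `amp_mv` is the apex value.
.spr_kernel <- function(t, tau_rise = 1, tau_decay = 4) {
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  t_apex <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  k / (exp(-t_apex / tau_decay) - exp(-t_apex / tau_rise))
}

# apex offset of the kernel after its onset, in seconds
.spr_kernel_apex <- function(tau_rise = 1, tau_decay = 4) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Generate an SPR pulse train
#'
#' Baseline plus smooth pulses (difference of two exponentials, rise 1 s,
#' decay 4 s, visible width roughly 10 s). `pulse_times_s` give the *apex*
#' instants and `pulse_amp_mv` the apex amplitudes in millivolt. Optional
#' high-frequency artifact bursts can be superimposed (motion of one hand on
#' the steering wheel only affects that hand's channel).
#'
#' @param duration_s trace duration in seconds.
#' @param pulse_times_s apex times of the SPR pulses (within the duration).
#' @param pulse_amp_mv apex amplitudes in millivolt, recycled; values beyond
#'   +-10 mV trigger a warning (the front end will saturate) and are kept.
#' @param pulse_width_s nominal visible pulse width; the rise/decay pair is
#'   scaled by `pulse_width_s / 10`.
#' @param baseline_mv constant baseline in millivolt.
#' @param artifact optional list
#'   `list(from_s=, to_s=, amp_mv=, band_hz=c(lo, hi))` describing a noise
#'   burst; `NULL` for none.
#' @param fs_hz native synthesis rate.
#' @param seed integer seed for the artifact noise (mandatory when
#'   `artifact` is given).
#' @param channel channel label.
#' @return An [spr_trace] in volts; `meta$clipped` flags apexes beyond the
#'   +-10 mV input range.
#' @export
generate_spr <- function(duration_s, pulse_times_s = numeric(),
                         pulse_amp_mv = 5, pulse_width_s = 10,
                         baseline_mv = 0, artifact = NULL, fs_hz = 1000,
                         seed = NULL, channel = "SPR1") {
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (any(pulse_width_s <= 0)) stop("pulse widths must be > 0", call. = FALSE)
  if (length(pulse_times_s) &&
      (min(pulse_times_s) < 0 || max(pulse_times_s) > duration_s))
    stop("pulse times must lie within the duration", call. = FALSE)
  amps <- rep_len(pulse_amp_mv, length(pulse_times_s))
  clipped <- abs(amps) > 10
  if (any(clipped))
    warning("pulse amplitude beyond +-10 mV: front end will saturate")
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  v <- rep(baseline_mv, n)
  w <- pulse_width_s / 10
  apex <- .spr_kernel_apex(1 * w, 4 * w)
  for (i in seq_along(pulse_times_s)) {
    onset <- pulse_times_s[i] - apex
    v <- v + amps[i] * .spr_kernel(t - onset, 1 * w, 4 * w)
  }
  if (!is.null(artifact)) {
    if (is.null(seed)) stop("`seed` is mandatory for artifact bursts", call. = FALSE)
    v <- v + .artifact_burst(t, fs_hz, artifact, seed)
  }
  spr_trace(v * 1e-3, fs_hz = fs_hz, channel = channel,
            meta = list(waveform = "spr_synth", pulse_times_s = pulse_times_s,
                        pulse_amp_mv = amps, clipped = clipped))
}

# band-limited noise burst, deterministic for a fixed seed
.artifact_burst <- function(t, fs_hz, artifact, seed) {
  stopifnot(all(c("from_s", "to_s", "amp_mv") %in% names(artifact)))
  band <- if (is.null(artifact$band_hz)) c(10, 45) else artifact$band_hz
  out <- numeric(length(t))
  sel <- t >= artifact$from_s & t <= artifact$to_s
  if (!any(sel)) return(out)
  noise <- with_seed(seed, stats::rnorm(sum(sel)))
  bf <- signal::butter(2, pmin(band / (fs_hz / 2), 0.99), type = "pass")
  burst <- as.numeric(signal::filtfilt(bf, noise))
  sdb <- stats::sd(burst)
  if (sdb > 0) burst <- burst / sdb
  # taper the burst edges with a raised cosine so it switches on smoothly
  m <- sum(sel)
  ramp <- pmin(1, pmin(seq_len(m), rev(seq_len(m))) / max(1, round(0.05 * m)))
  out[sel] <- artifact$amp_mv * burst * ramp
  out
}
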