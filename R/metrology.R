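# Metrological characterization: linearity with GUM uncertainty propagation,
# bandwidth sweep, FFT-phase delay estimation and data-loss accounting.
# Uncertainty bookkeeping follows standard GUM practice: type A from the
# scatter of repeated readings, type B from rectangular bounds, combined by
# root-sum-square with analytic sensitivity coefficients.

#' Value with standard uncertainty
#'
#' @param value measured/estimated value.
#' @param u standard uncertainty, same units, `>= 0`.
#' @return An object of class `uncertain`.
#' @export
uncertain <- function(value, u) {
  if (any(u < 0)) stop("standard uncertainty must be >= 0", call. = FALSE)
  structure(list(value = value, u = u), class = "uncertain")
}

#' @export
print.uncertain <- function(x, ...) {
  cat(sprintf("%.6g (u = %.3g)\n", x$value, x$u))
  invisible(x)
}

#' Propagate the attenuator onto a generator setting
#'
#' `V_in = alpha * V_g` with
#' `u(V_in) = sqrt((alpha * u(V_g))^2 + (V_g * u(alpha))^2)`.
#'
#' @param vg an [uncertain] generator voltage (any consistent unit).
#' @param atten an [attenuator_spec].
#' @return An [uncertain] input voltage.
#' @export
input_uncertainty <- function(vg, atten) {
  stopifnot(inherits(vg, "uncertain"), inherits(atten, "attenuator_spec"))
  if (any(vg$value < 0)) stop("generator amplitude must be >= 0", call. = FALSE)
  uncertain(atten$alpha * vg$value,
            sqrt((atten$alpha * vg$u)^2 + (vg$value * atten$u_alpha)^2))
}

# ADC type-B standard uncertainty at the amplifier output:
# INL treated as rectangular +-INL*LSB (u = INL*LSB/sqrt(3)) combined with
# quantization u = LSB/sqrt(12).
adc_type_b <- function(cfg) {
  lsb <- adc_lsb(cfg)
  sqrt((cfg$adc_inl_lsb * lsb)^2 / 3 + lsb^2 / 12)
}

#' Combine repeated RMS readings into an uncertain output voltage
#'
#' Value = mean of the readings; type A = standard deviation of the sample
#' mean (`sd / sqrt(n)`); type B = ADC INL + quantization model; combined by
#' root-sum-square.
#'
#' @param rms_row numeric vector of exactly `n_readings` RMS readings (V).
#' @param cfg a [frontend_config] (for the type-B model).
#' @param n_readings required number of readings (default 10).
#' @return An [uncertain] mean output voltage.
#' @export
output_uncertainty <- function(rms_row, cfg, n_readings = 10) {
  if (length(rms_row) != n_readings)
    stop("expected exactly ", n_readings, " readings", call. = FALSE)
  u_a <- stats::sd(rms_row) / sqrt(n_readings)
  uncertain(mean(rms_row), sqrt(u_a^2 + adc_type_b(cfg)^2))
}

#' Simulate a full linearity run of the chain
#'
#' Drives the simulated chain with a 1 Hz sinusoid at `n_amp` linearly
#' spaced generator amplitudes in `[0, 3.3]` Vpp behind the channel's
#' attenuator and acquires `n_readings` RMS values per amplitude, each
#' evaluated over 10 periods of the stimulus at the sensor output (AC
#' coupled: the V_REF operating point is removed before the RMS). Returns
#' the amplitude vector and the `n_amp x n_readings` RMS matrix.
#'
#' @param cfg a [frontend_config].
#' @param atten an [attenuator_spec]; defaults to the bench attenuator for
#'   the channel.
#' @param n_amp number of generator amplitudes (default 50).
#' @param n_readings RMS readings per amplitude (default 10).
#' @param f_hz stimulus frequency (default 1 Hz, centre of the band).
#' @param max_vpp top generator amplitude (default 3.3 Vpp).
#' @param fs_native_hz native synthesis rate.
#' @param u_vg_rel relative standard uncertainty of the generator amplitude
#'   setting (default 0.1%).
#' @param settle_s head transient discarded before the first reading
#'   (default 20 s, several low-side time constants).
#' @return An object of class `linearity_run` with fields
#'   `amplitudes_vpp`, `rms_matrix`, `atten`, `cfg`, `u_vg_rel`, `f_hz`.
#' @export
run_linearity <- function(cfg, atten = NULL, n_amp = 50, n_readings = 10,
                          f_hz = 1, max_vpp = 3.3, fs_native_hz = 1000,
                          u_vg_rel = 0.001, settle_s = 20) {
  stopifnot(inherits(cfg, "frontend_config"))
  if (is.null(atten))
    atten <- bench_attenuator(if (grepl("^SPR", cfg$channel)) "SPR" else "ECG")
  amps <- seq(0, max_vpp, length.out = n_amp)
  per <- 10 / f_hz                       # one reading = 10 periods
  dur <- settle_s + n_readings * per
  rms <- matrix(NA_real_, n_amp, n_readings)
  for (i in seq_len(n_amp)) {
    src <- generate_sine(amps[i], f_hz, atten, duration_s = dur,
                         fs_hz = fs_native_hz, channel = cfg$channel)
    out <- apply_frontend(src, cfg, method = "iir")
    reading <- adc_sample(out, cfg)
    v <- dequantize(reading, cfg)$values
    nper <- round(per * cfg$fs_hz)
    i0 <- round(settle_s * cfg$fs_hz)
    for (r in seq_len(n_readings)) {
      seg <- v[(i0 + (r - 1L) * nper + 1L):(i0 + r * nper)]
      seg <- seg - mean(seg)
      rms[i, r] <- sqrt(mean(seg^2))
    }
  }
  structure(list(amplitudes_vpp = amps, rms_matrix = rms, atten = atten,
                 cfg = cfg, u_vg_rel = u_vg_rel, f_hz = f_hz),
            class = "linearity_run")
}

# input RMS voltages (V) and their uncertainties for a linearity run
.linearity_inputs <- function(run) {
  vg_rms <- run$amplitudes_vpp / (2 * sqrt(2))
  input_uncertainty(uncertain(vg_rms, run$u_vg_rel * vg_rms), run$atten)
}

#' Least-squares gain estimate with GUM uncertainty
#'
#' The gain is the ordinary least-squares slope of mean output RMS against
#' input RMS. Uncertainty is propagated analytically through the slope
#' formula: with `S_xx = sum((x - mean(x))^2)`,
#' `dG/dy_i = (x_i - mean(x)) / S_xx` and
#' `dG/dx_i = ((y_i - mean(y)) - 2 G (x_i - mean(x))) / S_xx`,
#' combined by root-sum-square with `u(x_i)` (attenuator + generator) and
#' `u(y_i)` (type A + ADC type B).
#'
#' The raw least-squares slope equals the chain response at the stimulus
#' frequency, `G * |H(f0)| / G_dc-normalization`; with
#' `correct_response = TRUE` (the default) the slope is divided by the
#' model's normalized magnitude at `f0` so the reported value estimates the
#' amplifier gain itself (the slope is also kept, as `slope`).
#'
#' @param run a `linearity_run`.
#' @param correct_response divide the slope by the normalized front-end
#'   magnitude at the stimulus frequency (default `TRUE`); set `FALSE` when
#'   the readings did not pass through the filter model.
#' @return An object of class `gain_fit`: [uncertain] `gain` and `slope`
#'   plus the per-point inputs/outputs used.
#' @export
estimate_gain <- function(run, correct_response = TRUE) {
  stopifnot(inherits(run, "linearity_run"))
  x_u <- .linearity_inputs(run)
  x <- x_u$value
  if (length(unique(x)) < 2)
    stop("degenerate design: need >= 2 distinct amplitudes", call. = FALSE)
  y_u <- apply(run$rms_matrix, 1, output_uncertainty, cfg = run$cfg,
               n_readings = ncol(run$rms_matrix))
  y <- vapply(y_u, function(e) e$value, numeric(1))
  uy <- vapply(y_u, function(e) e$u, numeric(1))
  ux <- x_u$u
  sxx <- sum((x - mean(x))^2)
  g <- sum((x - mean(x)) * (y - mean(y))) / sxx
  dg_dy <- (x - mean(x)) / sxx
  dg_dx <- ((y - mean(y)) - 2 * g * (x - mean(x))) / sxx
  ug <- sqrt(sum((dg_dy * uy)^2) + sum((dg_dx * ux)^2))
  corr <- if (correct_response)
    Mod(frontend_response(run$cfg, run$f_hz)) / run$cfg$gain else 1
  structure(list(gain = uncertain(g / corr, ug / corr),
                 slope = uncertain(g, ug),
                 response_correction = corr,
                 x = x, ux = ux, y = y, uy = uy,
                 cfg = run$cfg),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> %s: G = %.4g +- %.2g (least squares over %d amplitudes)\n",
              x$cfg$channel, x$gain$value, x$gain$u, length(x$x)))
  invisible(x)
}

#' Relative deviation from linearity, in percent of full scale
#'
#' For each amplitude, `100 * (y_i / G - x_i) / FS` where `FS` is the
#' input-referred full scale of the channel (20 mV SPR, 10 mV ECG). Error
#' bars combine the input uncertainty and the output uncertainty referred
#' through the gain.
#'
#' @param run a `linearity_run`.
#' @param fit optionally, a precomputed `gain_fit` for the same run.
#' @return data.frame with `amplitude_vpp`, `v_in_V`, `deviation_pct_fs`,
#'   `u_pct_fs`.
#' @export
nonlinearity_profile <- function(run, fit = NULL) {
  if (is.null(fit)) fit <- estimate_gain(run)
  fs <- run$cfg$input_range_V
  g <- fit$slope$value
  dev <- (fit$y / g - fit$x) / fs * 100
  u <- sqrt((fit$uy / g)^2 + fit$ux^2) / fs * 100
  data.frame(amplitude_vpp = run$amplitudes_vpp, v_in_V = fit$x,
             deviation_pct_fs = dev, u_pct_fs = u)
}

#' Bandwidth sweep of the simulated chain
#'
#' Drives the chain with an attenuated 3.3 Vpp sinusoid at logarithmically
#' spaced frequencies and measures `|G(f)| = RMS_out / RMS_in` per step. The
#' observation window follows the coherent-sampling rule: exactly 10 periods
#' of the stimulus when `f < 10/3` Hz, otherwise 3 s. Frequencies at or
#' above the sensor Nyquist rate are excluded with a warning.
#'
#' @param cfg a [frontend_config].
#' @param atten attenuator (bench value for the channel when `NULL`).
#' @param n_freq number of steps (default 61).
#' @param f_range frequency range in Hz (default `c(0.1, 100)`).
#' @param amplitude_vpp generator amplitude (default 3.3 Vpp).
#' @param fs_native_hz native synthesis rate.
#' @param settle_s head transient discarded before the window.
#' @return An object of class `bandwidth_run`: `freqs_hz`, `gains`,
#'   `window_s`, `cfg`.
#' @export
bandwidth_sweep <- function(cfg, atten = NULL, n_freq = 61,
                            f_range = c(0.1, 100), amplitude_vpp = 3.3,
                            fs_native_hz = 1000, settle_s = 20) {
  stopifnot(inherits(cfg, "frontend_config"))
  if (is.null(atten))
    atten <- bench_attenuator(if (grepl("^SPR", cfg$channel)) "SPR" else "ECG")
  freqs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freq))
  nyq <- cfg$fs_hz / 2
  if (any(freqs > nyq)) {
    warning(sum(freqs > nyq), " step(s) above the sensor Nyquist rate excluded")
    freqs <- freqs[freqs <= nyq]
  }
  win <- ifelse(freqs < 10 / 3, 10 / freqs, 3)
  gains <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    dur <- settle_s + win[i] + 1 / cfg$fs_hz
    src <- generate_sine(amplitude_vpp, f, atten, duration_s = dur,
                         fs_hz = fs_native_hz, channel = cfg$channel)
    out <- apply_frontend(src, cfg, method = "iir")
    v <- dequantize(adc_sample(out, cfg), cfg)$values
    i0 <- round(settle_s * cfg$fs_hz)
    nwin <- round(win[i] * cfg$fs_hz)
    seg <- v[(i0 + 1L):(i0 + nwin)]
    seg <- seg - mean(seg)
    rms_in <- atten$alpha * amplitude_vpp / (2 * sqrt(2))
    gains[i] <- sqrt(mean(seg^2)) / rms_in
  }
  structure(list(freqs_hz = freqs, gains = gains, window_s = win, cfg = cfg),
            class = "bandwidth_run")
}

#' -3 dB cutoffs from measured bandwidth points
#'
#' Locates the -3 dB crossings of a measured `|G(f)|` profile relative to
#' its maximum, by log-log linear interpolation between the bracketing
#' measured points.
#'
#' @param run a `bandwidth_run`.
#' @return list with `lower_hz` and `upper_hz` (NA when the crossing lies
#'   outside the swept range).
#' @export
measured_cutoffs <- function(run) {
  f <- run$freqs_hz
  g <- run$gains
  imax <- which.max(g)
  target <- g[imax] / sqrt(2)
  cross <- function(idx_range) {
    idx <- idx_range[g[idx_range] > 0]
    below <- which(g[idx] < target)
    if (!length(below)) return(NA_real_)
    if (idx[1] < imax) {           # lower side: last below-target point
      i2 <- idx[max(below)] + 1L
      i1 <- i2 - 1L
    } else {                        # upper side: first below-target point
      i2 <- idx[min(below)]
      i1 <- i2 - 1L
    }
    if (i1 < 1 || i2 > length(f)) return(NA_real_)
    lf <- log(f[c(i1, i2)]); lg <- log(g[c(i1, i2)])
    exp(lf[1] + (log(target) - lg[1]) * diff(lf) / diff(lg))
  }
  list(lower_hz = if (imax > 1) cross(1:(imax - 1L)) else NA_real_,
       upper_hz = if (imax < length(f)) cross((imax + 1L):length(f)) else NA_real_)
}

#' Pairwise delays between channels from FFT phases
#'
#' All traces share one sinusoidal stimulus at `f0`; the phase of each trace
#' is read at the FFT bin nearest `f0` (the analysis length is truncated to
#' an integer number of stimulus periods so the bin is leakage-free) and
#' `dt[j, k] = (phi_k - phi_j) / (2 pi f0)`, wrapped to
#' `(-1/(2 f0), +1/(2 f0)]`. Positive `dt[j, k]` means channel `j` lags
#' channel `k`.
#'
#' @param traces named list of [spr_trace]s of equal rate.
#' @param f0 stimulus frequency in Hz.
#' @param snr_min minimum ratio of the carrier bin magnitude to the median
#'   spectral magnitude; below it a no-carrier error is raised.
#' @return An object of class `delay_matrix`: an antisymmetric matrix of
#'   delays in seconds.
#' @export
estimate_delays <- function(traces, f0, snr_min = 10) {
  stopifnot(length(traces) >= 2)
  fs <- traces[[1]]$fs_hz
  n_all <- vapply(traces, function(tr) length(tr$values), integer(1))
  if (length(unique(n_all)) != 1)
    stop("all traces must have the same length", call. = FALSE)
  n <- floor(n_all[1] / (fs / f0)) * (fs / f0)
  n <- floor(n)
  if (n < fs / f0) stop("trace shorter than one stimulus period", call. = FALSE)
  phases <- vapply(traces, function(tr) {
    x <- tr$values[seq_len(n)] - mean(tr$values[seq_len(n)])
    sp <- stats::fft(x)
    half <- sp[2:floor(n / 2)]
    bin <- which.min(abs((seq_len(n) - 1) / n * fs - f0))
    if (Mod(sp[bin]) < snr_min * stats::median(Mod(half)))
      stop("no carrier at ", f0, " Hz in channel ", tr$channel, call. = FALSE)
    Arg(sp[bin])
  }, numeric(1))
  m <- length(phases)
  dt <- outer(phases, phases, function(pj, pk) pk - pj) / (2 * pi * f0)
  # wrap to (-T0/2, +T0/2]
  T0 <- 1 / f0
  dt <- dt - T0 * ceiling(dt / T0 - 0.5)
  nm <- names(traces)
  if (is.null(nm)) nm <- vapply(traces, function(tr) tr$channel, character(1))
  dimnames(dt) <- list(nm, nm)
  structure(dt, class = c("delay_matrix", class(dt)))
}

#' @export
print.delay_matrix <- function(x, ...) {
  cat("<delay_matrix> pairwise delays (ms); [j, k] > 0 means j lags k\n")
  print(round(unclass(x) * 1000, 3))
  invisible(x)
}
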