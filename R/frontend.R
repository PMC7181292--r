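# Analog front end and ADC. The conditioning chain is a passive first-order
# input high-pass plus a DC-compensation loop (together a double high-pass
# pole at 1/(2*pi*tau_L) = 0.05 Hz with two zeros at the origin), an
# instrumentation amplifier of gain G, and a triple-real-pole anti-alias
# stage with time constant tau_H. In the Fourier domain, around the V_REF
# operating point:
#
#   V_out(jw) = V_REF + G * (tau_L jw)^2 /
#               [ (1 + tau_L jw)^2 (1 + tau_H jw)^3 ] * V_in(jw)
#
# The output is digitized by a 12-bit ADC over [0, 3.3] V at 200 Hz.

#' Front-end configuration
#'
#' Holds every symbol of the conditioning chain plus the ADC parameters.
#' Two gain profiles ship with the package: `"design"` (G_SPR = 160,
#' G_ECG = 370) and `"measured"` (the bench least-squares values 141.0,
#' 141.2, 378.3, 376.9); the measured profile is the default for
#' reproduction runs.
#'
#' @param channel `"SPR1"`, `"SPR2"`, `"ECG1"` or `"ECG2"`.
#' @param gain amplifier gain; when `NULL`, looked up from `gain_profile`.
#' @param gain_profile `"measured"` or `"design"`.
#' @param tau_L_s low-side time constant (default `1/(2*pi*0.05)` s, i.e. a
#'   0.05 Hz pole).
#' @param tau_H_s high-side (anti-alias) time constant; default 10 ms for SPR
#'   channels and 1 ms for ECG channels.
#' @param v_ref_V reference voltage, default 1.65 V (mid-supply).
#' @param fs_hz ADC sampling rate, default 200 Hz.
#' @param adc_bits ADC resolution, default 12.
#' @param supply_V ADC full-scale span, default 3.3 V.
#' @param input_range_V full-scale differential input span: 20 mV for SPR
#'   (+-10 mV), 10 mV for ECG (+-5 mV).
#' @param adc_inl_lsb ADC integral non-linearity bound in LSB (rectangular
#'   type-B model), default 1.
#' @return An object of class `frontend_config`.
#' @export
frontend_config <- function(channel = c("SPR1", "SPR2", "ECG1", "ECG2"),
                            gain = NULL,
                            gain_profile = c("measured", "design"),
                            tau_L_s = 1 / (2 * pi * 0.05),
                            tau_H_s = NULL,
                            v_ref_V = 1.65, fs_hz = 200, adc_bits = 12,
                            supply_V = 3.3, input_range_V = NULL,
                            adc_inl_lsb = 1) {
  channel <- match.arg(channel)
  gain_profile <- match.arg(gain_profile)
  is_spr <- grepl("^SPR", channel)
  if (is.null(tau_H_s)) tau_H_s <- if (is_spr) 10e-3 else 1e-3
  if (is.null(input_range_V)) input_range_V <- if (is_spr) 20e-3 else 10e-3
  if (is.null(gain)) {
    gain <- switch(gain_profile,
      measured = c(SPR1 = 141.0, SPR2 = 141.2, ECG1 = 378.3, ECG2 = 376.9)[[channel]],
      design   = if (is_spr) 160 else 370)
  }
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  if (!(tau_L_s > tau_H_s && tau_H_s > 0))
    stop("need tau_L_s > tau_H_s > 0", call. = FALSE)
  if (!(v_ref_V > 0 && v_ref_V < supply_V))
    stop("need 0 < v_ref_V < supply_V", call. = FALSE)
  if (adc_bits < 1) stop("`adc_bits` must be >= 1", call. = FALSE)
  structure(list(channel = channel, gain = gain, gain_profile = gain_profile,
                 tau_L_s = tau_L_s, tau_H_s = tau_H_s, v_ref_V = v_ref_V,
                 fs_hz = fs_hz, adc_bits = adc_bits, supply_V = supply_V,
                 input_range_V = input_range_V, adc_inl_lsb = adc_inl_lsb),
            class = "frontend_config")
}

#' @export
print.frontend_config <- function(x, ...) {
  cat(sprintf(
    "<frontend_config> %s: G = %.4g (%s), tau_L = %.4g s, tau_H = %.4g s\n",
    x$channel, x$gain, x$gain_profile, x$tau_L_s, x$tau_H_s))
  cat(sprintf("  ADC: %d bit over %.3g V @ %g Hz, V_REF = %.3g V, input FS %.3g V\n",
              x$adc_bits, x$supply_V, x$fs_hz, x$v_ref_V, x$input_range_V))
  invisible(x)
}

#' ADC quantization step at the amplifier output
#' @param cfg a [frontend_config].
#' @return LSB size in volts (`supply_V / 2^adc_bits`).
#' @export
adc_lsb <- function(cfg) cfg$supply_V / 2^cfg$adc_bits

#' Input-referred resolution of a channel
#'
#' One ADC code referred to the differential input:
#' `input_range_V / 2^adc_bits`. Evaluates to 4.9 uV for the SPR channels
#' (20 mV range) and 2.4 uV for the ECG channels (10 mV range).
#'
#' @param cfg a [frontend_config].
#' @return resolution in volts at the input.
#' @export
input_resolution <- function(cfg) cfg$input_range_V / 2^cfg$adc_bits

#' Complex front-end frequency response (closed form)
#'
#' Evaluates the AC part of the transfer function,
#' `G (tau_L jw)^2 / [(1 + tau_L jw)^2 (1 + tau_H jw)^3]`, at the requested
#' frequencies. The DC term (`V_REF`) is not included.
#'
#' @param cfg a [frontend_config].
#' @param f_hz frequencies in Hz.
#' @return complex vector of the same length as `f_hz`.
#' @export
frontend_response <- function(cfg, f_hz) {
  jw <- 2i * pi * f_hz
  cfg$gain * (cfg$tau_L_s * jw)^2 /
    ((1 + cfg$tau_L_s * jw)^2 * (1 + cfg$tau_H_s * jw)^3)
}

# generic -3 dB locator on a magnitude function: finds the passband maximum
# then bisects |H| = max/sqrt(2) on the requested side
.find_cutoff <- function(magfun, side = c("upper", "lower"),
                         f_lo = 1e-4, f_hi = 1e4) {
  side <- match.arg(side)
  opt <- stats::optimize(function(lf) -magfun(exp(lf)),
                         lower = log(f_lo), upper = log(f_hi), tol = 1e-12)
  f_max <- exp(opt$minimum)
  target <- magfun(f_max) / sqrt(2)
  g <- function(f) magfun(f) - target
  if (side == "upper") {
    hi <- f_max
    while (g(hi) > 0 && hi < f_hi * 10) hi <- hi * 2
    stats::uniroot(g, c(f_max, hi), tol = 1e-10)$root
  } else {
    lo <- f_max
    while (g(lo) > 0 && lo > f_lo / 10) lo <- lo / 2
    stats::uniroot(g, c(lo, f_max), tol = 1e-10)$root
  }
}

#' Upper -3 dB cutoff of a front-end configuration
#'
#' Numerically locates the frequency above the response maximum where
#' `|H(f)| = max|H| / sqrt(2)`, on the closed-form magnitude. With the 10 ms
#' SPR anti-alias stage this gives 8.2 Hz (prints as 8 Hz); with the 1 ms ECG
#' stage the model gives 81 Hz.
#'
#' @param cfg a [frontend_config].
#' @return cutoff frequency in Hz.
#' @export
upper_cutoff_hz <- function(cfg) {
  .find_cutoff(function(f) Mod(frontend_response(cfg, f)), "upper")
}

#' Lower -3 dB cutoff of a front-end configuration
#'
#' The double 0.05 Hz high-pass pole places the lower -3 dB point at
#' approximately 0.08 Hz.
#'
#' @param cfg a [frontend_config].
#' @return cutoff frequency in Hz.
#' @export
lower_cutoff_hz <- function(cfg) {
  .find_cutoff(function(f) Mod(frontend_response(cfg, f)), "lower")
}

# first-order bilinear sections for the streaming back end.
# H(s) = G * s^2 / [(s + a)^2 (s + b)^3] * (1/tau_H^3) with a = 1/tau_L,
# b = 1/tau_H, factored into two s/(s+a) high-pass sections and three
# b/(s+b) low-pass sections; each is mapped with s = K (1-z^-1)/(1+z^-1),
# K = 2 fs.
.frontend_sections <- function(cfg, fs_native_hz) {
  K <- 2 * fs_native_hz
  a <- 1 / cfg$tau_L_s
  b <- 1 / cfg$tau_H_s
  hp <- list(b = c(K, -K) / (K + a), a = c(1, (a - K) / (K + a)))
  lp <- list(b = c(b, b) / (K + b), a = c(1, (b - K) / (K + b)))
  list(hp = hp, lp = lp)
}

#' Apply the analog front end to an input trace
#'
#' Two interchangeable back ends are provided. `method = "iir"` runs a causal
#' discrete-time filter (cascade of bilinear-transformed first-order
#' sections) and is the streaming model used by the session pipeline;
#' `method = "fft"` multiplies by the closed-form frequency response
#' (circular, for steady-state characterization). Both add the `V_REF`
#' operating point. For a constant input, the steady-state output is exactly
#' `V_REF` (the zeros at the origin kill DC).
#'
#' @param input an [spr_trace] at the native rate, in volts at the sensor
#'   input.
#' @param cfg a [frontend_config].
#' @param method `"iir"` (causal streaming filter) or `"fft"` (steady-state
#'   frequency-domain back end).
#' @return An [spr_trace] at the same rate, in volts at the amplifier output.
#' @export
apply_frontend <- function(input, cfg, method = c("iir", "fft")) {
  method <- match.arg(method)
  stopifnot(inherits(input, "spr_trace"), inherits(cfg, "frontend_config"))
  if (length(input$values) == 0) stop("empty input trace", call. = FALSE)
  x <- input$values
  if (method == "iir") {
    sec <- .frontend_sections(cfg, input$fs_hz)
    y <- x
    y <- as.numeric(signal::filter(sec$hp$b, sec$hp$a, y))
    y <- as.numeric(signal::filter(sec$hp$b, sec$hp$a, y))
    for (i in 1:3) y <- as.numeric(signal::filter(sec$lp$b, sec$lp$a, y))
    y <- cfg$gain * y
  } else {
    n <- length(x)
    f <- c(0, seq_len(n - 1)) / n * input$fs_hz
    f[f > input$fs_hz / 2] <- f[f > input$fs_hz / 2] - input$fs_hz
    H <- frontend_response(cfg, f)
    y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
  }
  meta <- input$meta
  meta$frontend <- list(channel = cfg$channel, gain = cfg$gain, method = method)
  spr_trace(y + cfg$v_ref_V, fs_hz = input$fs_hz, t0_s = input$t0_s,
            channel = input$channel, stale = input$stale, meta = meta)
}

#' Sample an analog trace with the 12-bit ADC
#'
#' Samples the amplifier-output trace on the ADC grid
#' `t = t0 + phase_offset_s + k / fs` by linear interpolation, clips to
#' `[0, supply_V]` and rounds to the nearest code in `[0, 2^bits - 1]`.
#' Clipping sets a per-sample saturation flag instead of raising.
#'
#' @param analog an [spr_trace] covering the sampling window (volts at the
#'   amplifier output, V_REF included).
#' @param cfg a [frontend_config].
#' @param phase_offset_s offset of the ADC sampling grid relative to the
#'   trace start (e.g. the 72 us sequential-sampling skew of the second ECG
#'   channel); default 0.
#' @param duration_s optional: number of seconds to sample (defaults to the
#'   available trace duration).
#' @return An object of class `adc_reading`: integer `codes`, `fs_hz`,
#'   `lsb_V`, `t0_s` (time of code 1), logical `saturated`.
#' @export
adc_sample <- function(analog, cfg, phase_offset_s = 0, duration_s = NULL) {
  stopifnot(inherits(analog, "spr_trace"), inherits(cfg, "frontend_config"))
  if (is.null(duration_s)) duration_s <- trace_duration(analog)
  n <- floor((duration_s - phase_offset_s) * cfg$fs_hz - 1e-9) + 1L
  tq <- analog$t0_s + phase_offset_s + (seq_len(n) - 1L) / cfg$fs_hz
  v <- interp_trace(analog, tq)
  lsb <- adc_lsb(cfg)
  saturated <- v < 0 | v > cfg$supply_V
  v <- pmin(pmax(v, 0), cfg$supply_V)
  codes <- pmin(round(v / lsb), 2^cfg$adc_bits - 1)
  structure(list(codes = as.integer(codes), fs_hz = cfg$fs_hz, lsb_V = lsb,
                 t0_s = tq[1], saturated = saturated, channel = analog$channel),
            class = "adc_reading")
}

#' @export
print.adc_reading <- function(x, ...) {
  cat(sprintf("<adc_reading> %s: %d codes @ %g Hz, LSB = %.4g uV\n",
              x$channel, length(x$codes), x$fs_hz, x$lsb_V * 1e6))
  if (any(x$saturated)) cat(sprintf("  saturated samples: %d\n", sum(x$saturated)))
  invisible(x)
}

#' Convert ADC codes back to volts
#'
#' @param reading an `adc_reading` (or an integer code vector).
#' @param cfg a [frontend_config].
#' @param input_referred when `TRUE`, removes `V_REF` and divides by the
#'   gain, giving volts at the sensor input.
#' @param channel channel label for the returned trace.
#' @param stale optional staleness flags.
#' @return An [spr_trace].
#' @export
dequantize <- function(reading, cfg, input_referred = FALSE,
                       channel = NULL, stale = NULL) {
  codes <- if (inherits(reading, "adc_reading")) reading$codes else reading
  fs <- if (inherits(reading, "adc_reading")) reading$fs_hz else cfg$fs_hz
  t0 <- if (inherits(reading, "adc_reading")) reading$t0_s else 0
  if (is.null(channel)) {
    channel <- if (inherits(reading, "adc_reading")) reading$channel else "GEN"
  }
  v <- codes * adc_lsb(cfg)
  if (input_referred) v <- (v - cfg$v_ref_V) / cfg$gain
  spr_trace(v, fs_hz = fs, t0_s = t0, channel = channel, stale = stale)
}
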