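# Physiological analysis: Pan-Tompkins R-peak detection, tachogram and
# jitter statistics, HRV time/frequency features, moving-window SPR RMS and
# scalar SPR features.

#' RR tachogram
#'
#' @param peak_times_s R-peak instants in seconds (strictly increasing).
#' @param source `"sensor"`, `"reference"` or `"truth"`.
#' @param rr_min_ms,rr_max_ms cleaning bounds: RR intervals outside the
#'   range are discarded (defaults 200 and 3000 ms).
#' @return An object of class `tachogram` with `peak_times_s`, `rr_ms` and
#'   `rr_times_s` (each interval timestamped at its closing peak).
#' @export
tachogram <- function(peak_times_s, source = c("sensor", "reference", "truth"),
                      rr_min_ms = 200, rr_max_ms = 3000) {
  source <- match.arg(source)
  peak_times_s <- sort(as.numeric(peak_times_s))
  rr <- diff(peak_times_s) * 1000
  keep <- rr > rr_min_ms & rr < rr_max_ms
  structure(list(peak_times_s = peak_times_s,
                 rr_ms = rr[keep],
                 rr_times_s = peak_times_s[-1][keep],
                 source = source,
                 n_discarded = sum(!keep)),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> (%s) %d peaks, %d RR intervals", x$source,
              length(x$peak_times_s), length(x$rr_ms)))
  if (length(x$rr_ms))
    cat(sprintf(", mean RR %.1f ms (HR %.1f bpm)",
                mean(x$rr_ms), 60000 / mean(x$rr_ms)))
  cat("\n")
  invisible(x)
}

#' Pan-Tompkins R-peak detection
#'
#' Classic stages: band-pass 5-15 Hz, five-point derivative, squaring,
#' 150 ms moving-window integration, adaptive dual thresholds with a 200 ms
#' refractory period and a search-back pass for intervals longer than 1.66
#' times the running RR average. The reported peak time is the local maximum
#' of `|raw - median(raw)|` within the integration window around each
#' detection, so polarity-inverted ECG is handled by the squaring stage and
#' the absolute-value refinement.
#'
#' @param ecg an [spr_trace] (input-referred ECG, any polarity); `fs >= 100`
#'   Hz and at least 10 s of data.
#' @return A [tachogram] with `source = "sensor"`. A flat trace yields an
#'   empty tachogram with a warning.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "spr_trace"))
  fs <- ecg$fs_hz
  if (fs < 100) stop("need fs >= 100 Hz", call. = FALSE)
  if (trace_duration(ecg) < 10) stop("need at least 10 s of data", call. = FALSE)
  x <- ecg$values
  if (stats::sd(x) == 0) {
    warning("flat signal: no peaks detected")
    return(tachogram(numeric(0)))
  }
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  # five-point derivative (Pan-Tompkins FIR), zero-phase alignment by lag 2
  der <- signal::filter(c(2, 1, 0, -1, -2) / 8, 1, c(bp, 0, 0))
  der <- as.numeric(der)[-(1:2)]
  sq <- der^2
  nwin <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / nwin, nwin), sides = 2))
  mwi[is.na(mwi)] <- 0
  refr <- round(0.200 * fs)
  # candidate local maxima of the integrated signal
  is_pk <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_pk)
  if (!length(cand)) {
    warning("no candidate peaks")
    return(tachogram(numeric(0)))
  }
  # adaptive thresholds initialized from the first 2 s
  init <- mwi[seq_len(min(length(mwi), round(2 * fs)))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    k <- cand[i]
    v <- mwi[k]
    if (k - last >= refr && v >= thr()) {
      # one QRS can ripple into several integration-wave local maxima;
      # merge candidates inside the refractory window, keeping the tallest
      grp <- cand[cand >= k & cand < k + refr]
      k <- grp[which.max(mwi[grp])]
      v <- mwi[k]
      i <- i + sum(cand >= cand[i] & cand < cand[i] + refr) - 1L
      peaks <- c(peaks, k)
      if (length(peaks) > 1) rr_hist <- c(rr_hist, k - last)
      spki <- 0.125 * v + 0.875 * spki
      last <- k
    } else if (k - last >= refr) {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: if we overshot 1.66x the running RR average, accept the
      # tallest missed candidate above half threshold
      if (length(rr_hist) >= 2) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if (k - last > 1.66 * rr_avg) {
          miss <- cand[cand > last + refr & cand < k]
          if (length(miss)) {
            mk <- miss[which.max(mwi[miss])]
            if (mwi[mk] >= 0.5 * thr()) {
              peaks <- c(peaks, mk)
              rr_hist <- c(rr_hist, mk - last)
              spki <- 0.25 * mwi[mk] + 0.75 * spki
              last <- mk
              next  # re-examine current candidate against the new `last`
            }
          }
        }
      }
    }
    i <- i + 1L
  }
  peaks <- sort(unique(peaks))
  # refine: local maximum of |raw - median| inside the integration window.
  # Quantization can make adjacent samples tie at the apex; a small
  # neighbor-weighted term breaks such plateaus toward the true apex side
  # instead of which.max()'s structural left bias.
  half <- nwin
  med <- stats::median(x)
  t_pk <- vapply(peaks, function(k) {
    lo <- max(1L, k - half)
    hi <- min(length(x), k + half)
    seg <- abs(x[lo:hi] - med)
    m <- length(seg)
    score <- seg + 0.1 * (c(seg[-1], 0) + c(0, seg[-m]))
    j <- lo - 1L + which.max(score)
    ecg$t0_s + (j - 1L) / fs
  }, numeric(1))
  tachogram(unique(t_pk))
}

#' Jitter statistics of a constant-rate tachogram
#'
#' For a source with nominal constant RR, reports the maximum absolute
#' deviation of the detected RR intervals from nominal, their sample
#' standard deviation, and the closed-form deterministic jitter bound
#' `T_s / sqrt(3)` for the trace's sample period (2.89 ms at 200 Hz,
#' printed as 2.8 ms at the bench's precision).
#'
#' @param tach a [tachogram] with at least 10 RR intervals.
#' @param nominal_rr_ms the true constant RR of the source, in ms.
#' @param fs_hz sampling rate of the sensor that produced the tachogram
#'   (default 200).
#' @return list `max_abs_dev_ms`, `std_ms`, `theoretical_std_ms`.
#' @export
jitter_stats <- function(tach, nominal_rr_ms, fs_hz = 200) {
  stopifnot(inherits(tach, "tachogram"))
  if (length(tach$rr_ms) < 10)
    stop("insufficient data: need >= 10 RR intervals", call. = FALSE)
  dev <- tach$rr_ms - nominal_rr_ms
  list(max_abs_dev_ms = max(abs(dev)),
       std_ms = stats::sd(tach$rr_ms),
       theoretical_std_ms = 1000 / fs_hz / sqrt(3))
}

# Welch PSD with Hann windows; returns f (Hz) and one-sided density
# (units^2 / Hz)
.welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2 * scale
    half <- sp[seq_len(nf)]
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    acc <- acc + half
  }
  list(f = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

#' Time- and frequency-domain HRV features
#'
#' Time-domain features are the standard formulas on the NN intervals:
#' mean RR, SDNN, SDSD, RMSSD, NN50, pNN50, mean HR (mean of the
#' instantaneous `60000 / RR`) and the mean HR derivative. Frequency-domain
#' features are band powers of the PSD of the cubic-spline interpolated,
#' 4 Hz resampled, linearly detrended tachogram estimated by Welch
#' averaging (150 s Hann segments, 50% overlap): LF = `[0.04, 0.15]` Hz,
#' HF = `[0.15, 0.4]` Hz, in ms^2.
#'
#' @param tach a [tachogram].
#' @param resample_hz tachogram resampling rate (default 4 Hz).
#' @param lf_band,hf_band band edges in Hz.
#' @param seg_s Welch segment length in seconds (default 150).
#' @param overlap Welch overlap fraction (default 0.5).
#' @return An object of class `hrv_features` (a named list).
#' @export
hrv_features <- function(tach, resample_hz = 4,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                         seg_s = 150, overlap = 0.5) {
  stopifnot(inherits(tach, "tachogram"))
  rr <- tach$rr_ms
  if (length(rr) < 2) stop("empty tachogram", call. = FALSE)
  d <- diff(rr)
  nn50 <- sum(abs(d) > 50)
  feats <- list(
    mean_rr_ms = mean(rr),
    sdnn_ms = stats::sd(rr),
    sdsd_ms = if (length(d) > 1) stats::sd(d) else 0,
    rmssd_ms = if (length(d)) sqrt(mean(d^2)) else 0,
    nn50_count = nn50,
    pnn50_pct = if (length(d)) 100 * nn50 / length(d) else 0,
    mean_hr_bpm = mean(60000 / rr)
  )
  # resampled instantaneous series for the spectral features and the HR
  # mean derivative
  tt <- tach$rr_times_s
  if (length(unique(tt)) >= 4 && diff(range(tt)) > 10) {
    grid <- seq(min(tt), max(tt), by = 1 / resample_hz)
    rr_i <- stats::spline(tt, rr, xout = grid, method = "fmm")$y
    hr_i <- 60000 / rr_i
    feats$hr_mean_derivative_bpm_per_s <- mean(diff(hr_i)) * resample_hz
    detr <- stats::lm.fit(cbind(1, grid), rr_i)$residuals
    psd <- .welch_psd(detr, resample_hz, seg_len = round(seg_s * resample_hz),
                      overlap = overlap)
    df <- psd$f[2] - psd$f[1]
    band_power <- function(band)
      sum(psd$psd[psd$f >= band[1] & psd$f < band[2]]) * df
    feats$lf_ms2 <- band_power(lf_band)
    feats$hf_ms2 <- band_power(hf_band)
    feats$lf_hf_ratio <- if (feats$hf_ms2 > 0) feats$lf_ms2 / feats$hf_ms2 else NA_real_
    feats$total_power_ms2 <- sum(psd$psd) * df
    feats$rr_variance_ms2 <- stats::var(detr)
  } else {
    feats$hr_mean_derivative_bpm_per_s <- NA_real_
    feats$lf_ms2 <- NA_real_
    feats$hf_ms2 <- NA_real_
    feats$lf_hf_ratio <- NA_real_
    feats$total_power_ms2 <- NA_real_
    feats$rr_variance_ms2 <- NA_real_
  }
  structure(feats, class = "hrv_features")
}

#' @export
print.hrv_features <- function(x, ...) {
  cat("<hrv_features>\n")
  cat(sprintf("  mean RR %.1f ms | HR %.2f bpm | SDNN %.2f ms | RMSSD %.2f ms\n",
              x$mean_rr_ms, x$mean_hr_bpm, x$sdnn_ms, x$rmssd_ms))
  cat(sprintf("  SDSD %.2f ms | NN50 %d | pNN50 %.1f%%\n",
              x$sdsd_ms, x$nn50_count, x$pnn50_pct))
  if (is.finite(x$lf_ms2))
    cat(sprintf("  LF %.1f ms^2 | HF %.1f ms^2 | LF/HF %.2f\n",
                x$lf_ms2, x$hf_ms2, x$lf_hf_ratio))
  invisible(x)
}

#' Moving-window RMS of an SPR trace
#'
#' Centered sliding-window RMS at the input rate; at the edges the window is
#' truncated to the available samples.
#'
#' @param spr an [spr_trace].
#' @param window_s window duration in seconds (default 5; must be shorter
#'   than the trace).
#' @return An [spr_trace] of the same length holding the RMS profile.
#' @export
spr_rms <- function(spr, window_s = 5) {
  stopifnot(inherits(spr, "spr_trace"))
  n <- length(spr$values)
  w <- round(window_s * spr$fs_hz)
  if (w >= n) stop("window must be shorter than the trace", call. = FALSE)
  half <- w %/% 2L
  cs <- cumsum(c(0, spr$values^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  rms <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  spr_trace(rms, fs_hz = spr$fs_hz, t0_s = spr$t0_s, channel = spr$channel,
            meta = list(window_s = window_s, derived = "moving_rms"))
}

#' Scalar SPR features over a window
#'
#' The five features used for stress discrimination: variance, energy
#' (`sum(x^2) * dt`), mean absolute value, mean absolute derivative and
#' maximum absolute derivative (first differences divided by the sample
#' period).
#'
#' @param spr an [spr_trace] (non-empty).
#' @return An object of class `spr_features` (named list; derivative
#'   features are 0 for a single-sample trace).
#' @export
spr_scalar_features <- function(spr) {
  stopifnot(inherits(spr, "spr_trace"))
  x <- spr$values
  if (!length(x)) stop("empty trace", call. = FALSE)
  dt <- 1 / spr$fs_hz
  dx <- if (length(x) > 1) diff(x) / dt else 0
  structure(list(
    variance = if (length(x) > 1) stats::var(x) else 0,
    energy = sum(x^2) * dt,
    mean_abs = mean(abs(x)),
    mean_abs_deriv = mean(abs(dx)),
    max_abs_deriv = max(abs(dx))
  ), class = "spr_features")
}

#' @export
print.spr_features <- function(x, ...) {
  cat(sprintf(
    "<spr_features> var %.4g | energy %.4g | mean|x| %.4g | mean|dx| %.4g | max|dx| %.4g\n",
    x$variance, x$energy, x$mean_abs, x$mean_abs_deriv, x$max_abs_deriv))
  invisible(x)
}
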