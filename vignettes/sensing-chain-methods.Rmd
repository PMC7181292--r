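---
title: "Methods: simulating and characterizing a wireless SPR + ECG sensing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing a wireless SPR + ECG sensing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprecg)
```

`sprecg` is a software twin of a wearable stress-sensing system: two
skin-potential-response (SPR) channels measured on the hands, two ECG
channels on the chest, SPR data carried to the ECG box over a lossy
UDP-style wireless link and realigned there into a common 5 ms frame
cadence. The package simulates each stage well enough that the system's
published metrological characterization — linearity with GUM uncertainty,
bandwidth, transport delay, RR-interval jitter and cross-device HRV
agreement — can be recomputed from first principles, with no hardware.

This vignette documents the models, the defaults and the numerical choices.

## The analog front end

Each channel conditions a low-level differential voltage around a mid-supply
reference `V_REF = 1.65 V`:

$$
V_\mathrm{out}(j\omega) = V_\mathrm{REF} +
G \, \frac{(\tau_L j\omega)^2}{(1+\tau_L j\omega)^2 (1+\tau_H j\omega)^3}
\, V_\mathrm{in}(j\omega)
$$

* two zeros at the origin and a **double high-pass pole** at
  $1/(2\pi\tau_L) = 0.05$ Hz — a passive input filter plus a DC-compensation
  loop that servoes the amplifier output to `V_REF`, removing offsets, bias
  currents and electrode drift. The resulting lower −3 dB edge is
  $0.05\sqrt{1/(\sqrt2-1)} \approx 0.08$ Hz with a +40 dB/dec skirt;
* a **triple real anti-alias pole** at $1/\tau_H$
  ($\tau_{H,\mathrm{SPR}} = 10$ ms, $\tau_{H,\mathrm{ECG}} = 1$ ms),
  −60 dB/dec above the edge. For the SPR channel the solver places the upper
  −3 dB point at 8.2 Hz (8 Hz at the bench's precision). For the ECG channel
  this model yields 81 Hz; the system's data sheet value is 75 Hz, a
  discrepancy inherent to the printed transfer function that we report
  as-is rather than resolve.

Two back ends implement the same response. The `fft` back end multiplies by
the closed form and is exact for steady-state (circularly continued)
stimuli; the `iir` back end factors the transfer function into five
first-order sections, maps each with the bilinear transform at the native
rate (1 kHz by default) and streams causally. Bilinear warping makes the
`iir` magnitude deviate from the closed form by more than 0.5% only beyond
~20 Hz on the SPR channel's $f^{-3}$ stopband slope, where the response is
below −20 dB; the equivalence tests therefore cover 0.2–50 Hz for the ECG
configuration and 0.2–20 Hz for the SPR configuration.

The ADC is an ideal rounding quantizer: 12 bits over 0–3.3 V at 200 Hz
(LSB 806 µV at the amplifier output; input-referred resolution
20 mV/4096 = 4.9 µV for SPR, 10 mV/4096 = 2.4 µV for ECG), sampling the
analog trace by linear interpolation and clipping with a saturation flag.
Its type-B uncertainty model combines ±1 LSB integral non-linearity
(rectangular, $u = \mathrm{LSB}/\sqrt3$) with quantization
($\mathrm{LSB}/\sqrt{12}$). Amplifier noise is deliberately absent: the
characterization bench measures a clean chain, and quantization is the
dominant idealized error source.

## Wire formats and alignment

SPR boxes send one 12-bit sample as two octets of six data bits each, plus
one H/L flag (bit 7) and one box flag (bit 6) so any octet is classifiable
in isolation; eight samples (40 ms) form one packet. The ECG box emits one
10-octet frame every 5 ms: header `0xAA 0x55`, two big-endian ECG codes
(top nibbles zero), one SPR sample per box. The field layout makes the
header pair structurally impossible inside a legal payload, so a reader can
resynchronize mid-stream; corrupted frames are skipped and counted. Since
the published description does not give the exact bit diagram, this layout
is normative for the package only.

Transport is a one-hop simulated UDP link — constant latency, bounded
uniform jitter (capped below half the packet period, so no reordering) and
Bernoulli packet loss. The ECG box treats each box's samples as a FIFO: one
pop per frame, and on underrun the last value is re-emitted with a *stale*
flag (the idle code 2048 before anything arrived). Under lossless transport
each SPR sample is emitted exactly one packet period (40 ms) after its
acquisition, which the FFT-phase delay estimator recovers exactly; the
per-channel analog group-delay difference (the 10 ms vs 1 ms anti-alias
stages differ by ~27 ms of phase delay at 1 Hz) is a property of the front
ends, not of the transport, so the delay scenario samples the common
stimulus identically on both paths to isolate the packetization delay.

## Synthetic signals

* **Calibration sinusoids** pass through a resistive attenuator
  (SPR 5.568×10⁻³ ± 8×10⁻⁶, ECG 1.497×10⁻³ ± 3×10⁻⁶) emulating skin source
  impedance.
* **ECG** is a five-Gaussian PQRST template with a ~1 mV R lobe
  (σ = 11 ms, wide enough that 200 Hz sampling loses under 5% of the apex),
  Q and S symmetric about R so the generator's reported R-peak times are
  exact ground truth, repeated at an arbitrary RR sequence; a clock-skew
  parameter stretches the time base ($t \to t(1+\mathrm{ppm}\cdot10^{-6})$)
  to emulate independent source/sensor clocks.
* **SPR pulses** are difference-of-exponential kernels (1 s rise, 4 s
  decay, ≈10 s visible width, apex-normalized amplitude within ±10 mV),
  optionally with band-limited (10–45 Hz) motion-artifact bursts on one
  hand only.

The generators emulate what the characterization needs and no more: no
respiration-coupled baseline wander, no electrode noise, no ectopic beats.
Tests passing on these signals show the *chain* is faithful; they do not
certify detector performance on pathological real-world ECG.

## Metrological characterization

**Linearity.** Fifty generator amplitudes linearly spaced over 0–3.3 Vpp at
1 Hz; ten RMS readings per amplitude, each over exactly ten stimulus
periods (coherent windows, AC-coupled: the `V_REF` operating point is
removed before the RMS). The gain is the least-squares slope of mean output
RMS versus input RMS. Uncertainty follows GUM practice end to end:
generator setting (0.1% of setting by default — the bench generator's spec
is not published — times the attenuator) into $u(V_\mathrm{in})$; type A
(sd of the mean of ten readings) plus the ADC type-B model into
$u(V_\mathrm{out})$; and analytic sensitivity coefficients of the slope,
$\partial G/\partial y_i = (x_i-\bar x)/S_{xx}$ and
$\partial G/\partial x_i = (y_i-\bar y-2G(x_i-\bar x))/S_{xx}$, combined
root-sum-square. A Monte-Carlo propagation cross-check agrees within 5%.
One modeling subtlety: the chain response at the 1 Hz stimulus is 0.9916
(SPR) / 0.9975 (ECG) of the amplifier gain, so the raw slope
under-estimates it; `estimate_gain()` divides by the known normalized
response at the stimulus frequency by default and recovers the configured
gains (141.0/141.2/378.3/376.9 measured profile; 160/370 design profile)
exactly, while the raw slope is retained for the deviation-from-linearity
profile (reported in percent of the input full scale, 20 mV SPR / 10 mV
ECG). The simulated chain's non-linearity is quantization-limited at
~0.002% FS, far below the 0.15% FS hardware bound.

**Bandwidth.** Sixty-one log-spaced frequencies over 0.1–100 Hz at 3.3 Vpp;
the observation window is ten periods (coherent) below 10/3 Hz and 3 s
above. Frequencies above the 100 Hz Nyquist limit are excluded with a
warning. Measured −3 dB points are interpolated log-log between bracketing
samples; the lower edge falls below the 0.1 Hz sweep start, as on the
bench.

**Delays.** With a common 1 Hz stimulus on all channels, each trace's FFT
phase is read at the bin nearest 1 Hz over an integer number of periods
(leakage-free, no zero padding), and pairwise delays
$\Delta t_{jk} = (\varphi_k - \varphi_j)/2\pi f_0$ are wrapped to
$(-1/2f_0, +1/2f_0]$; the matrix is antisymmetric by construction.

**Jitter.** A five-minute constant-rate 60 bpm synthesized ECG is acquired
through the chain. The source clock skew defaults to 370 ppm, making the
effective RR 1000.37 ms — deliberately incommensurate with the 5 ms
sampling grid, as two free-running crystals are. Pan–Tompkins detection
(band-pass 5–15 Hz, five-point derivative, squaring, 150 ms integration,
adaptive dual thresholds with 200 ms refractory and search-back; candidates
within one refractory window merged to the tallest; apex refined as the
local maximum of the raw trace with a small neighbor-weighted term that
breaks quantization plateaus) then yields the tachogram. Closed-form
analysis of this setup: detected peaks are the true times rounded to the
grid, the phase advances by a constant 0.37 ms per beat, and the RR error
takes exactly two values, giving
$\mathrm{sd} = T_s\sqrt{p(1-p)}\cdot(5/T_s) = 1.31$ ms with
$p = (RR \bmod T_s)/T_s = 0.074$ — below both the independent-phase
$T_s/\sqrt6 = 2.04$ ms regime and the deterministic bound
$T_s/\sqrt3 = 2.89$ ms. A bench with uncontrolled noise decorrelates beat
phases and lands nearer 2 ms; reproducing that would require adding a noise
source the clean-chain model intentionally omits, so the package reports
the deterministic value. The maximum RR deviation, 4.63 ms, respects the
one-sample-period bound.

## Physiological features

Time-domain HRV features use the standard NN-interval formulas (mean RR,
SDNN, SDSD, RMSSD, NN50, pNN50, mean of instantaneous HR, mean HR
derivative on the 4 Hz-resampled HR series). Spectral features follow
common HRV-software defaults, which the published comparison delegated to
its analysis tool without stating: cubic-spline interpolation of the
tachogram, 4 Hz resampling, linear detrend, Welch PSD with 150 s Hann
segments at 50% overlap; LF = 0.04–0.15 Hz and HF = 0.15–0.40 Hz band
powers in ms². A Parseval-style test keeps total band power within 10% of
the resampled tachogram variance. RR cleaning discards intervals outside
200–3000 ms and does not interpolate ectopics (the synthetic data are
clean).

The cross-rate comparison (`hrv_rate_comparison()`) drives one five-minute
synthetic ECG whose RR process carries both an LF (0.1 Hz, 30 ms) and an
HF/respiratory (0.25 Hz, 20 ms) modulation — both bands must hold genuine
power for a relative HF comparison to be meaningful, as they do in real
tachograms — through the 200 Hz chain and, in parallel, through direct
512 Hz sampling emulating a higher-rate commercial reference recorder. The
maximum relative deviation over {mean HR, SDNN, RMSSD, LF, HF} is ~2.3%,
inside the 6% envelope reported for the hardware against its reference.

SPR analysis provides the 5 s centered moving-window RMS (edges truncated)
and the five scalar stress features: variance, energy
($\sum x^2\,\Delta t$), mean |x|, mean |dx/dt| and max |dx/dt|.

Scenario statistics (`paired_compare()`, `compare_feature_tables()`) use a
two-sided paired t-test and an **exact** two-sided Wilcoxon signed-rank
test (dynamic programming over doubled ranks: zeros dropped, mid-ranks for
ties, $p = 2\min(P(W\le w), P(W\ge w))$ capped at 1). Two-sided tests
reproduce the published significance levels on the bundled ten-driver
table; "average increase" is the ratio of scenario means, which matches the
published 39/2/19/14/42% figures where a mean of per-subject ratios does
not.

## Problem sizes and reproducibility

Characterization runs use the study's own sizes — 50×10 linearity matrix,
61-step sweep, five-minute physiological records — and complete in seconds
at the 1 kHz native rate; unit tests use reduced sizes (15×3 linearity,
13-step sweep, 2–3 minute records) chosen so every assertion still
exercises the same code paths. All stochastic paths (transport loss/jitter,
artifact noise, scenario layouts) take explicit integer seeds and are
bit-reproducible; the deterministic scenarios (jitter, delay, cross-rate)
produce identical results for any seed by construction. Session artifacts
(trace CSVs, binary captures, result JSONs) carry a configuration hash so
a stored configuration can be re-run and compared exactly.

## Known limitations

* No amplifier/electrode noise model: uncertainty magnitudes that the
  bench derives from real scatter (e.g. the ±0.6/±1.6 gain uncertainties)
  come out smaller here, and the empirical RR jitter sits at its
  deterministic value rather than the noise-decorrelated one.
* The ECG upper band edge inherits the printed transfer function's 81 Hz,
  not the 75 Hz data-sheet figure.
* Motion-artifact *removal* is out of scope: the package generates
  artifacts and exposes the two-channel traces, but ships only a
  pass-through in place of a separation algorithm.
* The wire bit layout is normative for this artifact only.
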