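Package: sprecg
Title: Software Twin of a Wireless Skin-Potential and ECG Stress-Sensing Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a two-channel endosomatic electrodermal activity (skin
    potential response, SPR) plus two-channel ECG wireless acquisition system
    end to end: calibration and physiological signal synthesis, the analog
    front-end transfer function and 12-bit ADC, the byte-level packet formats
    and UDP-like transport with FIFO stream alignment, and the full
    metrological characterization of the chain (linearity with GUM uncertainty
    propagation, bandwidth, FFT-phase delay estimation, data-loss accounting).
    Includes physiological analysis of the acquired signals: Pan-Tompkins
    R-peak detection, RR tachogram and jitter statistics, time- and
    frequency-domain heart rate variability features, moving-window SPR RMS,
    and paired scenario statistics with an exact Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
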