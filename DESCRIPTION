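Package: lfpconnect
Title: Aperiodic Spectral Parameterization and Mutual-Information
    Connectivity for Multichannel LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Systems-level analysis of multichannel local field potential
    (LFP) recordings around a pharmacological intervention. Separates the
    aperiodic (1/f-like) component of bipolar-derived power spectra and fits
    the power law y = 10^A/f^B, giving per-structure offset (A) and exponent
    (B) changes between baseline and drug epochs; estimates pairwise
    functional connectivity with a Gaussian-copula mutual-information
    estimator evaluated in short non-overlapping windows, with post/baseline
    ratio summaries, within/between-structure contrasts and region-by-region
    change matrices; and applies nonparametric (Wilcoxon) contrast
    statistics. A synthetic multi-structure LFP generator with known
    spectral and coupling ground truth supports end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
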