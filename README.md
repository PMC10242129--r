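# lfpconnect

Systems-level analysis of multichannel local field potential (LFP)
recordings around a pharmacological intervention, for electrophysiologists
comparing baseline and drug-state brain activity across many implanted
structures at once.

Two readouts are produced from a channels × samples voltage matrix plus an
electrode map:

1. **Aperiodic spectral parameterization.** Bipolar (differential)
   electrode pairs → Hann/Welch spectrograms → per-epoch median spectra →
   iterative removal of oscillatory peaks (including 130–160 Hz
   high-frequency oscillations and 50-Hz mains) → least-squares fit of the
   power law

   *y* = 10^A / f^B  over 1–300 Hz,

   where the offset *A* (log₁₀ µV²/Hz) indexes broadband power (a proxy
   for neuronal population activity) and the exponent *B* indexes the
   spectral slope (a proxy for excitation–inhibition balance). Per
   structure, the change ΔA, ΔB between a baseline epoch and a
   post-injection epoch is estimated and tested (Wilcoxon signed rank).

2. **Functional connectivity by Gaussian-copula mutual information
   (GCMI).** Monopolar signals downsampled to 1 kHz are cut into
   non-overlapping 2-s windows; per channel pair and window, samples are
   rank-transformed to standard-normal margins and MI is computed
   parametrically, Î = −½·log₂(1 − r²) bits, with an analytic
   small-sample bias correction. Median MI per epoch gives a
   post/baseline ratio per pair, summarized within/between structures,
   as a region × region change matrix, and by post-vs-baseline linear
   fits — plus a split-baseline stationarity control.

A synthetic multi-structure LFP generator with known ground truth
(per-channel A and B per epoch, latent-source coupling matrix,
common-mode artifact, oscillations, step drug effect at t = 0) makes the
entire pipeline verifiable by parameter recovery.

## Worked example

Simulate a small two-structure experiment with a ketamine-like effect
(offset up by 0.3, coupling scaled to 0.7 after injection) and run the
full pipeline:

```r
library(lfpconnect)

cfg <- sim_config(
  structures = data.frame(structure = c("mPFC", "S1"),
                          region = c("PFC", "SenC"), n_channels = 6L),
  fs = 1000, duration_pre = 150, duration_post = 150,
  drug_effect = list(dA = 0.3, dB = 0, coupling_scale = 0.7), seed = 42)
sim <- simulate_experiment(cfg)

report <- run_pipeline(sim$recording, sim$emap, pipeline_config(
  spectral_baseline = c(-130, -10), spectral_post = c(10, 130),
  conn_baseline = c(-130, -10), conn_post = c(10, 130),
  run_baseline_control = FALSE, seed = 42))
print(report)
```

```
== Aperiodic spectral change (per structure) ==
 structure region n_pairs     dA      p_dA sig_dA        dB    p_dB sig_dB
      mPFC    PFC      15 0.2813 6.104e-05      * -0.008027 0.01807      *
        S1   SenC      15 0.3068 6.104e-05      *  0.006646 0.48870

== Functional connectivity ==
<connectivity_summary> 66 pairs (30 within-structure), 66 reliable
  baseline within vs between mean MI: +156.0%
  within fit: post = 0.439 * base +0.1226, R^2 = 0.327 (n=30)
  between fit: post = -0.108 * base +0.1309, R^2 = 0.008 (n=36)
   scope  n median_ratio       p sig
  within 30       0.8844 0.02496   *
 between 36       1.0970 0.30350
```

Reading the output: the injected +0.3 offset change is recovered per
structure (`dA` ≈ 0.28 and 0.31, significant in both), the exponent is
essentially unchanged, and the within-structure connectivity ratio drops
significantly below 1 (0.88) after the injected coupling reduction, while
between-structure pairs — whose MI is dominated by the estimator floor on
autocorrelated signals — stay near 1. Baseline within-structure MI
exceeds between-structure MI, as in real recordings. (At this deliberately
small scale, occasional borderline p-values like the mPFC `dB` asterisk
are expected; the methods vignette discusses pooled-pair
pseudo-replication and the `stat_unit = "animal_median"` alternative.)

The single estimator pieces are available directly: `gcmi_pair(x, y)`,
`copula_transform(x)`, `fit_powerlaw(spec)` / `fit_aperiodic(spec)` (an
S3 model object with `coef`, `predict`, `plot`, `residuals` methods),
`compute_spectrogram()`, `median_spectrum()`, `bipolar_pairs()`,
`windowed_mi()`, `pair_connectivity()`, `structure_summary()`,
`baseline_control()`. On-disk I/O uses a float32 + JSON-sidecar layout
(`write_recording`/`read_recording`), TSV electrode maps, and
`write_report()` emits the TSV report bundle. A command-line front end
lives at `inst/scripts/lfp-pipeline.R`
(`simulate`, `inspect`, `run`).

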