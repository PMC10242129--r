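---
title: "Aperiodic spectra and mutual-information connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aperiodic spectra and mutual-information connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpconnect)
```

# The analysis in one paragraph

`lfpconnect` analyzes multichannel extracellular voltage recordings (local
field potentials, LFPs) collected around a systemic drug injection at
t = 0. Two complementary readouts are produced. First, the *aperiodic*
(non-oscillatory) part of the power spectrum of bipolar-derived electrode
pairs is modelled as a power law

$$y(f) = \frac{10^{A}}{f^{B}},$$

where the offset $A$ (in $\log_{10} \mu V^2/\mathrm{Hz}$) tracks broadband
power — a proxy for overall neuronal population activity — and the
exponent $B$ tracks the steepness of spectral decay, commonly read as a
proxy for the excitation–inhibition balance of the circuit (flattening =
relatively more excitation). Per-structure changes
$\Delta A = A_\text{post} - A_\text{base}$ and $\Delta B$ are tested with
Wilcoxon signed-rank statistics. Second, functional connectivity between
monopolar channel pairs is quantified with Gaussian-copula mutual
information (GCMI) in consecutive 2-s windows; the per-pair median MI in a
baseline and a post-injection epoch gives a post/baseline ratio, which is
summarized within and between anatomical structures and as a
region-by-region change matrix.

A synthetic multi-structure LFP generator with fully known ground truth —
per-channel $(A, B)$ per epoch, a latent-source coupling matrix, a
common-mode signal, narrowband oscillations and a step drug effect — makes
every stage testable by parameter recovery.

# Spectral stage

## Bipolar derivation

Voltages recorded against a common reference contain far-field
contributions. Subtracting two electrodes implanted in the same structure
cancels any source common to both exactly (an algebraic identity), leaving
locally generated potentials. Two pairing modes exist: all same-structure
pairs (`"all_within_structure"`, the quantitative default) and
`"neighbors"` (Chebyshev distance 1 on the 250-µm array grid), which
mirrors how example spectrograms are usually drawn.

## Spectrogram and median spectra

Power spectral densities use Hann-tapered windows with density scaling
(µV²/Hz); per window the Parseval identity
$\sum_k P_k \,\Delta f = \sum_n (w_n x_n)^2 / \sum_n w_n^2$ holds to
rounding error. Defaults are 2-s windows with 50 % overlap: no source
document for this class of analysis states the segmentation, and 2 s is
the shortest window resolving the 1-Hz lower fit bound with two full
cycles. Per epoch the *median* across windows is taken, making the
spectrum robust to transient artifacts.

A consequence worth knowing: each windowed periodogram bin is
approximately exponentially distributed, so the across-window median sits
at $\ln 2 \approx 0.693$ of the mean, i.e. the median spectrum is a
constant $\log_{10} \ln 2 \approx -0.16$ below the mean spectrum on the
log scale (empirically ≈ −0.1 after log-binned fitting with overlapping
windows). This constant cancels exactly in $\Delta A$, the analysis
endpoint, so no bias correction is applied.

## Aperiodic–periodic separation and the power-law fit

Oscillatory humps (e.g. high-frequency oscillations at 130–160 Hz under
ketamine or LSD) would bias the power-law fit. They are removed by
iterative peak pruning in log–log space: fit, flag contiguous bins whose
positive residual exceeds `peak_threshold_sd` (default 2.5) standard
deviations, grow each flag into its > 1 SD shoulders, mask, refit — at
most `max_iters` (default 5) rounds. Mains interference at 50 Hz and
harmonics is always masked (the recordings this analysis style targets
come from 50-Hz countries). The source algorithm family is named in the
literature without settings; the defaults here were chosen for the
synthetic recovery tests and are exposed as arguments.

The fit itself is ordinary least squares of $\log_{10} P$ on
$\log_{10} f$ over 1–300 Hz, after resampling onto ≤ 100 log-spaced bins
so that each frequency decade carries comparable leverage (standard
practice in aperiodic parameterization; a linear grid would let the
300-Hz end dominate). Because bin averages of points on a log–log line
stay on the line, the fit is exact to machine precision on noiseless
power laws — a property the test suite checks across a grid of
$A \in [-3, 3]$, $B \in [0, 4]$.

$A$ and $B$ are fitted per pair and epoch; structure summaries take the
median over pairs of the per-pair deltas (matching the way median offset
and slope changes are usually reported).

# Connectivity stage

## The GCMI estimator

For each channel the samples in a window are rank-transformed,
$z_i = \Phi^{-1}\!\big(\mathrm{rank}(x_i)/(n+1)\big)$ (average ranks for
ties — deterministic, reproducible), giving empirical standard-normal
margins. The mutual information of the pair is then computed
parametrically from the correlation $r$ of the transformed pair:

$$\hat I = -\tfrac{1}{2}\log\big(1 - r^2\big) \quad [\text{nats}],$$

reported in bits by default. This is a lower bound on the true MI,
exactly invariant to strictly monotone transforms of either margin (hence
to gain, offset and saturating nonlinearities of the amplifier chain),
and symmetric. An analytic small-sample bias term
$\tfrac12[\psi(\tfrac{n-1}{2}) - \psi(\tfrac{n-2}{2})]$ (from the
expected log-determinant of a Wishart covariance estimate) is subtracted
by default; whether the original analyses used it is not documented, so
both paths exist (`bias_correct`). At $n = 2000$ the corrected estimator
agrees with the closed form $-\tfrac12\log_2(1-\rho^2)$ to well under
0.02 bits in expectation across $\rho \in \{0, 0.3, 0.6, 0.9\}$.

One estimator property matters for interpretation: on short windows of
strongly autocorrelated signals (red noise, $B \approx 2$) the effective
sample size is far below $n$, so even independent channel pairs show a
positive MI floor (~0.1 bits at 2 s, 1 kHz). This floor is a property of
any sample-MI estimate on such signals, affects baseline and post epochs
alike, and pushes pair ratios toward 1 for weakly coupled pairs.

## Windowing, ratios and summaries

Connectivity uses *monopolar* signals downsampled to 1 kHz (configurable;
2 kHz is equally legitimate). Epochs are tiled by non-overlapping 2-s
windows, $\lfloor T / 2\,\mathrm{s} \rfloor$ of them — a 15-min epoch
yields exactly 450 MI values per pair. Medians over windows per epoch
give `mi_base`, `mi_post` and `ratio = mi_post / mi_base`. Bias-corrected
medians are clamped at zero and pairs with `mi_base` below 0.001 bits are
flagged unreliable and dropped from summaries: ratios with near-zero
denominators are meaningless. The floor value is a package choice (no
source states one).

Summaries: a region × region matrix of mean ratios (mean, matching
"average change" conventions; per-cell counts are kept), least-squares
fits of post-median vs baseline-median MI within and between structures
with $R^2$, the baseline within-vs-between mean MI difference in percent,
and signed-rank contrasts of post vs baseline MI per scope. A
split-baseline control applies the identical machinery to the two halves
of the baseline epoch; under stationarity the ratio is ≈ 1.

# Statistics

All contrasts are nonparametric: Kolmogorov–Smirnov against a
moment-matched normal documents the (invariably rejected) normality
assumption, then Wilcoxon signed-rank (paired, e.g. baseline vs post per
electrode pair) or rank-sum (unpaired) tests, two-sided throughout
(sidedness is never stated in this literature; two-sided is the
conservative reading). Exact p-values are used for small tie-free
samples, the normal approximation with tie/zero handling otherwise; an
all-zero difference vector returns p = 1 by convention. Per-structure
tests are uncorrected by default (matching the per-structure asterisk
convention); Benjamini–Hochberg is available via `p_adjust = "BH"`.

Pooling electrode pairs within a structure pseudo-replicates: pairs
sharing a channel (or an animal) are correlated, so per-structure
p-values are anticonservative. This is flagged in the run log, and
`stat_unit = "animal_median"` tests per-animal medians instead — with few
animals this is very conservative (n = 3 animals cannot reach p < 0.05 in
a signed-rank test).

# The synthetic generator

Each channel is built as

$$x_i(t) = p_i(t) + \sum_k L_{ik}\, s_k(t) + c(t) \; [+\ \text{oscillations}],$$

with private noise $p_i$, latent sources $s_k$ (one per structure plus
one global cross-structure source, so within-structure coupling exceeds
between by construction), and a common-mode signal $c$ added
sample-identically to every channel. All broadband components are
synthesized by frequency-domain spectral shaping: white Gaussian noise is
transformed, its coefficients scaled by $\sqrt{10^A f^{-B} \cdot f_s/2}$,
and inverse-transformed — the expected one-sided PSD is then *exactly*
$10^A/f^B$, at $O(n \log n)$ cost. The DC bin is zeroed (the fit starts
at 1 Hz, so this is invisible). Sources share the channels' median
$(A, B)$ so every mixture remains an exact power law. Oscillations are
band-pass-filtered noise bursts (not sinusoids), so their spectral
signature is a hump of finite bandwidth; amplitude is in-band RMS. The
default inventory is one 130–160-Hz HFO-like component on all channels.

The drug effect is a step at t = 0: offsets shift by `dA`, exponents by
`dB`, and the latent loading variance scales by `coupling_scale`
(loadings by its square root). A step, not a pharmacokinetic ramp,
because the analysis epochs start ≥ 30 min after injection where the ramp
shape is irrelevant. Epoch parameters and the realized loading matrix are
returned as ground truth (`true A`, `true B` per channel and epoch; the
coupling matrix $LL^\top$ per epoch).

Default conditions mirror the study design they emulate: nine structures
of six channels from three animals each (the region-inclusion rule is "at
least six recordings from at least three animals"), 60 min pre and post,
1 kHz sampling, baseline $(A, B) = (1, 2)$, and per-channel loading
jitter (`coupling_jitter = 0.5`) so baseline connectivity varies broadly
across pairs, as it does in real recordings. `coupling_within = 0.9` and
`coupling_between = 0.45` were calibrated once so the baseline
within-vs-between mean MI difference lands in the reported ~70 % regime.
Everything is reproducible bit-for-bit from the config seed; source
mixing deliberately avoids BLAS matrix products, whose threaded
reductions are not run-to-run deterministic.

What the generator does *not* emulate: biophysical (conductance-level)
dynamics, behavioral covariates, pharmacokinetic onset ramps,
nonstationary artifacts, electrode drift, or volume-conduction geometry
beyond the single common-mode term. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not fidelity to any particular biological dataset.

# Numerical choices and degenerate inputs

* Recordings are rejected at load if they contain NaN; analyses assume
  gapless data. On-disk samples are little-endian float32 (`as_float32()`
  makes the precision explicit); sidecar metadata is JSON, electrode maps
  are TSV.
* Time is in seconds with t = 0 at injection; sample intervals are
  half-open `[start, end)`; channel pairs are unordered.
* Anti-alias filtering for downsampling: order-8 Chebyshev-I (0.01 dB
  ripple) at 0.8 × the new Nyquist, applied forward–backward (zero
  phase), staged for large factors so the relative cutoff stays
  numerically safe; only integer decimation factors are supported.
* Constant windows make MI undefined (error); perfectly dependent pairs
  return `+Inf` with a warning; copula ties take average ranks.
* `separate_aperiodic` warns (but returns) when more than half of the
  bins are masked.
* Negative bias-corrected MI medians are clamped to 0 before ratios.

# Problem sizes used by the tests and the acceptance script

Tests and the acceptance script run scaled-down versions of the full
design, chosen as the smallest sizes at which every recovery property is
comfortably resolved: typically four structures × six channels, 240 s
per epoch at 1 kHz, with 180-s analysis epochs (90 MI windows per pair),
and 60-s single-channel series for spectral recovery. Two caveats of
small scale are documented rather than hidden: (1) the split-baseline
control needs halves long enough for low-frequency band power of red
noise to stabilize — with $B = 2$ and minutes-long halves the control
ratio wobbles by ±10–15 %, so the stationarity check uses pink
($B = 1$) background; (2) with heterogeneous loadings, rescaling the
coupling changes the small non-cancelling latent residual in bipolar
spectra (~0.005 log₁₀ units), so the drug-archetype demonstrations use
homogeneous within-structure loadings, for which bipolar cancellation is
exact.

# Known limitations

* The offset/exponent estimates inherit the (delta-cancelling) median
  bias described above; absolute $A$ values are ≈ 0.1 log₁₀ units low.
* GCMI on autocorrelated windows has a positive floor; between-structure
  ratios are compressed toward 1 where true coupling is weak.
* The per-structure pooled-pairs tests pseudo-replicate; the
  animal-median mode is principled but underpowered at three animals.
* Only undirected, time-domain, pairwise dependence is measured — no
  directed/lagged measures, no frequency-resolved MI, no
  graph-theoretic summaries.
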