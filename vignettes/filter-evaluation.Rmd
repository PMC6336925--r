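---
title: "Evaluating digital filters for GLM analysis of fNIRS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating digital filters for GLM analysis of fNIRS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsfilt)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through light attenuation at two wavelengths. The concentration signals
(ΔHbO₂, ΔHbR) carry a task-evoked response of at most a few tenths of a
micromolar riding on physiological noise of comparable or larger amplitude:
cardiac pulsation near 1 Hz, respiration near 0.3 Hz, Mayer waves near
0.1 Hz, very-low-frequency vascular activity below 0.04 Hz, and slow
instrumental and coupling drifts. Digital band-pass or low-pass filtering is
the standard remedy, but the filter family, order and cut-off frequencies
are often chosen by habit, and a badly specified filter either leaves noise
that biases the general linear model (GLM) estimates or removes part of the
response itself.

`nirsfilt` turns the filter choice into a measurable experiment: it
generates multi-subject synthetic concentration data in which the
task-evoked component — and therefore the true regression coefficient β —
is known exactly, pushes the data through a configurable preprocessing
pipeline (modified Beer–Lambert conversions, optional motion correction, a
filter grid, three serial-correlation treatments), and scores every filter
specification by how well the group-level β values recover the ground
truth.

## The simulated experiment

The default protocol is a block design: a 20 s lead-in rest followed by 14
cycles of 20 s task and 20 s rest, sampled at 5 Hz (580 s, 2900 samples).
Its stimulation frequency is `f_stim = 1/(20 s + 20 s) = 0.025` Hz. The
task component is the boxcar convolved with a double-gamma hemodynamic
response function, rescaled to unit peak and multiplied by the generating
amplitude, so the amplitude *is* the recoverable β:

```{r task}
protocol <- protocol_spec()
protocol$f_stim
hrf <- hrf_spec()
kernel <- sample_hrf(hrf, fs = 5)
```

Three amplitude presets define the reference βs: 0.8/−0.27 µM (Amplitude 1),
0.5/−0.17 µM, and 0.3/−0.1 µM for ΔHbO₂/ΔHbR — the HbR response is about
−1/3 of the HbO₂ one. Internally every concentration is in Molar; µM values
are converted at the configuration boundary.

### The HRF parameterization

The kernel is a difference of two gamma densities (unit rate), the positive
one modelling the response and the negative one the undershoot, with an
undershoot ratio of 1/6 and a 32 s support. The requested landmarks are the
peak at 6 s and the undershoot trough at 16 s. Because the positive
response's decaying tail shifts the trough of the *difference*, the two
gamma shapes are solved numerically at construction (Nelder–Mead on the
stationarity conditions) so the difference kernel itself attains its
extrema exactly at the requested times; with the defaults the solved shapes
are ≈ 7.014 and ≈ 15.339 rather than the naive 7 and 17. The kernel is zero
at t = 0 and scaled to unit peak.

## The synthetic resting noise

The study conditions emulate 16-channel, ~10 min resting recordings at
5 Hz. No generative model of those recordings exists, so the package makes
one with the structural features that matter for group β statistics:

* **Systemic oscillators** — cardiac 1.1 ± 0.15 Hz (0.4 µM), respiration
  0.3 ± 0.05 Hz (0.2 µM), Mayer 0.095 ± 0.01 Hz (0.3 µM), VLF
  0.02 ± 0.01 Hz (0.3 µM); frequency, base amplitude and phase drawn per
  subject and *shared across channels*, with per-channel amplitude scaling
  (SD 0.2) and small phase lags (SD 0.3 rad). Sharing is essential: systemic
  physiology is global, so the median over 16 channels must not average it
  away; independent channels would understate between-subject variability
  of the subject medians by more than an order of magnitude.
* **A baseline settling trend** `A (1 − exp(−t/120 s))` with
  A ~ N(0.5, 0.3) µM per subject. Real recordings show slow monotone
  settling of probe coupling and superficial blood volume with a consistent
  average direction; it is this component that makes unremoved
  low-frequency content *systematically* inflate β for filters that do not
  cut below 0.01 Hz, rather than merely adding variance.
* **A smoothed random-walk drift** (0.8 µM RMS, 60 s smoothing), half
  channel-common and half channel-specific.
* **White measurement noise** (0.05 µM SD), independent per channel.

The HbR realization shares the subject's rhythms at 1/3 amplitude with
independent oscillator phases, and carries the settling trend and common
drift anti-correlated with HbO₂.

What this generator does *not* emulate: heavy-tailed subject populations
(drift and settling amplitudes are Gaussian, so the gross normality
violations and outlier subjects seen with real low-order filtering are
under-represented), spatial structure beyond one common/specific split,
non-stationary heart rate, infant spectral characteristics, and real
optode-physics artifacts. Passing ordering tests on this replica therefore
demonstrates the pipeline's behaviour under controlled, realistic spectra —
not a quantitative prediction for any particular device or cohort.

Everything is seeded: a master seed deterministically derives per-subject
streams, identical configurations reproduce datasets bit for bit, and the
three amplitude datasets share noise realizations (as when the same resting
recordings are reused with different injected components).

## Conversions and motion correction

The modified Beer–Lambert law is the linear map
`ΔOD_λ = (ε_HbO₂,λ ΔHbO₂ + ε_HbR,λ ΔHbR) · d · DPF` with source–detector
separation d = 3 cm and a differential pathlength factor of 6 applied to
both wavelengths (705/830 nm). Decadic extinction coefficients pair with
base-10 optical density throughout; the packaged coefficient table holds
approximate compiled literature values and is replaceable — every
acceptance-level property uses round-trip identities, so no result depends
on the specific coefficients. Because the map is linear and the filters are
LTI, filtering in OD space and converting commutes with converting and
filtering concentrations to numerical precision; the package verifies the
paired comparison reports "no difference", which is the substantive reason
the choice of filtering domain does not matter.

Motion artifacts (spikes, baseline shifts) can be injected and corrected
with targeted PCA: detection flags samples whose excursion within a 0.5 s
window exceeds 10 SDs of the channel's first difference (or an absolute
threshold), dilates flags by 1 s, and unions channels; correction removes
leading principal components of the flagged multi-channel segments until
97% of segment variance is gone, re-anchors each segment's left edge for
continuity, and re-detects up to 5 times. The SD is computed on first
differences to be robust to drifts. Outside the mask the signal is returned
bit-identical. These are the published parameter semantics of the
Homer2-style recursive tPCA; internals are an independent implementation,
and motion correction is off by default so filter comparisons do not depend
on it.

## Filter design conventions

All three families are realized as transfer-function coefficients:

* **Butterworth (BW)** via the bilinear transform; −3 dB at fc for a single
  pass. Applied forward–backward (zero phase), which squares the magnitude
  response — the realized attenuation at fc is −6 dB, and
  `amplitude_response()` reports the squared (realized) response.
* **FIR** linear-phase Hamming-window designs of length order + 1, −6 dB at
  fc; gain normalized to exactly 1 at DC (low-pass) or at the pass-band
  centre (band-pass). Applied in a single pass with the output advanced by
  the rounded group delay order/2 — the delay of a linear-phase FIR is
  constant over frequency, so a shift restores alignment.
* **Moving average**: a uniform window of length `round(0.443 · fs / fc)`,
  whose first −3 dB point falls at fc; low-pass only.

Edges are handled by odd (anti-symmetric) reflection padding of three
filter lengths, capped at the record length — a 1001-tap FIR on a
2900-sample record would otherwise lose a third of it — and the IIR passes
start from the steady state of the first padded sample so constants pass at
exactly the DC gain.

### Stability is a property of the realization

High-order IIR designs fail not because their *true* poles leave the unit
circle but because the transfer-function coefficients, once rounded to
double precision, define a polynomial whose roots do. Stability is
therefore judged on the coefficients exactly as designed, with pole
magnitudes computed as companion-matrix eigenvalues (the classical `roots`
algorithm) and a tolerance of `max |pole| < 1 − 1e-12`. Two band-pass cells
(order 5 with upper edges 0.09 and 0.2 Hz) sit so close to the boundary
that different root-finding algorithms disagree on them; the
companion-matrix route classifies the whole published grid correctly, while
a Jenkins–Traub root finder flips exactly those two cells. Designs whose
coefficients overflow to non-finite values (band-pass order 1000) are
classified unusable/unstable. Unstable designs are refused by
`apply_filter()` and recorded as skipped cells by the sweep, mirroring the
dashed table cells of stability-screened reports.

## GLM estimation and serial-correlation treatments

The design matrix has two columns: the unit-peak task regressor (identical
construction to the injected component) and a constant. β is the exact
least-squares solution. Because fNIRS is oversampled relative to the
hemodynamics, residuals are heavily autocorrelated; three treatments are
compared:

* **none** — plain OLS at 5 Hz;
* **downsample** — cubic-spline evaluation of the filtered data on a 1 Hz
  grid. The design columns are passed through the *same* spline operator as
  the data rather than being rebuilt by convolution at 1 Hz: spline
  evaluation is linear, so noise-free recovery stays exact to machine
  precision, which a re-discretized regressor would break at the percent
  level. No extra anti-alias filter is applied, since the evaluated filters
  already band-limit the data below the new Nyquist frequency;
* **precolor** — both the data and every design column are smoothed with
  the HRF kernel normalized to unit sum (preserving the constant column),
  using the same reflection-padded convolution. Precoloring does not make
  residual autocorrelation small — it makes it *known*, dominated by the
  kernel rather than by the unknown noise process; the tests assert exactly
  that (the precolored residual lag-1 autocorrelation is near the kernel's
  own and insensitive to the AR coefficient of the noise).

## Group statistics and the sweep

Per subject, the median β over non-excluded channels; per cell of the
factorial (filter spec × amplitude × signal domain × correction ×
chromophore), the Shapiro–Wilk W and p of the 18 subject medians, IQR fence
outlier flags (type-7 quartiles; fences `Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`;
outliers are reported, not removed, unless requested), and a two-sided
one-sample t-test of the medians against the reference β (df = 17 for 18
subjects). All tests are two-sided.

`rank_filters()` orders specifications by mean |t| (default), by
|p − 0.05|, or by mean absolute group bias, with deterministic tie-breaks
(lower order, then narrower band). The |p − 0.05| criterion is offered
because it is sometimes quoted as "closer to α is better", but it is a
statistically odd target; |t| and |bias| are reported alongside, and
rankings are computed per amplitude rather than silently pooled, since any
cross-amplitude weighting is a judgement call.

## Numerical choices

* Durations are converted to sample counts by rounding half up.
* Stability tolerance `1e-12` on the pole magnitude; round-trip identities
  asserted at `1e-10`; linearity at `1e-12`.
* Welch PSD: Hamming windows of 120 s with 50% overlap, one-sided density
  normalized by `fs · Σw²` (integral approximates the variance); a window
  longer than the record degrades to a single full-length segment with a
  warning.
* Kaiser FIR order estimate `N = (A − 7.95)/(2.285 · Δω)`, rounded up to
  even.
* Degenerate inputs error early and loudly: constant samples in the
  Shapiro–Wilk test, zero-variance t-tests, all-zero paired differences
  (reported as "no difference" — the OD-versus-concentration case),
  non-positive intensities with the offending index named.

## Problem sizes used by the test suite

The packaged tests run the full study geometry where it matters — 18
subjects × 16 channels at 5 Hz for the ordering properties, ten master
seeds for the precoloring comparison — and a reduced geometry (6 × 8) for
the domain-equivalence sweep; these sizes are the package's choice of a
replica large enough for stable group statistics while keeping the suite
convenient to run.

## Known limitations

* The ranking criteria are deliberately simple. Ranking by raw |t| rewards
  a noisy but unbiased filter over a precise one with a small systematic
  bias: a properly specified narrow band-pass removes task harmonics above
  its upper edge and therefore carries a few-percent attenuation bias with
  small variance, which |t| penalizes heavily. On this package's replica
  the low-order FIR cells consequently achieve *smaller* |t| than the
  recommended order-1000 band-pass — the same structure visible in
  stability-screened real-data reports, where low-order FIR rows show small
  t but fail normality with outlier subjects. A practical selection should
  therefore combine |t| or |bias| with the normality and outlier
  diagnostics the sweep records, as `group_result` exposes them.
* With Gaussian subject-level drift amplitudes, the low-pass specifications
  fail chiefly by variance and trend bias on ΔHbO₂; on ΔHbR (small
  reference β) their pooled bias can sit within noise of the recommended
  band-pass cell's attenuation bias, so LP-versus-BP margins on the replica
  are small even where the qualitative direction is clear.
* The MBLL implementation is differential only (no partial volume or
  wavelength-dependent DPF), the tPCA is an independent re-implementation
  of the published parameter semantics, and the SNIRF/HDF5 interface is not
  included — datasets exchange as delimited text with JSON sidecars.
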