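---
title: "Methods: frequency-specific cortical activity networks from sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-specific cortical activity networks from sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortnet)
```

## The analysis problem

During N2 sleep the infant cortex produces spontaneous oscillatory
activity whose long-range coordination can be measured from
high-density scalp EEG.  `cortnet` estimates that coordination as
frequency-specific *functional connectivity networks* in cortical
source space, in two intrinsic coupling modes:

* **Amplitude–amplitude coupling (AAC)** — co-modulation of the slow
  amplitude envelopes of two band-limited signals, interpreted as
  comodulation of gross cortical excitability over seconds.
* **Phase–phase coupling (PPC)** — consistency of the instantaneous
  phase difference, reflecting fast, millisecond-scale coordination.

Each of 58 cortical parcels is a network node; each of the
`choose(58, 2) = 1653` parcel pairs is an edge.  Per subject, band and
mode the pipeline produces a symmetric 58 × 58 adjacency matrix, and
group statistics compare those matrices across clinical strata
(epilepsy syndrome; neurocognitive outcome at one and two years; the
outcome *trajectory* between those ages).

Scalp EEG mixes every cortical source into every electrode (volume
conduction), so naive sensor-space correlations are dominated by
zero-lag artefacts.  The pipeline addresses this three ways:
estimators that ignore zero-lag coupling (orthogonalized envelope
correlation; weighted phase-lag index), source reconstruction before
network estimation, and simulation-based pruning of parcel pairs that
the sensor array cannot resolve.

## Filter bank

The spectrum from 0.5 to 39.7 Hz is tiled by 25 narrow bands whose
centre frequencies follow a geometric ladder, `fc[k+1] = 1.2 fc[k]`
starting at 0.5 Hz.  Each band is a linear-phase Kaiser-window FIR
band-pass with passband `[0.85, 1.15] fc`, stopband edges
`[0.5, 1.5] fc`, and at least 40 dB stopband attenuation; the measured
response at the centre stays within 1 dB of unity.  Orders come from
the standard Kaiser estimate over the 0.35 fc transition, with cutoffs
at the transition midpoints and a 6 dB design margin so the contract
holds at the stop edges themselves (verified in the tests by
evaluating the designed response).  Filters are applied zero-phase
(symmetric FIR with group-delay compensation) because any filter phase
would bias the phase metrics downstream.  Discontinuous N2 segments
are filtered independently, one filter length is trimmed from each
segment end, and segments shorter than three filter lengths are
skipped for that band.

Broadband conditioning (0.15–48 Hz) uses the same design.  A 0.15 Hz
high-pass corner at 40 dB implies a filter several seconds long; the
synthetic pipeline therefore skips conditioning (its generator is
already in-band) and `condition_broadband()` exposes a `trim` switch
for real recordings.

Working sampling rate is 250 Hz; decimation applies a 60 dB Kaiser
anti-alias low-pass before subsampling.  Bad channels are replaced by
spherical-spline estimates (order `m = 4`, 50 Legendre terms, ridge
`1e-8`) before average re-referencing.

## Source model

The forward model is deliberately modular: real analyses supply a gain
matrix and parcel assignment from an MRI/BEM pipeline (tissue
conductivities 1.79 / 0.1 / 0.43 S/m are carried as metadata); for
development and validation `make_toy_bundle()` builds a desk-scale
spherical head: sensors on the upper unit hemisphere, radially
oriented dipoles at relative depths 0.6–0.85, and the analytic
homogeneous-sphere potential

$$V(R, \theta) = \frac{p}{4 \pi \sigma R^2}
  \sum_{n \ge 1} (2n+1) f^{\,n-1} P_n(\cos\theta), \qquad f = b / R.$$

Parcels are contiguous angular patches (seeded k-means on dipole
directions) labelled by region (frontal / central / temporal /
occipital × hemisphere) from their centroids.

The inverse is the minimum-norm kernel
$K = G^\top (G G^\top + \lambda C)^{-1}$ with **identity noise
covariance** $C = I$ and no depth prior ($R = I$), normalized per
source by $\sqrt{\mathrm{diag}(K K^\top)}$ (dSPM).  The
regularization default follows the SNR rule
$\lambda = \mathrm{tr}(G G^\top) / (n_{\mathrm{sens}} \cdot
\mathrm{SNR}^2)$ with SNR = 3; both are configurable because no
canonical value exists for this quantity.  Dipole estimates are
averaged within each parcel (fixed radial orientations make the plain
mean well defined without sign-flipping).  The whole
sensor → source → parcel chain is linear and is precomputed as one
matrix (`parcel_operator()`) where repeated application matters.

With the *identity bundle* (one sensor per parcel, unit gain) the
source stage is a null transformation, which gives the pipeline a
powerful self-test: connectivity measured at the sensors must equal
connectivity at the parcels.

## Connectivity estimators

Both estimators operate on the analytic (Hilbert) signal of each
band-filtered parcel time course, computed per continuous segment.

**oCC (AAC).**  In non-overlapping 1 s windows, the analytic signal of
one member is orthogonalized against the other sample-wise,
$y_{\perp x}(t) = \Im\!\left[ y(t)\, \overline{x(t)} / |x(t)| \right]$,
removing the component sharing x's instantaneous phase — exactly the
part volume conduction can produce.  The envelopes $|y_{\perp x}|$ and
$|x|$ are concatenated across windows and Pearson-correlated; the
procedure is repeated with roles swapped and the two coefficients
averaged.  Values lie in [−1, 1]; `y = x` gives exactly 0.  Envelopes
are linear (a log-envelope option exists in the code path for users
who prefer the log convention).

**dwPLI (PPC).**  Per window $j$, $I_j = \Im\,\overline{S}_{xy}$ is
the imaginary part of the window-mean cross-spectrum; the debiased
squared weighted phase-lag index is

$$\mathrm{dwPLI} = \frac{(\sum_j I_j)^2 - \sum_j I_j^2}
  {(\sum_j |I_j|)^2 - \sum_j I_j^2}.$$

Consistent nonzero lags give 1; zero-lag coupling gives 0; under
independence the numerator is a sum of cross-products with zero mean,
so the estimator is unbiased where the plain squared ratio has a
$\mathcal{O}(1/n_{\mathrm{win}})$ positive bias (both facts are
verified by Monte-Carlo in the tests).  Raw values can be slightly
negative; adjacency matrices store the clipped value (0–1 convention)
and keep the raw copy.  dwPLI windows default to `max(1, 4/fc)` s so
every cross-spectral sample holds at least four carrier cycles; this
windowing is a package choice, as is the non-overlap convention shared
with oCC.

Adjacency diagonals are masked (`NA`), never 0 or 1, so they can never
leak into global means.

## Fidelity pruning

Even in source space some parcel pairs are unresolvable with 64
sensors.  For every pair the package simulates activity in which only
that pair is synchronized (a shared band-limited oscillation at a
quarter-cycle lag, default 10 Hz carrier — configurable, as no
canonical simulation band exists), projects it through the forward
model, reconstructs parcels with the inverse, and correlates
reconstructions with the original artificial activity.  The pair
statistic per iteration is the *minimum* over the two members of the
correlation with their own original signal (the conservative
combiner); the surrogate pool collects, globally over all pairs and
iterations, the absolute correlations between *non-synchronous*
reconstructed parcels and the synchronized activity — the signal
leakage null.  A pair survives when the median of its statistic beats
the surrogate 99th percentile.  The reference analysis runs 500
iterations per pair; the package tests run 10–50 (the decision is a
median against a pooled percentile, which stabilizes quickly, and the
tests check seed-to-seed stability of the excluded fraction at ±1
percentage point).  The mask depends only on the head model, the
inverse, the parameters and the seed — never on subject data — and is
applied uniformly to every subject's matrices.

## Sleep spindles

Spindles (11–15 Hz waxing–waning bursts, the hallmark of N2) are both
a detection target and a potential confound for sigma-band networks.
The per-channel detector band-passes to 11–15 Hz, forms a smoothed
(0.1 s moving average) Hilbert envelope, flags excursions above
3 × the channel mean envelope, extends them down to 1.5 × the mean,
and keeps durations in [0.5, 3] s.  Candidates are then gated by
cross-channel evidence: the summed squared envelope over all channels
must peak, inside the candidate, above θ (default 0.5) times the mean
of all candidates' peaks of that summed envelope, computed once per
recording (the per-recording reading of "mean peak amplitude";
θ = 0 disables the gate).  Detector constants follow the common
envelope-detector family and are all exposed in `spindle_params()`.

Gated intervals separated by gaps ≤ 1 s merge into *spindle groups*;
`spindles_per_group` counts channel-level detections inside the group
span — the only reading under which a 1–2 s group can contain ~15
events.  Spindle *removal* excises the gated intervals (± 0.25 s pad)
and re-segments the record, so no filter or window ever spans a cut;
zero-padding or amplitude zeroing would instead manufacture spectral
artefacts.  Records left with under 3 minutes are flagged.

## Group statistics

Per band and mode: the per-subject global mean over unmasked edges
feeds a Kruskal–Wallis test across groups; edge-wise one-tailed
Wilcoxon rank-sum tests (both directions, e.g. Typical > Mild and
Mild > Typical) are corrected with Benjamini–Hochberg at α = 0.05 per
(band × mode × direction) family; the **network density K** is the
fraction of unmasked edges significant after correction.  Rank-sum
p-values are exact when the smaller group has ≤ 10 subjects and
tie-corrected normal otherwise.  The effect size is the rank-biserial
correlation $r = 1 - 2U/(n_A n_B) \in [-1, 1]$ — chosen because it is
the natural companion of the rank-sum statistic; reported magnitudes
are therefore not claimed to equal any other ES convention.
Trajectory analysis groups subjects by their 1 y → 2 y outcome pair,
drops groups below two subjects, and tests only pairs sharing the
1-year label, BH-corrected across bands.  Because every test is
rank-based, K is invariant under any monotone transform applied
uniformly to all subjects — a property the tests check directly.

Region summaries report, for each region and region pair, the
fraction of possible (unmasked) edges that are significant, plus the
centroid-distance distribution of significant edges (log scale when
plotted) and the interhemispheric fraction.

## The synthetic generator — what it emulates and what it does not

No public recordings accompany the underlying study, so validation
rests on a generator whose ground truth is known exactly:

* **Background**: $1/f^{1.1}$ noise with a Gaussian sigma bump at
  12 Hz (relative amplitude 0.6), mimicking the infant N2 spectrum;
  slope and bump are configurable.
* **Envelope coupling**: both members' log-normal slow envelopes
  (log-sd 0.4, modulator band 0.1–0.5 Hz) mix a shared modulator with
  a weight solved *on the log scale* so the envelope Pearson
  correlation hits the target exactly for log-normal marginals:
  $\rho_z = \log(1 + \rho(e^{\sigma^2}-1)) / \sigma^2$.  Carriers are
  phase-independent by default; a `locked` option fixes a carrier lag
  (e.g. π/2) so that orthogonalization preserves the full envelope —
  the configuration used when validating oCC recovery end to end.
* **Phase coupling**: a shared drifting carrier with a fixed lag plus
  von Mises jitter (Best–Fisher sampler), concentration exposed.
* **Spindles**: raised-cosine bursts at 11–15 Hz, Poisson-placed
  without overlap or at fixed times, with exact truth intervals.
* **Sensor stage**: gain projection plus spatially white Gaussian
  noise at a target SNR.  No line noise (analyses live below 48 Hz)
  and no ocular/muscle artefacts — the generator validates the
  estimators and statistics, not artefact robustness.  Passing tests
  therefore demonstrate correct recovery of known couplings through
  the chain, not performance on artefact-laden clinical data.

Cohort-level fixtures exist at two scales: full signal cohorts
(`simulate_cohort()`, per-group coupling offsets on a designated pair)
and matrix-level cohorts (`simulate_cohort_matrices()`, per-subject
adjacency matrices with offsets implanted in a chosen edge set), the
latter used for FDR-control and type-I simulations where re-running
the signal chain for hundreds of cohorts would add nothing but time.

## Numerical choices and problem sizes

Determinism: every stochastic function takes an explicit seed and
restores the caller's RNG state; identical (inputs, seed) give
bit-identical outputs.  FIR filtering runs via FFT convolution with
exact group-delay alignment.  Degenerate inputs are flagged, not
silently zeroed: zero-envelope oCC inputs and all-zero cross-spectra
return 0 with a `degenerate` attribute; constant edges record p = 1.

The shipped validation suite uses desk-scale sizes chosen to exercise
every contract while staying comfortably reproducible on one CPU:
60–600 s records, 2–58 parcels, 8–64 sensors, 10–50 fidelity
iterations, 50-seed FDR simulations at n = 15 per group, 200-seed
null calibrations, and 1000-replicate type-I checks.  The full-scale
settings (500 fidelity iterations, 25 bands, 10-minute records) are
the package defaults in `pipeline_config()`.

## Known limitations

* Average re-referencing mixes every channel into every other with
  weight 1/n.  When two sources carry a *consistent nonzero* phase
  lag, their re-referenced mixtures have genuinely lagged components,
  which no zero-lag-insensitive estimator can reject; at 64 channels
  the 1/64 leakage is negligible, but on very small montages (such as
  the 6–8 channel identity bundles used in smoke tests) it is visible.
  Cohort simulations therefore default to phase-independent carriers
  for envelope coupling, keeping the phase channel null.
* The toy head model is a single-shell sphere; it reproduces the
  geometry-dependent *structure* of leakage, not infant-specific
  conductivity profiles.  Real analyses should supply their own gain
  and parcellation.
* Spindle detector constants are declared package defaults, not
  values inferred from any clinical dataset.
* The oCC orthogonalization is instantaneous (sample-wise within
  windows); frequency-domain orthogonalization variants would differ
  in detail.
* Cohort-level clinical findings (specific p-values, effect sizes,
  densities of the motivating study) depend on the clinical recordings
  and MRI head model and are out of scope; the package reproduces the
  *machinery* and validates it on synthetic ground truth.
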