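---
title: "Methods: PLI connectivity and MST topology for resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity and MST topology for resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmst)
```

## The problem

Alzheimer's disease (AD) disrupts the coordination of neural oscillations
long before structural imaging shows damage. Resting-state EEG offers a
cheap, non-invasive window on this: if two cortical regions oscillate with
a consistent phase relationship, they are presumed to communicate. The
difficulty is that (a) a single neural source is volume-conducted to many
electrodes, producing spurious *zero-lag* correlations, and (b) comparing
full weighted connectivity graphs across people requires arbitrary
thresholds. This package implements the standard two-step answer:

1. **Phase Lag Index (PLI)** connectivity, which is blind to zero-lag
   coupling by design, and
2. **minimum spanning tree (MST)** topology, which reduces every subject's
   graph to a canonical N-node, (N−1)-edge backbone so that topological
   metrics are comparable without any threshold.

On top sit nonparametric group statistics (Kruskal–Wallis with Dunn
post-hoc and Holm–Bonferroni control), covariate-adjusted correlations with
clinical scores and CSF biomarkers, and single-feature ROC discrimination
between the diagnostic groups HC (healthy control), MCI-AD (mild cognitive
impairment due to AD) and AD.

## Preprocessing model

The chain is fixed: EOG removal → average re-referencing → broad 0.5–48 Hz
band-pass → downsampling to 250 Hz → per-band band-pass → 2 s epoching →
amplitude-based rejection (default peak-to-peak limit 100 µV, minimum 40
surviving epochs). Notable choices:

* **Zero-phase filtering.** Filters are Hamming-windowed sinc FIR designs.
  A symmetric FIR applied once with group-delay compensation has exactly
  zero phase response, so we use a single pass rather than forward–backward
  filtering; the numerical result honours the same contract (no phase
  distortion, configurable transition width, ≈53 dB stop-band). The default
  transition width is `min(low edge, 2 Hz)` so the 0.5 Hz high-pass edge of
  the broad filter stays sharp.
* **Band filtering before epoching.** Filtering the continuous signal and
  cutting epochs afterwards avoids filter edge artifacts inside the short
  2 s windows. The alternative order is not exposed because there is no
  analysis benefit to offset its cost.
* **Automated artifact rejection.** Visual inspection is not reproducible;
  an epoch is rejected when any channel's peak-to-peak amplitude exceeds
  the limit. Rejection is monotone in the limit and the dropped indices are
  logged.
* **Downsampling by decimation.** 1000 → 250 Hz keeps every 4th sample;
  this is alias-free because the preceding 0.5–48 Hz filter removed all
  content above the new 125 Hz Nyquist. Non-integer factors use Fourier
  resampling behind an explicit opt-in.

## The PLI estimator

For two channels with instantaneous phases φᵢ(t), φⱼ(t), the PLI is

$$\mathrm{PLI} = \left| \langle \mathrm{sign}\, \sin(\varphi_i(t) - \varphi_j(t)) \rangle \right| \in [0, 1].$$

Phases come from the analytic signal (FFT-based Hilbert transform) of each
band-limited epoch. Conventions that the text of most papers leaves open,
fixed here:

* **sign(0) = 0**, so exactly zero-lag (e.g. volume-conducted) pairs give
  PLI = 0 rather than an arbitrary ±1.
* **Per-epoch averaging.** PLI is computed within each 2 s epoch over the
  retained samples and then averaged across epochs (pooling all samples is
  available via `pool_samples = TRUE`; the two coincide when every epoch
  shares the same lag distribution).
* **Edge exclusion.** 5% of samples at each epoch boundary are excluded
  from the average to suppress Hilbert transform edge effects
  (configurable via `edge_fraction`).
* **Degenerate channels.** A zero-variance channel in an epoch has no
  defined phase; that epoch is skipped for pairs involving the channel,
  with a warning.

The pairwise accumulation runs in compiled code; everything else is plain R.

## MST construction and metrics

Edge weights are `1 − PLI`, so the spanning tree of minimal total weight
keeps the strongest couplings. Kruskal's algorithm sorts edges ascending
and adds each unless it closes a cycle; ties are broken lexicographically
by channel index pair, making the tree bit-reproducible on degenerate
inputs (this matters only when weights collide exactly; the selected edge
set is provably invariant under any strictly increasing reweighting, which
the tests check).

With N nodes and M = N − 1 edges, the metric suite is:

| metric | definition | star (N=62) | chain (N=62) |
|---|---|---|---|
| degree max | max node degree | 61 | 2 |
| BC max | max betweenness, normalized by (N−1)(N−2) | 1 | ≈0.5 |
| diameter | max hop distance / M | 2/61 | 1 |
| eccentricity | mean over nodes of max hop distance / M | ≈2/61 | 46/61 |
| leaf fraction Lf | #degree-1 nodes / M | 1 | 2/61 |
| tree hierarchy Th | L / (2·M·BCmax) | 0.5 | →0 |
| kappa | ⟨k²⟩/⟨k⟩ (degree divergence) | 31 | ≈1.98 |

Conventions fixed here because the source material is ambiguous:

* **Hop-count distances.** Eccentricity and diameter use unweighted hop
  distances normalized by M. This is the only convention under which
  published group-level eccentricities around 0.7 and diameters around
  0.85 are attainable; a weighted-distance variant would live on a very
  different scale. Betweenness uses ordered-pair counting with the printed
  1/((N−1)(N−2)) normalizer, so a star centre scores exactly 1.
* **Kappa** is read as the standard degree divergence ⟨k²⟩/⟨k⟩ — the
  definition used throughout the MST brain-network literature for "breadth
  of the degree distribution".
* **Mean eccentricity** (not per-node values) is the group-comparison
  variable, and each band's mean PLI rides along as the eighth variable.

## Group statistics

Kruskal–Wallis (tie-corrected, χ² approximation) is the omnibus per
(band, metric) cell; Dunn's test (pooled-rank z with tie correction)
runs only where the omnibus is significant at α = 0.05 two-sided. Holm
adjustment is applied to the omnibus p-values **within each band** (8
metrics per family, 5 families) by default; a global family is available.
The source text says only that Holm was used "to control for multiple
testing", so the family boundary is a package decision — per-band was
chosen because the five bands are conventionally reported as separate
analyses. Whether Dunn p-values are themselves Holm-adjusted is equally
unstated; raw Dunn p-values are the default (`adjust_dunn = FALSE`).

Partial correlations residualize both variables on the covariates (sex
coded 0/1, age and education linear) and correlate the residuals with
degrees of freedom reduced by the covariate count; an empty covariate set
reduces exactly to plain Pearson.

## ROC discrimination

One feature at a time: stratified 50/50 split (seeded, odd subjects go to
the training half), univariate logistic fit on the training half, test-half
scores ranked into an empirical ROC with trapezoidal AUC. The 95% CI is a
2,000-resample stratified bootstrap over the test half, and the p-value
against AUC = 0.5 is the rank-sum test on the two classes' scores — both
computed on the test half only, since the split exists to keep evaluation
honest. AUC is a rank statistic, so the logistic model changes nothing for
a monotone univariate score; it is retained for interface fidelity with
the published analysis.

## The synthetic cohort: what it emulates, and what it does not

Real recordings from the clinical study are not deposited, so the package
ships a generator whose *defaults are the stated world*: 62 scalp + 2
ocular channels, 1000 Hz, 480 s eyes-closed, group sizes 30/14/21
(HC/MCI-AD/AD). Per band, a latent narrowband process (band-filtered white
noise) is mixed into every channel with a channel-specific constant phase
offset — implemented by rotating the latent analytic signal, which is
exact at all frequencies, unlike an integer sample delay — and an
amplitude proportional to the subject's coupling strength in that band.
Independent broadband noise (8 µV), occasional broadband artifact bursts
(rate 0.04 per 2 s block, 200 µV SD) and two low-frequency ocular channels
complete the recording.

Parameters that required a one-time decision:

* **Coupling defaults** encode theta-up/beta-down in AD with MCI-AD
  intermediate in theta and AD-like in beta (see `default_coupling()`),
  with between-subject jitter SD 0.03.
* **Band amplitudes** (delta 3, theta 2.8, alpha 3.2, beta 5, gamma 10 µV
  at the 8 µV noise floor) were calibrated once so the realized HC band
  mean PLI lands in the 0.2–0.32 range reported for real cohorts, and then
  frozen.
* **Effect sizes are deliberately larger than clinical.** The published
  group differences (≈1 SD) cannot reliably clear a 0.8 test-half AUC with
  ~25 test subjects; the generator's defaults produce a clearly separated
  AD group so that the *pipeline-recovery* property (sign pattern plus
  AUC > 0.8 in ≥ 90% of replicate cohorts) is a meaningful test of the
  code rather than a coin flip on sampling noise.
* **Phase offsets** are drawn once per cohort from the master seed,
  uniformly on ±(0.35, π−0.35) — avoiding the exact offsets 0 and π at
  which the PLI is blind by construction. Pairwise offset differences may
  still fall near those blind spots, which simply lowers some pairs' PLI,
  as in real data.
* **Clinical scores and CSF values** are group-mean draws (means/SDs from
  the published cohort demographics where printed; HAMA/HAMD/ADL values
  are invented plausible stand-ins) plus a linear link to the subject's
  theta/beta coupling deviations, with signs arranged so that t-Tau rises
  with beta coupling, p-Tau falls with theta coupling, and Aβ1–42 rises
  with theta coupling. These exist to give correlation-sign tests
  something real to find; they are not a disease model.

What a green test does **not** establish: the generator has no 1/f
spectral background, no volume-conduction mixing matrix (zero-lag
insensitivity is tested with explicit zero-lag channels instead), no
non-stationarity, and no realistic artifact taxonomy. It validates the
estimators and the pipeline plumbing, not clinical effect sizes.

## Numerical choices and degenerate inputs

* FFT convolution sizes are padded to 2-3-5-smooth lengths; signals are
  reflection-padded so filtered outputs keep the input length.
* A recording shorter than one epoch, a band edge at or above Nyquist, an
  unconnected weight graph, a sub-3-node tree (betweenness undefined), a
  zero-variance correlation input, and a split with a singleton class all
  raise immediate, specific errors rather than propagating NaN.
* All randomness — cohort generation, splits, bootstraps — flows from
  explicit integer seeds recorded in outputs (`split_seed`, the cohort
  manifest), making every pipeline product reproducible byte-for-byte.

## Known limitations

* The EDF writer quantizes to 16 bits over each channel's range (the
  format's own limit); round-trips are exact only to that precision.
* The BrainVision reader supports the common binary multiplexed layouts
  (IEEE float 32 and int 16), not the vectorized or ASCII variants.
* Weighted-distance tree metrics, weighted PLI variants, coherence and
  source-space analysis are intentionally out of scope.
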