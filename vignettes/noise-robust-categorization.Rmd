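---
title: "Categorizing auditory responses to vocalizations in noise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing auditory responses to vocalizations in noise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisecat)
```

# The problem and the measurement model

Auditory neurons confronted with a vocalization embedded in masking noise
distribute along a continuum between two extremes: responses that track the
vocalization regardless of the masker, and responses that track the masker
regardless of the vocalization. `noisecat` quantifies where on this
continuum a multiunit recording sits, separately for each
signal-to-noise ratio (SNR) and each masker type, and turns the resulting
profiles into five named categories whose stability, masker dependence and
predictability can then be studied.

The measurement unit is one *recording*: all trial blocks of one
electrode site under a fixed stimulus protocol — four vocalizations in
quiet and embedded in two maskers (a spectrally matched stationary noise
and a naturalistic chorus noise) at SNRs of +10, 0 and −10 dB, the two
maskers alone, and a block of 129 pure tones covering eight octaves. All
spike times are trial-relative seconds with trial start at zero; each
block stores its own stimulus onset, so a 200-ms pre-onset window is
always available for spontaneous activity.

# The extraction index

For PSTHs built with 4-ms bins on the evoked window (repetition-averaged,
spikes/s), the extraction index of a noisy-condition response
$P_{snr}$ against the clean reference $P_v$ and the noise-alone reference
$P_n$ is

$$D_{x\text{-}snr} = 1 - \frac{P_x \cdot P_{snr}}{\lVert P_x\rVert\,
\lVert P_{snr}\rVert}, \qquad
EI = \frac{D_{n\text{-}snr} - D_{v\text{-}snr}}
          {D_{n\text{-}snr} + D_{v\text{-}snr}}.$$

The sum in the denominator is what bounds EI in $[-1, 1]$ and is the form
implemented here. Cosine distances make EI invariant to multiplying any
PSTH by a positive constant, and exactly antisymmetric under swapping the
two references; both properties are enforced by tests on random vectors.

Windowing: all three PSTHs of one comparison share the vocalization's
window length. The clean window starts at the vocalization onset; the
noisy-condition and noise-alone windows start where the signal occurs (or
would have occurred) inside the masker — `signal_onset_in_masker_s`,
default 0.200 s after masker onset, with a 0.300-s signal window inside
the 0.564-s masker analysis period. Windows are clipped to what the trial
actually holds rather than rejected.

Degenerate inputs have explicit conventions: if exactly one vector of a
cosine pair is all-zero the distance is 1 (a silent response is maximally
dissimilar to an evoked one — this keeps silent-in-noise responses
classifiable); if both are all-zero the distance, and hence the EI, is
undefined and flagged rather than invented. EI per (noise, SNR) is the
mean over the four per-vocalization EIs, skipping undefined ones; the
alternative of concatenating the four PSTH vectors before a single EI is
available (`aggregate = "concat"`) but averaging is the default because it
keeps each vocalization's own clean reference.

## Surrogate significance

An EI value is only meaningful if the response carries temporal structure;
a flat response produces EI estimates scattered around zero. Each
recording therefore gets per-(noise, SNR) thresholds from 100 surrogate
replicates in which every condition is replaced by homogeneous Poisson
activity matched to that condition's measured evoked rate, trial count and
window; the threshold is the surrogate mean + 2 SD, and a recording is
retained only if at least one of its six EI values exceeds its threshold.
Because the cosine distances are scale invariant, the surrogates are drawn
directly as Poisson bin counts of the pooled PSTH
($k_b \sim \mathrm{Pois}(n_{trials}\, r\, \Delta)$), which has exactly the
distribution of binning that many homogeneous Poisson spike trains and is
an order of magnitude faster. The surrogate distributions are kept per
SNR, not pooled.

This filter is one-sided ("significantly higher"), which has a
consequence worth stating: a recording whose six EI values are all
negative can only be retained through none of them — in practice such
masker-like recordings enter cohorts through their cells in the *other*
noise type, where they are usually not masker-like. The synthetic recovery
cohort (below) reflects this.

# Categorization

Per noise type, the 3-value EI profiles of all selected recordings are
clustered by K-means: Lloyd iterations, Euclidean distance, k-means++-
style seeded initialization, best of 50 restarts by the clustering MSE
$\frac{1}{N}\sum_i \lVert \mathrm{EIP}_{cluster(i)} - \mathrm{EIP}_i
\rVert^2$. k = 5 is canonical; the elbow sweep `elbow_curve()` over
k = 1..10 is a diagnostic, not an automatic selector. Clustering runs per
noise type on 3-value profiles (rather than once on 6-value joint
profiles) because categories are defined, reported and compared per noise.

Cluster naming is a deterministic rule on two centroid features —
$m$ = mean EI and $r$ = EI(+10 dB) − EI(−10 dB): the all-negative centroid
with the lowest $m$ is *masker-like* (fallback: lowest $m$); among the
rest the largest $r$ above the remaining median is *balanced*; the highest
remaining $m$ is *signal-like*; the smallest remaining $|m|$ is
*insensitive*; the remainder is *signal-dominated*. Ties break by
descending $m$, then cluster index. The rule is this package's own
construction (human inspection is the usual practice); it is validated on
centroid shapes matching the category definitions and is permutation
invariant by construction.

**Bootstrap stability.** For each recording and noise, 100 replicates
resample the 20 trials of every condition independently with replacement,
recompute the PSTHs and the EI profile, and reallocate the profile to the
nearest *original* centroid. The modal category count (out of 100) is the
stability; ≥ 95 marks the recording *reliable*. Replicates with an
undefined EI fall into an explicit `"undefined"` outcome that counts
against stability. Resampling is implemented as multinomial weight vectors
multiplying per-trial count matrices, so a recording whose trials are
identical is exactly invariant (100/100 by construction).

# Noise-type switching and mutual information

The 5 × 5 switching matrix counts recordings by (category in stationary
noise, category in chorus noise); rows are stationary. Switch percentages
per category are $100(1 - \text{diag}/\text{row sum})$, per structure the
same fraction on that structure's recordings. Mutual information is the
plug-in Shannon estimate in bits with zero cells contributing zero and no
bias correction — the identities MI = log₂ 5 for a diagonal equal-count
matrix, MI = 0 for an outer-product matrix, and
0 ≤ MI ≤ min(H(rows), H(cols)) are enforced exactly in tests.

# Descriptors and classification

Twelve descriptors per noise type, in four groups: **tfrp** (BF firing
rate in spikes/s, tuning bandwidth in octaves, response duration in ms),
**signal** (clean-vocalization firing rate and CorrCoef, averaged over the
four vocalizations), **masker** (masker firing rate and CorrCoef over the
0.564-s analysis period, the adaptation ratio FRm300/FRm200, and the
spike counts of the first and last 50 ms), and **signal_to_masker**
(signal rate over FRm200 and over FRm300). FRm200 is the rate over the
first 200 ms of the masker; FRm300 the rate over the 300-ms window where
the signal would have occurred. Ratios with zero denominators are flagged
NA and imputed with the column median; recordings with more than three
imputed descriptors are excluded from classification.

The classifier is a linear discriminant with shared within-class
covariance, empirical priors, and a small fixed ridge
($10^{-6}\,\mathrm{tr}(S)/p$ added to the diagonal) so collinear
descriptors at small n cannot break the fit. Descriptors are standardized
on each training fold only (no test leakage). The cost matrix (0 diagonal,
2 for predicting *insensitive* when the truth is anything else, 1
elsewhere) is applied at the decision stage — predictions minimize
expected cost under the posterior — not by reweighting training. Folds are
stratified and seeded; the 15 descriptor-group combinations are enumerated
with TFRP-containing subsets first (1 = all four, 8 = TFRP alone,
12 = signal alone, 14 = masker alone, 15 = signal-to-masker alone) and
evaluated on identical folds. `generalize_lda()` fits once on the reliable
cohort and evaluates on the disjoint remainder.

The trial-to-trial reliability CorrCoef is the mean Pearson correlation
over all unordered trial pairs of 1-ms-binned spike trains convolved with
a Gaussian kernel. The printed prefactor of the usual pairwise-covariance
formula ($1/N(N-1)$ with a sum over $i<j$) would score identical trains
0.5; the pair mean used here scores them 1, which is the behavior a
reliability index bounded by 1 needs. The "10-ms" Gaussian window is read
as $\sigma$ = 10 ms. Pairs in which either smoothed trace has zero
variance are excluded; with no valid pair the index is flagged undefined.

# Tone-tuning quantification (TFRP)

Per tone frequency, a 1-ms-bin PSTH over the 100 ms after tone onset gives
a 100 × 129 rate map, smoothed with a uniform 5 × 5 window whose edge
cells renormalize over the available sub-window (values stay true local
means). Baseline statistics come from the 50-ms pre-onset window pooled
across frequencies and smoothed identically, using full-window cells only.
Significance requires a 4-connected region above baseline mean + 6 SD,
with two robustness rules motivated by Poisson counting at multiunit
spontaneous rates: edge cells' thresholds widen by $\sqrt{25/n_{window}}$
(their means average fewer cells, so their sampling variance is larger),
and the supra-threshold region must exceed one 5 × 5 window footprint,
because a single hot 1-ms bin smears into exactly one window of speckle.
Under flat Poisson input at 4–10 spikes/s the empirical false-positive
rate is then below 5% (0/200 in the shipped calibration test, against
~14% without the two rules). BF is the frequency of the global maximum of
the smoothed map; bandwidth is the octave span and response duration the
time extent of the largest significant region.

The evoked-versus-spontaneous response test is a two-sided paired Wilcoxon
signed-rank on per-trial rates (the natural rank-based choice at n = 20),
falling back to a sign test below six nonzero differences; all-zero
differences give p = 1.

# The synthetic generator

Every synthetic recording is an inhomogeneous Poisson process built from
latent ingredients fixed per recording: a sparse sum of half-cosine bumps
as each vocalization's rate envelope (mimicking whistle amplitude
envelopes), a masker envelope per noise type, a Gaussian log-frequency
tuning bump for tones, and an exponential short-term adaptation profile
(floor 0.5, τ = 0.15 s) on the masker response. A *category archetype*
mixes the vocalization and masker envelopes with SNR-dependent weights
$w_{sig}, w_{mask}$; trials get a unit-mean lognormal gain (CV 0.15–0.2)
and Gaussian spike-time jitter (2–6 ms) that controls temporal
reliability.

The default archetypes were calibrated once, before any acceptance
measurement, to two published constraints on the category profiles: the
noise-free template EIs must land in the category sign regions
(signal-like > 0.5 at +10/0 dB; masker-like < 0 everywhere; balanced from
> 0.5 at +10 dB to < 0 at −10 dB), and chorus noise must impact responses
more than stationary noise. The second constraint is why the chorus
envelope — bumpy, built like a superposition of calls — is normalized to
the same mean energy as the flat stationary masker: without that
normalization the chorus masker component is energetically weaker and the
EI ordering between the noises comes out backwards. Rates are
multiunit-scale (baselines 3–5 spikes/s, evoked gains 50–150 spikes/s);
at lower rates the Poisson noise floor of 4-ms/20-trial PSTHs inflates
both cosine distances and compresses every EI toward zero, which no
clustering can undo.

The recovery study condition is a *crossed cohort*
(`crossed_cohort_counts()`): a balanced 5 × 5 joint over (stationary
category × chorus category), ten recordings per pair — 50 recordings per
category per noise, 80% of them noise-type sensitive. This matters because
of the one-sided surrogate filter: recordings masker-like in *both*
noises can essentially never pass it, so a switch-free cohort loses its
masker-like column before clustering. Cohorts with substantial switching
are also what the analysis is designed for.

What the generator does **not** emulate: spectral content (everything is
a rate envelope; there is no acoustics), correlated noise across trials
beyond a shared gain, non-Poisson spiking statistics (refractoriness,
bursting), electrode drift, or any structure-specific response physiology
— structure labels are bookkeeping for the reporting layer. Passing tests
therefore show that the analysis chain recovers what it assumes, not that
real data satisfy those assumptions.

# Determinism and problem sizes

Every source of randomness flows from one global seed through
`derive_seed(seed, tags...)`, a string hash that gives each (stage,
recording) pair its own stream — adding recordings does not perturb
existing ones, and rerunning a pipeline config reproduces every output
bit-for-bit. The shipped test suite runs the full pipeline at 250
recordings per seed for five seeds for the recovery check, 200 replicates
for each calibration bound (surrogate false positives, TFRP false
positives, CorrCoef independence), and 1000 random triples for the EI
symmetries; these sizes were chosen so each stochastic bound is measured
with a standard error well below the margin it is checked against.

# Known limitations

- The five categories are imposed on a continuum; near cluster borders
  the bootstrap reliability, not the point assignment, is the meaningful
  quantity.
- The cluster-naming rule assumes the five centroids qualitatively match
  the category definitions; on degenerate data (e.g. fewer than five real
  behaviors) it still returns five names, and only the elbow diagnostic
  reveals the mismatch.
- Plug-in mutual information is biased upward at small counts; no
  correction is applied, so MI values from small cohorts should be
  compared only against matched-size baselines.
- The cost-weighted LDA assumes shared within-class covariance; strongly
  heteroscedastic descriptor sets would favor quadratic boundaries that
  are out of scope here.
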