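# noisecat

Noise-robustness categorization of auditory spike-train recordings.

When a vocalization is embedded in masking noise, different auditory
neurons do very different things: some keep encoding the vocalization
almost untouched, some track the masker instead, some flip between the two
as the signal-to-noise ratio (SNR) changes, and many show no preference at
all. `noisecat` implements the complete analysis chain used to classify
multiunit recordings along this axis — from raw spike-event tables to named
response categories, their stability, their dependence on the type of
masker, and their predictability from responses to clean sounds — together
with a seeded synthetic spike-train generator that plants known categories
so the whole chain can be validated against ground truth.

It is written for auditory neurophysiologists working with protocols of the
form: a small set of vocalizations presented in quiet and embedded in two
masking noises (a spectrally matched stationary noise and a naturalistic
"chorus" noise) at several SNRs, plus the noises alone and a pure-tone
block for frequency tuning.

## The statistics at the core

**Extraction index (EI).** For a recording's peristimulus time histogram
(PSTH, 4-ms bins over the evoked window) at one SNR, with the clean
vocalization PSTH *P<sub>v</sub>* and the noise-alone PSTH
*P<sub>n</sub>* as references,

    D_x-snr = 1 − (P_x · P_snr) / (‖P_x‖ ‖P_snr‖),   x ∈ {v, n}
    EI      = (D_n-snr − D_v-snr) / (D_n-snr + D_v-snr)

EI is bounded in [−1, 1]: +1 means the noisy-condition response is
identical (up to scale) to the clean-vocalization response, −1 that it is
identical to the noise-alone response. Three SNRs × two noise types give a
six-value EI profile per recording. Significance of each EI value is
assessed against 100 rate-matched homogeneous-Poisson surrogates
(threshold: surrogate mean + 2 SD).

**Categorization.** Per noise type, the 3-value EI profiles of all selected
recordings are clustered with K-means (k = 5, Euclidean distance, MSE
criterion) and the clusters mapped deterministically to five named
categories: *signal-like*, *signal-dominated*, *balanced*, *insensitive*,
*masker-like*. A trial-resampling bootstrap (100 replicates) measures how
often each recording returns to its category; recordings with a modal count
≥ 95 are *reliable*.

**Noise-type switching.** A 5 × 5 matrix counts category changes between
the stationary and chorus noise; Shannon mutual information (plug-in, in
bits) summarizes how predictive one categorization is of the other
(log₂ 5 ≈ 2.3 bits for perfect preservation, 0 for independence).

**Prediction.** Twelve descriptors per noise type (tone-tuning properties;
firing rate and trial-to-trial reliability for the clean vocalizations and
the masker alone; masker short-term adaptation; signal-to-masker rate
ratios) feed a cost-weighted linear discriminant classifier (5-fold
cross-validation, cost 2 for misassigning any category into *insensitive*),
swept over all 15 combinations of the four descriptor groups.

## Worked example

Simulate a cohort of 250 recordings — a balanced 5 × 5 joint over
(category in stationary noise × category in chorus noise), i.e. 50
recordings per category per noise — and run the full pipeline:

```r
library(noisecat)

protocol <- stim_protocol()     # 4 vocalizations, 2 noises, SNR +10/0/−10,
                                # 20 trials, 129 tones, 4-ms EI bins
gen <- generator_config(protocol, counts = crossed_cohort_counts(10L),
                        seed = 1L)
cfg <- pipeline_config(generator = gen, combos = c("1", "8", "12"),
                       seed = 1L)
report <- run_pipeline(cfg)
print(report)
```

```
noisecat pipeline report
  recordings: 250; selected: 215
  stationary: k = 5, MSE = 0.0108
  chorus: k = 5, MSE = 0.0313
  MI (all recordings): 0.125 bits
  MI (reliable only): 0.276 bits
  planted-category recovery (stationary): 100.0%
  planted-category recovery (chorus): 94.0%
  LDA accuracy, all descriptors (stationary): 74.42%
  LDA accuracy, all descriptors (chorus): 56.74%
```

215 of 250 recordings pass the selection criteria (significant
vocalization response, significant tone tuning, six defined EI values, at
least one EI above its surrogate threshold); clustering plus the labelling
rule recovers 100% / 94% of the planted categories per noise. The low
mutual information (0.125 bits against a 2.32-bit ceiling) reflects that
this cohort was planted with 80% noise-type switchers. The recovered
stationary-noise centroids show the five expected profile shapes:

```r
cl <- report$clusterings$stationary
round(cl$centroids[order(cl$label_map), ], 2)
```

```
       p10    00   m10
[1,]  0.52 -0.11 -0.49    # balanced
[2,] -0.05 -0.07 -0.06    # insensitive
[3,] -0.46 -0.48 -0.48    # masker-like
[4,]  0.33  0.15 -0.07    # signal-dominated
[5,]  0.53  0.48  0.43    # signal-like
```

`write_report(report, "out/")` writes the tabular outputs
(`selection.csv`, `ei.csv`, `categories.csv`, `switching.csv`, `mi.json`,
`classifier_report.json`). Datasets themselves round-trip through plain
CSV/YAML files via `write_spike_events()` / `read_spike_events()`.

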