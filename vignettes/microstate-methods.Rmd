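---
title: "Microstate segmentation and multidomain EEG biomarkers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation and multidomain EEG biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Resting-state EEG alternates between a small number of quasi-stable scalp
topographies ("microstates", ~60–120 ms each). `microstatr` treats the
multichannel signal as a switching process: at every time point exactly one
of K = 4 canonical topographies is active, and the sequence of active
states is a symbolic time series whose statistics — dwell times, switching
structure, state-conditioned oscillatory content, sequence complexity —
are candidate group-level biomarkers.

The pipeline is:

1. **Preprocess** (`preprocess_recording`): zero-phase Hamming-window FIR
   band-pass 1–45 Hz, zero-phase 2 Hz-wide band-stop at 50 Hz, common
   average reference, polyphase resample to 128 Hz — in that order.
   Epochs of 2 s with 50% overlap; an epoch is rejected if any sample
   exceeds 100 µV or its worst per-channel variance z-score (across
   epochs) exceeds 3. Cross-subject channel heterogeneity is resolved by
   conforming everyone to the modal channel-name set (missing channels
   zero-filled, extras dropped).
2. **Segment** (`gfp_curve`, `extract_peak_maps`, `learn_templates`,
   `assign_labels`): global field power GFP(t) is the *population*
   standard deviation across channels at each sample. Topographies at GFP
   local maxima (≥ 2 samples apart; higher peak wins conflicts) are
   unit-normalized, pooled across subjects group-blind, and clustered
   with K-means (k-means++ seeding, 10 restarts, best objective kept).
   Centroids are renormalized and ordered by descending cluster size.
   Back-fitting normalizes each sample's channel vector and assigns the
   template with the largest dot product; ties go to the lowest index and
   zero-norm samples carry the previous label forward.
3. **Extract features** (`subject_features`): the canonical 80-column
   vector per subject — 35 temporal, 20 spectral, 15 complexity, 10
   higher-order (details below).
4. **Screen** (`feature_screen`): two-sided Mann–Whitney U per feature
   with mid-ranks, plus Cohen's d (pooled SD) and Cliff's delta, signed
   ASD − NT. Raw p-values by default; Benjamini–Hochberg is available but
   off.
5. **Classify** (`cross_validated_eval`, `cumulative_ablation`,
   `attribution_rank`, `topk_retrain`): stratified 10-fold CV over a
   roster of seven classifiers with randomized search nested in the
   training split, cumulative-domain ablation, exact tree-path Shapley
   ranking, and a grid-searched top-20 retrain.

# Polarity

The back-fitting rule as classically printed uses the *signed* dot
product. On oscillatory sources this is degenerate: the active
topography's amplitude is zero-mean, so half of all samples anticorrelate
with their own template and signed matching mislabels them. Both
`learn_templates` and `assign_labels` therefore expose `ignore_polarity`.
The op-level default stays signed (strict replication of the printed
rule); the cohort pipeline (`ms_pipeline`) defaults to the
polarity-invariant variant, which is the established convention in the
microstate literature: clustering assigns maps by maximum |cosine| and
updates each centroid as the first principal component of its members
(power iterations inside the loop, an exact eigendecomposition at
convergence), and back-fitting compares by |dot product|.

# Feature definitions and units

**Temporal (35).** Per state k ∈ 0..3: mean run duration (ms), coverage
(fraction of samples), occurrence (runs per second), and dwell entropy
(nats; Shannon entropy of the run-duration distribution normalized within
the state). The 4×4 first-order transition matrix (row-conditional pair
frequencies, self-pairs included; unvisited rows all-zero). Switching
rate (label changes per opportunity). Recurrence rate (fraction of
recurrent sample pairs, main diagonal included, as the double sum is
written) and determinism (fraction of off-main-diagonal recurrence points
on diagonal lines of length ≥ 2 — the main diagonal is excluded there,
otherwise determinism is pinned near 1). All computed per 2-s epoch
(T = 256, bounding the O(T²) recurrence scan) and averaged over accepted
epochs.

**Spectral (20).** For each state, samples carrying its label are pooled
*within* each epoch; an epoch-state contributes only if the pooled
duration reaches 1 s. Welch PSD (128-sample Hann segments, 50% overlap,
per-segment demeaning, density scaling) per channel on the pooled series;
band power is the mean PSD over half-open bins [lo, hi) for delta 1–4,
theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz, averaged over channels
then over contributing epochs. Individual microstate runs almost never
reach 1 s, and at ~100 ms dwells only ≈ 1% of epoch-states pass the
pooled rule, so per-subject estimates rest on a handful of epochs and a
substantial fraction of cells is NaN (~60% on the default synthetic
cohort). NaN is deliberate — never silently zero — and flows into the
screening (pairwise drops, reported) and the harness (explicit imputation
policy). Pooling concatenates discontiguous runs without tapering.

**Complexity (15).** The per-epoch label sequences are flattened into one
continuous sequence (overlap included, preserving the per-epoch feature
convention) and five metrics are evaluated at coarse-graining scales 1,
2, 4 (keep every s-th label): sample entropy (m = 2, r = 0.2·SD,
Chebyshev, self-matches excluded; −ln(A/B)); permutation entropy (m = 3,
delay 1, ties broken by earlier index, natural log); DFA exponent
(integrated demeaned series, linear detrend in non-overlapping windows
log-spaced 4..N/4, ≥ 8 sizes, log–log slope); LZ76 complexity
(exhaustive-history parse over the native alphabet, normalized by
n/log₂n); and the rescaled-range Hurst exponent (windows 8..N/2). The
5 × 3 layout honours the canonical count of 15; the multiscale convention
is this package's resolution of an otherwise underdetermined
decomposition. For integer label sequences with r < 1 the sample-entropy
tolerance can only be met by exact equality, so matches are counted by
m-gram hashing in O(N) — numerically identical to the O(N²) Chebyshev
scan, which remains the general path (and the test oracle).

**Higher-order (10).** Transition entropy (sum of per-row Shannon
entropies of the transition matrix, 0·log 0 := 0); mean inter-transition
interval (samples); 3-gram entropy after remapping observed labels to
contiguous integers; an approximate phase-locking value (modulus of the
mean unit phasor of the Hilbert-transform phase of the demeaned label
series; constant input gives 1 by convention); fractional-occupancy first
differences dfo_state_1..3; and transition-graph density |E|/(K(K−1))
on the directed graph of observed transitions, with average degree and
mean local clustering on its simple undirected projection. The mock
cross-frequency-coupling scalars (seeded uniform draws, one per state)
are excluded from the canonical vector and available behind
`include_cfc` — they carry no signal by construction.

# The synthetic cohort

`generator_config()` freezes the study conditions the pipeline is
designed for: 28 subjects per group, 54 channels (Biosemi-64 names
truncated), 128 Hz, 150 s. Each subject is a semi-Markov chain over K = 4
states — dwell times discretized gamma (shape 2, mean 13 samples ≈ 100 ms,
inside the physiological 60–120 ms range), jumps from the
self-transition-free renormalized row of a uniform transition matrix —
driving a rank-1 topography per state. The state amplitude is a sum of
band-limited oscillations (white noise band-passed per canonical band,
unit variance, gain-weighted per state-band) plus a 1/f component
(spectral shaping of white noise, power exponent 1) scaled to half the
state's mean gain, on top of 1 µV white sensor noise. State gain profiles
are heterogeneous (state 0 alpha-dominant, state 1 theta-leaning, state 3
delta-leaning) at ~2 µV per-channel signal RMS.

Two contrasts are planted in the ASD group: the state-3 delta gain is
doubled, and all dwell means are shortened by 20% (faster switching, the
direction reported for autistic adults). These defaults are what the
acceptance checks exercise: the screening must find both effects with
correct signs at n = 28 + 28.

What the generator does *not* emulate: volume conduction from dipolar
sources (no leadfield), ocular/myogenic artifacts beyond additive noise,
inter-subject variability (all subjects of a group share identical
generative parameters and planted maps), and non-stationarity over the
recording. The absence of inter-subject variability makes the synthetic
cohort far more separable than any real clinical sample — the bundled
classification analyses reach near-perfect accuracy on it, and the
cumulative ablation is flat because the temporal domain alone already
saturates. Passing tests therefore demonstrate the *pipeline's*
correctness and sensitivity under its own generative assumptions, not
clinical validity on real EEG; the ablation's expected rising shape is
exercised separately on a feature cohort constructed so that every
domain carries independent signal.

# Numerical choices

- Filters: Hamming-window FIR, length 3.3·fs/transition-width (1 Hz
  transition for the band-pass, 0.5 Hz for the notch), applied
  forward–backward via FFT convolution with reflection padding (zero
  phase, squared magnitude response). Steady-state attenuation at 50 Hz
  is < 1%; tests measure away from the edge transients.
- Resampling: `signal::resample` with a small rational approximation of
  the rate ratio.
- K-means: Lloyd iterations, k-means++ seeding, 10 restarts under one
  seed; cluster-size ordering breaks ties by first occurrence. The
  polarity-invariant variant optimizes Σ(1 − cos²).
- Mann–Whitney p-values: exact null CDF (`pwilcox`) when there are no
  ties and n₁n₂ ≤ 400; otherwise normal approximation with tie correction
  and continuity correction. Exact enumeration under ties is
  combinatorially infeasible at these sizes; the two paths agree to
  < 0.01 at n = 15 + 15 (tested).
- Degenerate inputs return NaN with a warning (undefined sample entropy,
  zero pooled SD, fewer than two transitions, constant series for
  Hurst/DFA) rather than sentinel values; errors are reserved for
  contract violations (empty inputs, shape mismatches, all epochs
  rejected).
- Determinism: every stochastic step (template restarts, fold assignment,
  candidate sampling, booster fits with `nthread = 1`) derives its seed
  from the user seed; identical configuration gives identical output.

# Classification harness

The roster: L1/L2 logistic regression (`glmnet`), random forest, RBF-SVM,
a shallow feed-forward network (`nnet`), depth-wise gradient-boosted
trees (`xgboost`), a second boosted ensemble growing trees leaf-wise on
histograms (`tree_method = "hist"`, `grow_policy = "lossguide"` — the
LightGBM-style growth strategy), and a stacked ensemble of the two
boosters with a logistic meta-learner trained on out-of-fold base
predictions. Imputation and standardization are fit on training folds
only. `unit = "subject"` (the default) keeps all of a subject's rows in
one fold — the leakage-safe design; `unit = "epoch"` reproduces a plain
stratified split for replication of epoch-level setups, and the two must
never be conflated when reporting. ASD is the positive class throughout.
Randomized search draws 50 candidates per model by default (tests and the
bundled analyses use smaller budgets; the budget is a reported parameter,
not part of the model). The top-20 retrain uses a fixed 18-point grid
instead, mirroring the two-stage tuning design.

Shapley attributions come from the booster's exact tree-path
decomposition (`predcontrib`); per-instance contributions plus the bias
term reproduce the model margin to numerical precision (tested), and
features are ranked by mean |attribution|.

# Problem sizes used by the bundled checks

The test suite exercises the full default cohort (56 subjects, 150 s)
once for the recovery and null-calibration checks; oracle-equivalence
tests run on sequences of ≤ 500 samples against naive O(N²)
reimplementations; the ablation/top-k shape checks use a directly
constructed 200-row feature table with three informative columns per
domain (within-domain multivariate effect sizes 0.9–1.2 SD), sized so
each cumulative stage adds signal with comfortable statistical power.
The analysis scripts under `analysis/` run the same stages at the full
study conditions and write their tables under `results/`.

# Known limitations

- The 1-s pooled-duration rule makes state-conditioned spectra sparse at
  physiological dwell times; estimates average very few epochs and NaN
  cells are common. Treat absolute band powers on short recordings with
  caution.
- Complexity metrics are computed on the flattened *overlapping* epoch
  sequence, duplicating half of each epoch; this follows the per-epoch
  feature convention but slightly inflates regularity.
- R/S Hurst and small-window DFA carry known small-sample biases (white
  noise reads ~0.55–0.6 on R/S); between-group comparisons are unaffected
  but absolute values should not be over-interpreted.
- The graph features saturate quickly: with K = 4 and minutes of data all
  12 directed edges are almost always present, so density ≈ 1 carries
  little between-subject variance at realistic switching rates.
- Statistical screening applies no multiple-testing correction by
  default (raw p-values are the reporting convention here); use
  `adjust = "BH"` when controlling the false discovery rate matters.
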