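# microstatr

EEG microstate segmentation and multidomain biomarker analysis for
two-group resting-state studies (case vs control), built around the
autism-vs-neurotypical classification setting: 54-channel eyes-closed
recordings are segmented into four quasi-stable topographic brain states,
every subject is summarized by an 80-feature vector spanning four
domains, features are screened with nonparametric statistics, and an
interpretable cross-validated classification harness quantifies
discriminability. A synthetic semi-Markov EEG generator with plantable
group effects makes the entire pipeline testable end to end without any
external data.

Intended users: EEG researchers studying large-scale brain-state dynamics
who want a tested, deterministic, scriptable implementation of the
microstate feature stack and its statistical/ML downstream.

## The method

**Segmentation.** Global field power — the spatial standard deviation
across channels at sample *t*,

GFP(t) = sqrt( (1/N) Σᵢ (Vᵢ(t) − V̄(t))² ),

peaks at moments of strong, stable topography. Channel vectors at GFP
peaks are unit-normalized, pooled across subjects, and clustered by
K-means (k-means++ seeding, 10 restarts) into K = 4 templates
μ₁..μ₄ minimizing Σₖ Σ_{x∈Cₖ} ‖x − μₖ‖². Back-fitting labels every
sample with argmaxₖ ⟨v(t)/‖v(t)‖, μₖ⟩ (a polarity-invariant variant,
standard for oscillatory data, is the pipeline default; the signed rule
is available).

**Features (80 per subject).**

| domain | n | contents |
|---|---|---|
| temporal | 35 | per-state mean duration D_k, coverage C_k, occurrence O_k, dwell entropy H_k; 4×4 transition matrix P_{i→j}; switching rate; recurrence rate and determinism of the label sequence |
| spectral | 20 | state-conditioned Welch band power (delta/theta/alpha/beta/gamma × 4 states), epochs pooled per state with a 1-s minimum duration |
| complexity | 15 | sample entropy, permutation entropy, DFA exponent, LZ76 complexity, Hurst exponent at coarse-graining scales 1/2/4 |
| higher-order | 10 | transition entropy, mean inter-transition interval, 3-gram entropy, phase-locking value, fractional-occupancy derivatives, transition-graph density/degree/clustering |

**Statistics.** Per feature: two-sided Mann–Whitney U
(U = min(U₁, U₂), mid-ranks, exact null when feasible), Cohen's
d = (X̄ − Ȳ)/s_pooled and Cliff's Δ = (#(x>y) − #(x<y))/(n₁n₂), signed
case-minus-control.

**Classification.** Stratified 10-fold cross-validation with randomized
hyperparameter search nested in the training split, over logistic
regression, random forest, RBF-SVM, a shallow neural network, two
gradient-boosted tree ensembles and their stacked combination;
subject-grouped folds by default (leakage-safe). Cumulative-domain
ablation, exact tree-path Shapley feature ranking, and a grid-searched
top-20 retrain with ROC.

## Worked example

Simulate a small cohort with the default planted contrasts (2× state-3
delta gain and 20% faster switching in the case group), run the full
pipeline, and screen one feature:

```r
library(microstatr)

cfg <- generator_config(n_per_group = 4, duration = 60, seed = 7)
cohort <- generate_cohort(cfg)
run <- ms_pipeline(cohort$recordings, K = 4, seed = 42)

dim(run$features)
#> [1]  8 82        # 8 subjects x (subject, group + 80 features)

run$features[1:4, c("subject", "group", "state_0_coverage",
                    "switching_rate", "ngram_entropy")]
#>   subject group state_0_coverage switching_rate ngram_entropy
#> 1   NT_01    NT        0.2284788      0.2523862      3.001348
#> 2   NT_02    NT        0.2473011      0.2621034      3.061201
#> 3   NT_03    NT        0.2366071      0.2641457      3.054045
#> 4   NT_04    NT        0.2506975      0.2528011      3.010201

scr <- suppressWarnings(
  feature_screen(run$features[, feature_names()], run$features$group,
                 positive = "ASD"))
scr[scr$feature == "mean_inter_transition_interval",
    c("feature", "p_value", "cohens_d", "cliffs_delta")]
#>                           feature    p_value  cohens_d cliffs_delta
#> 72 mean_inter_transition_interval 0.02857143 -2.890248           -1
```

The planted faster switching shows up as a shorter mean
inter-transition interval in the case group: negative Cohen's d and
Cliff's delta (case minus control), p < 0.05 already at 4 + 4 subjects.

The scripts under `analysis/` run the same stages at the full study
conditions (28 + 28 subjects, 150 s): `01_simulate_cohort.R` →
`02_segment_and_features.R` → `03_screen_features.R` → `04_classify.R` →
`05_ablation_and_shap.R`, writing their tables under `results/`.

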