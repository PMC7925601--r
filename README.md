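# speechtrf

Encoding-model analysis of EEG responses to continuous speech, centred on
the word-level semantic machinery of the N400: lexical surprisal from an
interpolated modified Kneser–Ney 5-gram language model, semantic
dissimilarity from word embeddings, and their temporal response functions
(TRFs) estimated by lagged ridge regression. The package targets
researchers who want to study ageing- or cognition-related changes in
semantic prediction during natural listening, and ships a complete seeded
forward model so every stage of the analysis is testable without any
external recordings.

## The model

A TRF is a linear filter mapping a stimulus feature time series `S(t)` to
the neural response:

    R(t) = TRF * S(t)            (* = convolution)

realized as a lagged design matrix `S` (lags −200…800 ms) and estimated in
closed form by ridge regression,

    TRF = (SᵀS + λI)⁻¹ Sᵀ r,

with λ selected by fourfold (leave-one-trial-out) cross-validation from a
grid spanning 0.1–1000, one λ per subject, maximizing the Pearson
correlation between predicted and held-out EEG averaged across trials and
channels. Three regressors enter simultaneously: impulse trains at
content-word onsets scaled by

- **semantic dissimilarity** — 1 − Pearson correlation between a word's
  embedding and the average embedding of its preceding (content-word)
  context, per sentence or over a fixed window of 3/5/7/9/11 words;
- **lexical surprisal** — −log P(word | 4 preceding words) under an
  interpolated modified Kneser–Ney 5-gram model, rescaled to match the
  dissimilarity distribution;
- an **onset nuisance regressor** of constant height (the pooled mean of
  the two feature values) absorbing acoustic onset responses.

Per-feature model evidence is the **permutation delta**: the drop in
cross-validated prediction accuracy when that feature's impulse heights are
shuffled across its onsets (5 permutations, positions fixed, other
regressors intact). The N400 trough latency is the lag of the minimum TRF
weight within 200–600 ms; preprocessing reproduces the standard chain
(anti-aliased downsampling to 128 Hz, 0.5–8 Hz zero-phase 4th-order
Butterworth, 2.5× leave-one-out bad-channel rule with spherical-spline
interpolation, mastoid referencing, and MCCA group denoising with 40 PCs /
110 canonical components). The statistical battery gates every comparison
through an Anderson–Darling normality test plus the 1.5 IQR outlier rule,
routing to t-tests or Wilcoxon/Mann–Whitney/Kruskal–Wallis accordingly, and
includes running paired t-tests with Benjamini–Hochberg FDR and
age-controlled partial correlations.

## Worked example

Simulate a two-group cohort (8 + 8 subjects, 32 channels, 4 × 60 s trials
at 128 Hz, SNR 0.25) in which the older group's response kernels are
delayed by 74 ms and its dissimilarity response is attenuated to gain 0.3
while surprisal is intact, then run the full analysis:

```r
library(speechtrf)
cfg <- experiment_config(seed = 42)
cfg$cohort$group_params$older$dissimilarity_gain <- 0.3
rep <- run_experiment(cfg)
print(rep)
#> <experiment_report> 16 subjects, config 1e7d4a9a
#>   latency delay 40.0 ms (p = 0.0108)
#>   older_within: p = 0.00412 (paired t)
#>   younger_within: p = 0.945 (wilcoxon signed-rank)
#>   between_dissimilarity: p = 5.54e-07 (2-sample t)
#>   between_surprisal: p = 0.959 (mann-whitney U)
#>   fluency partial r = 0.19 (p = 0.686)
```

Reading the output: the older group's surprisal TRF trough is recovered as
delayed (40 ms on this seed — the injected 74 ms shift seen through 20 ms
per-subject latency jitter and trough-estimation noise at n = 8 per group;
the recovered delay is unbiased across seeds). The four accuracy contrasts
reproduce the expected pattern — within the older group surprisal predicts
EEG better than dissimilarity (p = 0.004), within the younger group the two
are indistinguishable, between groups the dissimilarity advantage of the
younger group is strong while surprisal shows no group difference. The
fluency correlation is weak here because the attenuated older-group gain
compresses the between-subject delta variance; with gain 1 (the
fluency-link experiments, `replicate_fluency_correlation()`), the
age-controlled partial correlation recovers the simulated link.

Per-subject detail and ground-truth recovery live in `rep$metrics` and
`rep$recovery`:

```r
head(rep$metrics[, c("group", "lambda", "mean_r", "delta_surprisal")], 2)
#>     group lambda mean_r delta_surprisal
#> 1 younger   31.6  0.328          0.0239
#> 2 younger   31.6  0.331          0.0394
range(rep$recovery$kernel_cor_surprisal)   # estimated vs generating kernel
#> [1] 0.759 0.993
```

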