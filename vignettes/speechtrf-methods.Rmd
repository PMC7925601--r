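---
title: "Methods: forward-modelled TRF analysis of semantic processing in continuous-speech EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward-modelled TRF analysis of semantic processing in continuous-speech EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the synthetic world it tests them in, the numerical choices
made where the design was genuinely open, and what a green test does and
does not establish. It states no empirical result that the test suite does
not itself compute.

## 1. The encoding model

The temporal response function (TRF) treats the EEG response as a linear
convolution of word-level stimulus features with unknown kernels,
`R(t) = TRF * S(t)`. We realize the convolution as a lagged design matrix —
column *(f, ℓ)* holds feature *f* delayed by ℓ samples, feature-major, lags
ascending, zero-padded at the trial edges — and estimate the kernels in
closed form by ridge regression, `TRF = (SᵀS + λI)⁻¹Sᵀr`, solved per
channel from shared normal equations via Cholesky factorization. An
unpenalized intercept column absorbs the response mean; the penalty is the
plain identity (no temporal-smoothness term), matching the displayed
estimator exactly.

Three regressors enter simultaneously, all impulse trains at content-word
onsets (sample index `round(onset × fs)`; colliding onsets are summed with
a warning):

* **Semantic dissimilarity** — 1 − Pearson correlation between the word's
  embedding and the average embedding of its preceding context. Context
  words are preceding *content* words; in sentence mode all of them within
  the sentence, in window mode the *k* most recent regardless of sentence
  boundary (k ∈ {3, 5, 7, 9, 11}). Values live in [0, 2]; a word equal to
  its context average scores exactly 0.
* **Lexical surprisal** — −log P(word | up to 4 preceding words) under a
  5-gram language model (natural log; the base is irrelevant after
  distribution matching but is fixed for reproducibility). Histories use
  all words, content and function, and never cross a sentence start.
  Surprisal is rescaled to the dissimilarity distribution's mean and sd
  (the study convention puts both near mean 0.48).
* **Onset nuisance** — constant height (mean of the trial's pooled
  dissimilarity and surprisal values) at every scored onset, capturing
  acoustic onset responses so they are not misattributed to the semantic
  features.

The *common-impulse rule*: a word unscored in either feature (missing
embedding, or empty context at a sentence start) is dropped from both
vectors, so the two semantic regressors mark identical onsets.

### Cross-validation and the permutation null

λ is selected by leave-one-trial-out cross-validation (fourfold for the
canonical four-trial session) over a log grid spanning 0.1–1000,
maximizing Pearson accuracy averaged across trials and channels — one λ
per subject; ties break to the smaller λ. Per-feature evidence is the
**permutation delta**: in each test fold, the target feature's impulse
heights are shuffled across its own onsets (positions fixed, other
regressors intact, 5 permutations by default, seeds derived
deterministically from (subject, feature, fold, index)), and the delta is
the true minus the mean null accuracy per channel. Because Pearson
correlation is shift-invariant, the intercept is omitted inside the CV
loops. N400 trough latency is the lag of the minimum weight in 200–600 ms
over a chosen channel set; ties return the earliest lag, and a minimum on
the window edge is flagged (`boundary` attribute, warning) rather than
silently trusted.

## 2. Preprocessing

The chain is downsample → band-pass → bad channels → mastoid reference →
MCCA, in that order. Downsampling is rational-rate resampling with a
Kaiser-windowed sinc anti-alias filter (cutoff 0.45× the output rate; the
source never specifies a method, and polyphase-style FIR resampling is the
field default). The band-pass is an order-4 Butterworth (0.5–8 Hz) applied
forward and backward — zero phase, squared magnitude; coefficients follow
the analog-prototype → band transform → bilinear route and are
edge-padded with odd reflection. The bad-channel rule is the 2.5×
leave-one-out standard-deviation criterion, applied per trial after
filtering (the source does not state before/after; after is the choice
here because the rule should see the analysis band). Flagged channels are
rebuilt by spherical-spline interpolation (order-4 Legendre kernel
truncated at 7 terms, diagonal regularization 1e−5; with regularization 0
the interpolant passes exactly through the nodes). Referencing subtracts
the mean of the two mastoids.

MCCA uses the summed-covariance formulation: each subject is reduced to
`n_pc` whitened principal components (no internal centering, so the
transform is strictly linear and zero maps to zero), the whitened blocks
are concatenated, and the eigenvectors of the concatenated covariance
define canonical components ordered by cross-subject shared variance.
Denoising projects a subject into canonical space, truncates to the
leading `n_cc` components (eigenvalue order — the source gives only the
counts 40/110), and back-projects; with full retention this reduces to the
subject's rank-`n_pc` reconstruction, and the operation is idempotent.

## 3. The synthetic world

No public recordings accompany this package, so every downstream stage is
exercised on a forward model whose structure mirrors what the analysis
assumes.

* **Lexicon/embeddings.** Words belong to semantic categories; each
  content word's unit vector is `s·centroid + √(1−s²)·noise` with
  `s = √(within-category similarity)` (default 0.6), so within-category
  cosine exceeds between-category cosine by construction. Default 300
  dimensions, matching common pretrained tables; tests use fewer. A 15%
  function-word stratum carries embeddings but no category.
* **Corpus.** Sentences from a first-order Markov chain whose transition
  scores are embedding cosines through a softmax (temperature 0.15), with
  words not repeating within a sentence; this makes some 5-grams recur
  (low surprisal) and others never occur (high surprisal), while keeping
  the realized dissimilarity–surprisal correlation weak (|r| ≈ 0.1–0.2 on
  generated trials, the regime reported for real narrative stimuli).
* **Transcript.** 190 words/minute; content-word durations truncated
  normal 334 ± 140 ms floored at 50 ms; inter-onset gaps jittered around
  60/rate and renormalized so the realized rate hits the target; onsets
  strictly increasing.
* **EEG.** Response = Σ features (impulse train ⊛ kernel) × topography,
  plus spectrally pink noise, white sensor noise, and a rank-1 artifact
  with one temporal course shared by all subjects (per-subject random
  topography) — the minimal structure that gives MCCA something to find.
  Kernels are Gaussian troughs: an *acoustic onset* kernel (110 ms,
  equal across groups, never shifted — the component the onset nuisance
  regressor exists to absorb; omitting it makes total signal variance
  strongly group-dependent and distorts between-group accuracy
  comparisons, which is how it earned its place in the default world) and
  two N400-like kernels (surprisal 380 ms, dissimilarity 400 ms, both
  negative, centro-parietal topography on a synthetic unit-sphere cap).
* **Cohort.** Two groups; the older group's semantic kernels are shifted
  by +74 ms and its dissimilarity kernel scaled by a group gain.
  Per-subject gain jitter (sd 0.3) and latency jitter (sd 20 ms);
  ages uniform in 19–38 / 55–77. Semantic fluency =
  20 + 10 × dissimilarity gain + N(0, 3.5²), which puts the population
  gain–fluency correlation near 0.65, the regime of the reported
  behavioural link; letter fluency is an unrelated covariate. Noise is
  calibrated against the gain-1 reference response; the default total SNR
  is 0.25 (the level the kernel-recovery checks are specified at).

What a green test does **not** establish: the world has no eye blinks or
EMG, no head geometry, no between-trial nonstationarity, and its SNR is
well above real single-subject speech-EEG; passing contrasts here means
the estimators are correct and adequately powered in a faithful linear
world, not that effect sizes transfer to real cohorts.

## 4. Numerical and design choices

* **Lag window −200…800 ms** — never stated by the source; brackets the
  200–600 ms trough search with margin on both sides.
* **λ grid** — 10^(−1…3) in half-decade steps by default (endpoints as
  stated); the reduced test profile uses whole-decade steps.
* **Tie-breaks** — smaller λ among accuracy ties; earlier lag among
  latency ties. Arbitrary but fixed.
* **Degenerate inputs** — constant predictions score r = 0 with a
  warning; identical paired samples yield the signed-rank p = 1; a
  variable collinear with the partial-correlation covariate returns r = 0;
  Kruskal–Wallis on identical values returns p = 1; λ = 0 on a
  rank-deficient design errors with advice rather than pseudo-inverting.
* **Statistical gate** — Anderson–Darling at α = 0.05 (unstated in the
  source; 0.05 is the conventional level) plus the 1.5 IQR rule; outliers
  trigger nonparametric routing only, never removal. Rank tests use exact
  small-sample nulls (n ≤ 25, no ties) and the continuity-corrected
  normal approximation otherwise; all tests two-sided; Cohen's d uses the
  pooled sd.
* **Permutations** are drawn independently per fold (whether the original
  analysis reused one shuffling across folds is unstated).
* **Scale profiles** — the default configuration runs 8 subjects/group,
  32 channels, 4 × 60 s at 128 Hz (minutes on one CPU); a `paper-scale`
  profile gives 19/group, 128 channels, 4 × 180 s. The acceptance suite
  additionally drops repeated-seed simulations to 16 channels and (where
  trough-latency resolution is not at stake) 64 Hz, with seed counts noted
  inline — a runtime decision fixed before outcomes were measured.
* **Containers** — EEG travels as plain-text TSV matrices with a JSON
  sidecar, embeddings in the word-per-line text format, configs and
  reports as JSON; the environment provides no HDF5 bindings, and text
  keeps the fixtures reviewable.

## 5. Known limitations

Surprisal's n-gram trainer is pure R and sized for synthetic corpora, not
web-scale text. MCCA assumes time-aligned, equal-length recordings.
Decoding (backward) models, banded regularization, and boosting-style TRF
estimation are out of scope, as is analysis of real public datasets —
supported as input formats, never exercised in CI.
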