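---
title: "Estimating brain free-energy differences and information-processing resources from EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating brain free-energy differences and information-processing resources from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurofep)
```

## The model

During a balanced two-category visual decision, an observer's surprise
about the true category $\nu$ is bounded by the variational free energy

$$F \;=\; \sum_\nu Q(\nu\mid\mu,m)\,\ln Q(\nu\mid\mu,m)
\;-\; \sum_\nu Q(\nu\mid\mu,m)\,\ln P(o,\nu\mid M),$$

in nats. $Q(\nu\mid\mu,m)$ is the recognition distribution the brain's
perception-state representation $\mu$ entails; $P(o,\nu\mid M)$ is the
joint distribution of optimal category perceptions $o$ and categories
$\nu$ under an ideal noise-free categorizer, which maps perceptions
one-to-one onto categories: a diagonal matrix with entries
$P(o) = P(\nu) = 0.5$. Evaluating $F$ for the four $(o,\mu)$
combinations gives the per-state differences $\Delta F(o,\mu)$, their sum
$\Delta F_{Total}$, and the matched ($o=\mu$) versus mismatched
($o\neq\mu$) collapses.

Two assumptions matter. First, the generative model is *ideal*: all
deviation of $Q$ from a point mass is charged to the brain, which is what
makes the quantity interpretable as an information-processing cost.
Second, the perception state $\mu$ is identified from EEG via classifiers
trained on the participant's *behavioral* reports, so $\mu$ encodes at
most as much category information as behavior expresses.

### Zero handling (`epsilon`)

The ideal generative model has exact zeros off the diagonal, which make
$\Delta F$ infinite whenever $Q$ places any mass on the mismatching
category. Since per-state differences in the 2–4 nat range are the
meaningful regime, the package substitutes a configurable
$\varepsilon > 0$ (default $10^{-3}$) for the zeros and reports it in
every output. With a recognition row near typical classifier accuracy
($q \approx [0.67, 0.33]$), $\varepsilon = 10^{-3}$ puts matched states
at $\approx 2.1$ nats, mismatched at $\approx 4.2$, and the four-state
total at $\approx 12.7$. The difference is bounded below by
$-\ln(0.5+\varepsilon)$ (Jensen), so it is always positive at this
$\varepsilon$.

### The resource parameter

The bounded-rationality softmax model prices the movement from a prior to
a decision distribution at $1/\zeta$ per nat:

$$-\Delta F(q) = \sum_\nu q(\nu)U(\nu) - \frac{1}{\zeta}
\sum_\nu q(\nu)\ln\frac{q(\nu)}{p_0(\nu)},$$

so larger $|\zeta|$ (more allocated resources) means smaller free-energy
difference magnitudes (`boltzmann_curve()` traces this reciprocal
relationship). For the two-decision task with equal priors the model
reduces to $P(d_1) = \mathrm{logistic}(\zeta\,(U_1 - U_2))$ with
$U_i = \ln P(d_i\mid m)$.

**Regression design.** The per-trial utility regressor
$x_t = U_1\,[d_t{=}1] - U_2\,[d_t{=}2]$ has a sign that is a
deterministic function of the decision itself, so a logistic regression
of the *decision* on $x_t$ is perfectly separable and has no finite
maximum-likelihood estimate. The package therefore regresses the
true-category indicator $y_t = [\nu_t{=}1]$ on $x_t$ without an
intercept (none appears in the equal-prior softmax). Under balanced
decisions this admits the closed form
$\hat\zeta = -\mathrm{logit}(p_{correct})/\ln 2$, which serves as the
analytic oracle in the tests: group accuracies of 70% and 63% map to
$\hat\zeta = -1.22$ and $-0.77$, matching the reported group values to
within a few hundredths. Above-chance accuracy always yields negative
$\hat\zeta$, and higher accuracy yields more-negative $\hat\zeta$, which
reproduces the reported ordering between the two task variants.

## The recognition pipeline

Per participant: preprocessing → PCA whitening → CSP → per-trial
features → one hyperparameter tuning pass → repeated K-means/SVM
classification → averaged $Q$.

* **Preprocessing order** is fixed: artifact scoring (peak-to-peak,
  default 150 µV — the criterion is a config key), bad-channel
  interpolation, average reference, band-pass, baseline. Flagged trials
  and non-responses are excluded before any fitting.
* **Band-pass filter.** The published chain uses a 0.1–30 Hz band-pass on
  epoched data. A time-domain FIR with a sub-0.1 Hz transition needs tens
  of thousands of taps at 256 Hz — far longer than a 1.2 s epoch — so the
  package realizes the filter in the frequency domain: a real
  raised-cosine amplitude response (zero phase by construction) applied
  to reflection-padded epochs, with the DC bin always zeroed and a 4 Hz
  transition above the 30 Hz edge. On these epochs the 0.1 Hz edge
  necessarily acts as DC/drift removal; attenuation at 0, 50 and 60 Hz
  exceeds the stated requirements (`bandpass_response()` exposes the
  response for inspection).
* **Channel interpolation** uses inverse-distance weights over the 4
  nearest neighbors on an idealized spherical 10/5 layout
  (`standard_montage()`), a deliberate simplification of spherical
  splines; on smooth fields it reconstructs to within ~10%.
* **Whitening as the conditioning step.** The published pipeline applies
  an ICA decomposition before CSP to stabilize covariance estimation; the
  algorithm and retention rule are not specified in the main text. The
  package uses PCA whitening of the pooled post-stimulus covariance
  (retaining 99% of variance) by default, which achieves the stated
  purpose — removing interdependencies and the rank deficiency introduced
  by average referencing — deterministically.
* **CSP.** Class covariances are trial-averaged, trace-normalized
  covariances of the 0–1000 ms window, classes defined by the
  participant's *decisions*. Filters solve
  $\Sigma_1 w = \lambda(\Sigma_1+\Sigma_2)w$ and are ordered by
  discriminability $\max(\lambda, 1-\lambda)$. All $N_{rank}$ filters
  feed the features $f_i = \log(\mathrm{var}(Z_i)/\sum_j
  \mathrm{var}(Z_j))$, so $\sum_i e^{f_i} = 1$ and features are
  amplitude-invariant.
* **Classification repeats.** Per repeat: fresh random K-means
  initialization (k = 2) on the features, cluster labels anchored to the
  behavioral decisions by the better of the two bijections (ties keep the
  identity mapping); a fresh stratified 10-fold partition; an RBF-SVM per
  fold trained on true-category labels. Hyperparameters (MATLAB-style
  kernel scale $\sigma$, mapped to libsvm $\gamma = 1/\sigma^2$, and box
  constraint = cost) are tuned once per participant by seeded log-uniform
  random search over $[10^{-3}, 10^5]$ minimizing stratified 10-fold CV
  misclassification — tuning before the repeats mirrors reporting a
  single hyperparameter pair per participant and is a mild optimism
  source, accepted deliberately. $Q(\nu\mid\mu)$ is the mean held-out
  posterior within each perception group, averaged over repeats (study
  default 200); per-trial indices are majority votes.
* **Posterior calibration.** Held-out posteriors come from a Platt-style
  sigmoid on decision values. Fitting that sigmoid on the training folds'
  own decision values is overconfident — the SVM separates its training
  data far better than unseen trials — and measurably biases $Q$ toward
  certainty (rows near 0.92 when the true conditional is 0.70). The
  calibration decision values are therefore produced by an internal
  3-fold cross-validation *within* the training folds (the standard Platt
  procedure). Degenerate decision values fall back to the base-rate
  posterior.

## The synthetic cohort generator

The generator emulates the study's structure so every downstream stage is
testable: balanced Gabor stimulus spaces (diagonal-boundary II and
conjunction-rule RB variants on a normalized feature square, boundary
margin 0.02), latent perceptions matching the true category with
probability $p$, decisions flipping with a lapse rate, lognormal RTs with
lower medians on correct trials, spatially correlated 1/f background EEG
(smooth random mixing over the montage, per-channel RMS 10 µV), and a
perception-specific component: one of two orthogonal unit-norm smooth
topographies times a Hann waveform on 300–700 ms. Workload scores are
`clip(intercept + slope·ζ + noise, 0, 1)`.

Defaults are the study's task/recording parameters where stated (256 Hz,
−200..1000 ms, up to 72 channels of the 10/5 system) and scientifically
conventional choices elsewhere: 240 trials per task, perceptual
accuracies 0.72 (II) / 0.65 (RB) near the reported group means so the
II > RB ordering is reproduced, lapse 2%, non-responses 1%, artifact
contamination 5% at 10× amplitude.

**The `snr` dial.** `snr` is a perception-signal to background-noise
amplitude ratio: at the waveform peak, the Euclidean norm of the signal
topography across the array equals $2\,\mathrm{snr}$ × the per-channel
background RMS. The factor 2 calibrates the scale so that `snr = 0` is
pure noise (recognition at chance), `snr = 2` is reliably decodable
single-trial signal (CSP features separate perception classes at ≥ 90%),
and `snr ≥ 5` recovers the injected perception index almost perfectly —
while single-channel deflections stay at physiological ERP scale
(~10–50 µV), safely below the artifact criterion. An earlier array-RMS
convention produced ~140 µV channel peaks at high snr, which tripped
artifact rejection and selectively discarded signal-bearing trials; the
current convention was fixed after that observation and is used for all
conditions.

**What passing tests do and do not show.** The generator's EEG is
stationary 1/f noise plus a single fixed evoked component per perception
state; real EEG has nonstationarities, ocular/muscle artifacts with
structure, volume-conduction detail and latency jitter none of which are
modeled. Synthetic results therefore validate the *estimator logic*
(recovery of known recognition structure, orderings, correlation signs),
not field-data effect sizes.

## Statistics

* Permutation repeated-measures ANOVA: observed $F$ and $\eta_p^2$ from
  the standard within-subject decomposition; $p$ from within-participant
  condition-label permutation with add-one smoothing (the two-condition
  case reduces exactly to sign-flipping paired differences and is
  computed vectorized). The two-way scheme permutes raw values within
  participant; residual-permutation variants were considered and not
  used, for simplicity and exactness in the two-condition case.
* Pointwise paired t-tests over time with max-statistic familywise
  correction via sign flips; masks are reported as temporal ranges (the
  selected-trial effect sizes would be circularly biased, so none are
  attached).
* Pearson correlations tested by randomization (shuffling one variable),
  two-tailed with add-one smoothing.
* BH-FDR step-up over each correlation family (delegated to
  `stats::p.adjust`; the step-up identity is property-tested against a
  brute-force enumeration).

## Numerical and design notes

* $0\ln 0 := 0$ only in the entropy term; the cross term uses the
  $\varepsilon$-regularized model and stays finite.
* Every random draw derives from a master seed through a documented
  hierarchy (participant → stage → repeat), so participant-level reruns
  are bit-identical; derived seeds stay inside the 32-bit integer range.
* K-means ties in cluster anchoring map cluster 1 → perception 1,
  deterministically.
* Repeats whose perception grouping degenerates (an empty group) are
  discarded; more than 10% discarded aborts the participant with an
  error rather than returning a biased average.
* The orchestration surface is the function pair `run_participant()` /
  `run_cohort()` plus `scripts/acceptance.R`; the package targets R
  analysts, so no shell subcommand tool is shipped.

## Problem sizes used in the test suite

Unit tests run on small fixtures (tens of trials, up to 16 channels).
The end-to-end claims use: snr sweeps at 240 trials × 32 channels with 50
classification repeats; the matched/mismatched ordering at 6 participants
× 10 repeats; the cohort-level $\Delta F_{Total}$–$\zeta$ coupling at 40
participants × 240 trials × 20 repeats (accuracies drawn uniformly on
[0.55, 0.9]); statistic calibration at 2000 null datasets × 500
permutations (ANOVA type-I error) and 200 replications × 300 permutations
(max-statistic familywise error). These sizes were chosen as the smallest
at which the quantities under test are stable; the full study-scale
defaults (48 participants, 200 repeats) remain the package defaults.

## Known limitations

* The recognition estimate inherits any bias of the classifier stack;
  with very small trial counts or extreme hyperparameters the SVM can sit
  at chance and $Q$ collapses toward uniform (the free-energy estimates
  then approach the uniform-Q value rather than the participant's true
  state).
* $\varepsilon$ is a modeling choice, not an estimated quantity; per-state
  values scale with $-\ln\varepsilon$, so only comparisons at fixed
  $\varepsilon$ are meaningful.
* The closed-form $\zeta$ oracle assumes balanced decisions; strongly
  unbalanced decision distributions are fitted by the regression but lose
  the closed-form correspondence.
* Montage coordinates are idealized; interpolation and synthetic
  topographies should not be read as anatomically precise.
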