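---
title: "Moving-window multivariate decoding of epoched EEG: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-window multivariate decoding of epoched EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

## The analysis problem

Experiments on automatic product evaluation present participants with a
series of images while 64-channel EEG is recorded, and collect for each
image a binary approach judgement (Yes/No on product appeal, curiosity,
or wanting) during recording plus a continuous 0--100 rating afterwards.
The scientific question is *when*, within the first second of exposure,
the multivariate pattern of brain activity starts to carry information
about those judgements.

`erpdecode` implements the standard decoding answer to that question:

1. **Moving-window decoding.** Epochs spanning −100 to 1000 ms around
   image onset (512 Hz) are tiled with consecutive 10-ms analysis
   windows (5 samples each at 512 Hz; a trailing partial window is
   dropped, and the pre-stimulus baseline period is analysed too, as a
   built-in sanity region). Within each window, single-trial data form
   a feature matrix — by default all channels × in-window samples, 320
   features for 64 channels — and a linear support-vector machine
   (LIBSVM through **e1071**, cost fixed at 1) is trained to predict the
   Yes/No response, or a linear support-vector regression to predict the
   0--100 rating.
2. **Cross-validation.** 10-fold cross-validation, stratified by class
   for the SVM, repeated 10 times with fold assignment re-randomized.
   The SVM statistic is the percentage of correct held-out predictions;
   the SVR statistic is the Fisher-Z-transformed Pearson correlation
   between held-out predictions and true ratings.
3. **Empirical null.** Every analysis is repeated with labels (or
   ratings) randomly shuffled across trials, once per cross-validation
   repetition, using the identical machinery. Chance is therefore an
   *empirical* series — near 50% accuracy and Z = 0 — rather than an
   assumed constant.
4. **Group inference.** Per window, a one-tailed paired-samples *t*
   test compares true against shuffled-label performance across
   participants. Multiple comparisons across windows are corrected with
   a cluster-based permutation test: clusters are maximal runs of
   contiguous windows with uncorrected *p* < 0.05 and positive *t*,
   scored by cluster mass (the sum of *t* values); the null
   distribution of the maximum cluster mass is built by sign-flipping
   each participant's difference series (true − null), which is
   exchangeable under the global null. Cluster *p* values use the
   permutation-inclusive estimator (1 + #{null ≥ observed}) /
   (1 + *n*~perm~); an exhaustive mode enumerates all 2^*n* flips for
   small groups.
5. **Feature-weight topography.** For a significant cluster, the linear
   SVM is refit per participant and window on all balanced trials;
   absolute weights are averaged over in-window samples per channel,
   z-standardized across channels within participant, averaged over the
   cluster's windows, and tested per channel against zero (one-tailed,
   uncorrected *p* < 0.05), highlighting which channels carry the
   discriminative signal. These maps rank channel contributions; they
   are not source localisation.

## The synthetic study generator

Real epoched data of this kind are not freely redistributable, so the
package ships a generator (`sim_config()`, `generate_study()`) that
emulates the study structure well enough to exercise and calibrate every
stage:

* **Design constants.** 38 participants split 12/16/10 into never /
  currently / past-vaping groups, 120 images probed once per question
  dimension (360 trials), 64 channels at 512 Hz, epochs −100..1000 ms.
* **Noise model.** Ongoing activity is spatially correlated
  1/f^1 (pink) noise — neighbouring channels correlate with an AR(1)
  profile (0.6) — carrying 80% of the noise variance, plus independent
  white sensor noise, scaled to a 10 µV per-channel standard deviation.
  This reproduces the low-frequency-dominated spectrum and spatial
  smoothness that make EEG decoding hard, without any biophysical
  source model.
* **Latent appeal.** A standardized participant × image latent variable
  (group mean + participant effect + image effect) drives *everything*:
  Yes/No responses through a logistic model, ratings through an affine
  map to the 0--100 scale (noise added, then clipped and rounded), and
  the injected EEG amplitude. One latent variable is the simplest
  structure that reproduces the empirical coupling between choices,
  ratings and decodable signal.
* **Signal injection.** The decodable component is
  amplitude × spatial pattern × temporal envelope, added in a sustained
  late window (440--860 ms, full amplitude) and a weak early window
  (100--300 ms, 40% amplitude), mirroring the two effect epochs such
  studies report. The default spatial pattern is a unit-norm
  posterior-weighted bump with a smaller frontal bump; the default
  envelope is a half-cosine, which avoids step discontinuities at the
  window borders that would make onset localization artificially crisp.
* **Behavioral calibration.** Default group means of latent appeal
  (−1.0 / 0.6 / −0.55 for never / current / past) with rating map
  35 + 28 × latent reproduce the qualitative group structure of such
  samples: currently-vaping participants give the most Yes responses
  and the highest ratings (circa 50 on average), never-vaped the fewest
  and lowest (circa 10), with past users in between, and per-image Yes
  counts positively correlated with mean ratings.

The default injected amplitude (1.5 µV per standardized latent unit) is
a free parameter — effect magnitudes are not recoverable from published
figures — so tests that must *recover* signal use stronger, explicitly
stated amplitudes, and tests of calibration use amplitude 0. What
passing tests show is that the pipeline detects what was injected and
stays silent when nothing was; they cannot show that real vape-product
EEG carries a signal of any particular size. The generator also omits,
deliberately: eye/muscle artifacts, non-stationary drift, trial-order
effects, and volume-conducted source structure.

## Preprocessing retained in scope

Upstream cleaning (filtering, re-referencing, ICA, interpolation) is
assumed done. The package applies the two epoch-level steps that belong
to the analysis proper, in this order:

1. `baseline_correct()` — subtract each trial × channel's mean over the
   100-ms pre-stimulus interval;
2. `reject_amplitude()` — flag trials exceeding ±150 µV on any channel.

The order matters when a trial has a large DC offset but benign
dynamics: rejecting on baseline-corrected amplitudes (as here) keeps
such trials. The threshold convention is strict (`> 150`), so a sample
at exactly ±150 µV survives.

Sample-time conventions: sample times sit on the grid k/512 s; every
millisecond interval is closed on the left and open on the right, so
the onset sample t = 0 belongs to the post-stimulus side and the
−100..1000 ms epoch holds 563 samples and 112 complete 10-ms windows.

## Eligibility, balancing and estimator choices

* **Classification eligibility**: at least 20 trials per class in a
  dimension, else the participant is skipped for that analysis (the
  boundary is inclusive: 20/20 is eligible).
* **Regression eligibility**: rating SD of at least 1 unit and at least
  5 distinct values ("sufficiently variable" made concrete; both
  thresholds are configurable).
* **Class balancing**: the majority class is randomly subsampled to the
  minority count before cross-validation. Without this, the empirical
  chance level of an unbalanced participant is not 50% and the
  true-vs-null comparison conflates imbalance with information.
* **Feature scaling**: features are z-scored with training-fold
  statistics only; constant features are zeroed rather than propagating
  division-by-zero.
* **Regularization**: the cost constant stays at 1 with no inner tuning
  loop — the analysis establishes *presence* of information by
  comparison to the shuffled-label null, not maximal accuracy, and a
  tuning loop would only add optimistic bias and runtime.
* **SVR correlation estimator**: the held-out correlation is computed
  per fold and Fisher-Z values are averaged (`pooling = "fold"`).
  Pooling predictions across folds before correlating is offered as an
  option but is *negatively biased under the null*: each fold's fitted
  intercept tracks its training-set rating mean, which in a finite
  sample anti-correlates with the held-out fold's mean. On the null
  calibration below the pooled variant sits visibly below zero
  (≈ −0.015 at the 3-fold desk grid) while the per-fold estimator is
  centred, which is what an analysis asserting "chance is Z = 0"
  requires.
* **Ties**: SVM decision values of exactly zero go to the first class
  in label order, making predictions deterministic.
* **Degenerate cases**: zero-variance paired differences give a
  flagged degenerate t (p = 0 or 1 by the sign of the common
  difference); zero-variance predictions or ratings contribute Z = 0
  with a warning; undefined image-level correlations are returned as
  flagged `NA`.

Every stochastic stage derives its seed deterministically from the
master seed and a stage/window key (`derive_seed()`), so windows can be
recomputed in isolation or in parallel with results identical to a
serial run, and a run manifest plus config suffices to reproduce any
output byte for byte.

## Calibration at desk scale

Full-scale runs (38 participants × 112 windows × 10 × 10 CV) are
hours-long; the package's calibration utilities therefore use a reduced
grid whose sizes are chosen to keep the whole battery in the
tens-of-minutes range while leaving the statistics interpretable:
20 participants, a 30-window epoch (−100..200 ms), 16 channels, 3-fold ×
1-repetition CV, and — for the 100-study familywise-error battery —
per-channel window-mean features (the lighter feature mode; familywise
error control is a property of the inference machinery, not of feature
dimensionality). The three headline checks:

* `null_calibration("svm")` — grand-mean shuffled-label accuracy on a
  signal-free study; should be 50% within Monte-Carlo error (the MC
  standard error is the SD of per-participant window means over
  √participants).
* `null_calibration("svr")` — grand-mean shuffled-rating Fisher-Z;
  should be 0 within Monte-Carlo error.
* `fwer_simulation()` — fraction of 100 independent signal-free studies
  in which the corrected pipeline declares any significant cluster;
  should not exceed the nominal 0.05 (within binomial error).

`scripts/acceptance.R` recomputes exactly these three quantities from
scratch at a caller-supplied seed. The test suite additionally verifies
signal *recovery*: with a late 440--860 ms injection at 24 µV per latent
unit (well above the noise floor, as effect sizes are free parameters)
and 16 participants, the corrected mask is non-empty and confined to the
injected window ±20 ms; adding the 40% early component produces an
uncorrected-significant run at 100--300 ms — detectable but too weak to
survive correction at this scale, mirroring the qualitative pattern such
studies report.

## Known limitations

* The generator's effects are injected as a fixed spatial pattern with
  a smooth envelope; real effects move across channels and time.
* Feature-weight maps inherit the usual caveat that linear-model
  weights are not activation patterns; an activation-transform variant
  is a natural extension and is deliberately not the default because
  the quantity of interest here is the classifier's own weighting.
* The per-channel significance of the topography is uncorrected across
  channels by design; treat it as descriptive.
* Between-group inferential comparison of decoding curves (beyond
  descriptive per-group runs) is out of scope.
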