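# erpdecode

Moving-window multivariate decoding of epoched EEG, with empirical-null
calibration and cluster-based permutation inference.

## What it is for

Studies of fast, automatic stimulus evaluation (for example, approach
responses to consumer products) record multi-channel EEG while
participants view images and judge them (Yes/No on appeal, curiosity,
wanting), then collect continuous 0–100 ratings afterwards. The
question is *when* the multivariate pattern of brain activity begins to
predict those judgements. `erpdecode` is for researchers running that
analysis: it decodes single-trial epochs in consecutive 10-ms windows
and tells you which windows carry reliable information, with familywise
error controlled across the whole time axis.

## The statistics at its core

Per participant, question dimension, and 10-ms window *w* with feature
matrix $X_w$ (channels × samples flattened, z-scored with training-fold
statistics):

* **SVM classification** — a linear soft-margin SVM (LIBSVM via
  `e1071`, C = 1) predicts Yes/No; the statistic is held-out accuracy
  $A_w$ averaged over 10-fold × 10-repetition cross-validation,
  stratified and class-balanced so chance is 50%.
* **SVR regression** — a linear ε-SVR predicts ratings; the statistic
  is the Fisher-Z correlation $Z_w = \operatorname{atanh} r(\hat y, y)$
  between held-out predictions and true ratings, computed per fold and
  averaged (chance is Z = 0).
* **Empirical null** — the identical machinery re-run with labels
  (ratings) shuffled once per CV repetition gives null series
  $A^0_w, Z^0_w$.
* **Group inference** — per window, a one-tailed paired *t* on
  $d_w = A_w - A^0_w$ across participants; clusters are maximal runs of
  contiguous windows with $p < .05$ and $t > 0$, scored by mass
  $\sum_w t_w$, and compared against the max-cluster-mass distribution
  under random per-participant sign flips of $d$:
  $p_{\text{cluster}} = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_{\text{perm}})$.
* **Feature weights** — per significant cluster, absolute SVM weights
  averaged per channel, z-standardized across channels, averaged over
  windows and tested against zero, ranking channel contributions.

A synthetic-study generator (spatially correlated pink + white noise; a
latent "appeal" variable that jointly drives Yes/No responses, ratings
and an injected spatiotemporal EEG component) makes every stage
testable without recorded data. Participants with fewer than 20 trials
in either response class, or insufficiently variable ratings, are
excluded per analysis — the same eligibility rules applied in practice.

## Worked example

A six-participant synthetic study with a strong component injected at
100–260 ms, decoded and tested end to end:

```r
library(erpdecode)

cfg <- sim_config(
  n_participants = 6, group_sizes = c(never = 2, current = 2, past = 2),
  n_images = 40, n_channels = 8, epoch_span = c(-100, 300),
  signal_window = c(100, 260), early_window = c(0, 80),
  early_amplitude_frac = 0, signal_amplitude = 40, noise_sd = 8,
  behavior_params = list(group_mean = c(never = 0, current = 0, past = 0),
                         participant_sd = 0.1, yes_intercept = 0,
                         yes_slope = 6))
study <- generate_study(cfg, seed = 42)

params <- decode_params(folds = 3, repetitions = 2, min_per_class = 10)
diffs <- NULL
for (ds in study$datasets) {
  ds <- baseline_correct(ds)
  ds <- reject_amplitude(ds)$dataset
  grid <- build_windows(ds$times, ds$sampling_rate, 10)
  res <- run_participant(ds, "appealing", "svm", grid, params,
                         seed = derive_seed(42, "p", ds$participant_id))
  diffs <- rbind(diffs, res$value_true - res$value_null)
}
cluster_permutation_test(diffs, n_permutations = 1000, seed = 7,
                         times_ms = grid$times_ms)
```

```
<group_stat_result> 6 participants, 41 windows, 1000 permutations
  cluster 1: windows 9-9 (-18..-18 ms), mass 2.11, p = 0.7602
  cluster 2: windows 16-16 (51..51 ms), mass 2.43, p = 0.6204
  cluster 3: windows 24-28 (129..168 ms), mass 24.76, p = 0.0010 *
  cluster 4: windows 30-34 (188..227 ms), mass 18.16, p = 0.0170 *
  cluster 5: windows 39-39 (275..275 ms), mass 2.83, p = 0.4575
```

The two corrected-significant clusters (`*`) fall inside the injected
100–260 ms window; the isolated supra-threshold windows elsewhere —
expected by chance at the 0.05 forming threshold — are correctly
rejected by the permutation correction. Whole runs can equally be
driven from a JSON config through `run_config()` and
`stage_simulate()` → `stage_decode()` → `stage_group()` →
`stage_behavior()` → `stage_report()`, or from the shell via
`Rscript inst/cli/erpdecode.R <stage> --config run.json`.

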