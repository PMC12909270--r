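#' Desk-scale null-study configuration
#'
#' A reduced, signal-free version of the study design used for chance and
#' familywise-error calibration: no injected signal, symmetric behavior
#' (Yes and No equally likely, no group offsets), a reduced montage and a
#' short epoch giving a 30-window grid at 512 Hz. All sizes can be
#' overridden.
#'
#' @param n_participants participants in the null study.
#' @param n_images images (= trials per question dimension).
#' @param n_channels montage size of the reduced study.
#' @param epoch_span ms; the default spans 30 complete 10-ms windows.
#' @param ... further overrides forwarded to [sim_config()].
#' @return a [sim_config()] with `signal_amplitude = 0`.
#' @export
null_study_config <- function(n_participants = 20, n_images = 120,
                              n_channels = 16, epoch_span = c(-100, 200),
                              ...) {
  gs <- c(never = 0, current = 0, past = 0)
  gs[] <- c(rep(ceiling(n_participants / 3), 2),
            n_participants - 2 * ceiling(n_participants / 3))
  sim_config(n_participants = n_participants, group_sizes = gs,
             n_images = n_images, n_channels = n_channels,
             epoch_span = epoch_span, signal_window = c(0, 100),
             early_window = c(0, 50), signal_amplitude = 0,
             behavior_params = list(
               group_mean = c(never = 0, current = 0, past = 0),
               yes_intercept = 0),
             ...)
}

#' Chance-level calibration of the shuffled-label analyses
#'
#' Generates a signal-free study, runs the full moving-window analysis
#' (true and shuffled-label series) for every participant on one question
#' dimension, and summarises the null series: its grand mean estimates
#' the empirical chance level, which should be 50% accuracy for the SVM
#' classifier and Fisher-Z = 0 for the SVR. The Monte-Carlo standard
#' error is the standard error of the per-participant window-mean values.
#'
#' @param mode `"svm"` or `"svr"`.
#' @param config a [sim_config()]; defaults to [null_study_config()].
#' @param params a [decode_params()]; the default uses the reduced
#'   3-fold x 1-repetition CV of the calibration grid.
#' @param dimension question dimension analysed.
#' @param seed master seed.
#' @return list: `grand_mean_null`, `grand_mean_true`, `mc_se`,
#'   `per_participant` (window-mean null value per participant),
#'   `n_windows`, `n_participants`.
#' @export
null_calibration <- function(mode = c("svm", "svr"),
                             config = null_study_config(),
                             params = decode_params(folds = 3, repetitions = 1),
                             dimension = "appealing", seed = 1) {
  mode <- match.arg(mode)
  stopifnot(config$signal_amplitude == 0)
  study <- generate_study(config, seed = derive_seed(seed, "nullstudy"),
                          dimensions = dimension)
  per_null <- c(); per_true <- c(); n_windows <- NA_integer_
  for (ds in study$datasets) {
    ds <- preprocess(ds)
    grid <- build_windows(ds$times, ds$sampling_rate, params$window_ms)
    n_windows <- grid$n_windows
    res <- run_participant(ds, dimension, mode, grid, params,
                           seed = derive_seed(seed, "cal", mode,
                                              ds$participant_id))
    if (is.null(res)) next
    per_null <- c(per_null, mean(res$value_null))
    per_true <- c(per_true, mean(res$value_true))
  }
  list(grand_mean_null = mean(per_null), grand_mean_true = mean(per_true),
       mc_se = stats::sd(per_null) / sqrt(length(per_null)),
       per_participant = per_null, n_windows = n_windows,
       n_participants = length(per_null))
}

#' Familywise-error simulation of the full group pipeline
#'
#' Repeatedly simulates independent signal-free studies, runs the
#' moving-window SVM decoding (true and shuffled-label series) for every
#' participant, applies the cluster-based permutation correction, and
#' reports the fraction of studies declaring at least one corrected-
#' significant cluster -- the empirical familywise error rate, which
#' should not exceed the nominal cluster alpha. The default uses the
#' reduced calibration grid with channel-mean features to keep large
#' simulation batteries tractable.
#'
#' @param n_studies number of independent null studies (>= 1).
#' @param config a signal-free [sim_config()] used for every study.
#' @param params a [decode_params()].
#' @param n_permutations cluster permutations per study.
#' @param alpha_forming,alpha_cluster cluster test thresholds.
#' @param dimension question dimension analysed.
#' @param seed master seed; study s uses a seed derived from `(seed, s)`.
#' @return list: `fwer` (fraction of positive studies), `positive`
#'   (logical per study), `n_studies`, `binomial_se`.
#' @export
fwer_simulation <- function(n_studies = 100,
                            config = null_study_config(n_images = 60),
                            params = decode_params(folds = 3, repetitions = 1,
                                                   feature_mode = "chanmean"),
                            n_permutations = 500, alpha_forming = 0.05,
                            alpha_cluster = 0.05, dimension = "appealing",
                            seed = 1) {
  stopifnot(n_studies >= 1, config$signal_amplitude == 0)
  positive <- logical(n_studies)
  for (s in seq_len(n_studies)) {
    sseed <- derive_seed(seed, "study", s)
    study <- generate_study(config, seed = sseed, dimensions = dimension)
    diffs <- NULL
    for (ds in study$datasets) {
      ds <- preprocess(ds)
      grid <- build_windows(ds$times, ds$sampling_rate, params$window_ms)
      res <- run_participant(ds, dimension, "svm", grid, params,
                             seed = derive_seed(sseed, "p", ds$participant_id))
      if (is.null(res)) next
      diffs <- rbind(diffs, res$value_true - res$value_null)
    }
    gs <- cluster_permutation_test(diffs, n_permutations = n_permutations,
                                   alpha_forming = alpha_forming,
                                   alpha_cluster = alpha_cluster,
                                   seed = derive_seed(sseed, "perm"))
    positive[s] <- any(gs$significant)
  }
  fwer <- mean(positive)
  list(fwer = fwer, positive = positive, n_studies = n_studies,
       binomial_se = sqrt(alpha_cluster * (1 - alpha_cluster) / n_studies))
}
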