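#' Decoding parameters
#'
#' Bundles the tunable constants of the per-participant moving-window
#' analyses. Defaults follow the analysis protocol: 10-fold
#' cross-validation repeated 10 times, linear kernel with fixed cost 1
#' (the model is deliberately not tuned for accuracy -- inference rests on
#' the comparison against the shuffled-label null, not on the absolute
#' accuracy), 10-ms windows, spatiotemporal features, one label shuffle
#' per CV repetition, classification eligibility at 20 trials per class.
#'
#' @param folds CV folds.
#' @param repetitions CV repetitions (fold assignment re-randomized each).
#' @param cost soft-margin regularization constant of the linear SVM/SVR.
#' @param window_ms analysis window duration, ms.
#' @param feature_mode `"spatiotemporal"` (channels x samples) or
#'   `"chanmean"` (per-channel window means).
#' @param min_per_class classification eligibility threshold.
#' @param min_unique,min_sd regression eligibility thresholds (distinct
#'   rating values; rating-unit SD).
#' @param n_shuffles_per_repetition label shuffles per CV repetition in
#'   null runs.
#' @return a list of class `decode_params`.
#' @export
decode_params <- function(folds = 10, repetitions = 10, cost = 1,
                          window_ms = 10,
                          feature_mode = c("spatiotemporal", "chanmean"),
                          min_per_class = 20, min_unique = 5, min_sd = 1,
                          n_shuffles_per_repetition = 1) {
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions), cost = cost,
                 window_ms = window_ms,
                 feature_mode = match.arg(feature_mode),
                 min_per_class = min_per_class, min_unique = min_unique,
                 min_sd = min_sd,
                 n_shuffles_per_repetition = as.integer(n_shuffles_per_repetition)),
            class = "decode_params")
}

#' Fisher-Z transform of a correlation
#'
#' `z = atanh(r)`, with `r` clamped just inside (-1, 1) so perfect
#' correlations map to a large finite value.
#' @param r correlation coefficient(s).
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r) atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, r)))

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

# z-score columns by training statistics; constant columns are zeroed
scale_train_test <- function(Xtr, Xte) {
  n <- nrow(Xtr)
  m <- colMeans(Xtr)
  v <- (colSums(Xtr^2) - n * m^2) / (n - 1)
  s <- sqrt(pmax(v, 0))
  s[s < 1e-12] <- Inf   # constant feature carries no information
  list(tr = t((t(Xtr) - m) / s), te = t((t(Xte) - m) / s))
}

#' Cross-validated linear SVM classification accuracy
#'
#' Trains a linear soft-margin SVM (LIBSVM through \pkg{e1071}) on
#' stratified training folds and scores the held-out folds; the returned
#' value is the percentage of correct held-out predictions averaged over
#' folds and repetitions. Fold assignment is re-randomized per repetition.
#' Features are z-scored using training-fold statistics only. Decision
#' values of exactly zero resolve to the first class in label order.
#'
#' With `shuffle_labels = TRUE` the labels are permuted uniformly at
#' random once per repetition before fold assignment, yielding the
#' empirical-null accuracy with identical CV machinery.
#'
#' @param features matrix `trials x features`.
#' @param labels binary labels; should be balanced (see
#'   [balance_classes()]) so 50% is the chance level.
#' @param folds,repetitions,cost see [decode_params()].
#' @param seed integer seed; results are deterministic given it.
#' @param shuffle_labels run the shuffled-label null instead.
#' @return mean held-out accuracy in percent.
#' @export
svm_cv_accuracy <- function(features, labels, folds = 10, repetitions = 10,
                            cost = 1, seed = 1, shuffle_labels = FALSE) {
  y <- factor(as.character(labels))
  if (nlevels(y) != 2) stop_invalid("labels must contain exactly two classes")
  if (min(table(y)) < folds)
    stop_invalid("fewer trials (%d) in a class than folds (%d)",
                 min(table(y)), folds)
  n <- nrow(features)
  set.seed(seed)
  acc <- numeric(repetitions)
  for (rep_i in seq_len(repetitions)) {
    y_rep <- if (shuffle_labels) y[sample.int(n)] else y
    fold <- stratified_folds(y_rep, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- fold == f
      sc <- scale_train_test(features[!te, , drop = FALSE],
                             features[te, , drop = FALSE])
      m <- e1071::svm(sc$tr, y_rep[!te], kernel = "linear", cost = cost,
                      scale = FALSE, fitted = FALSE,
                      na.action = stats::na.pass)
      w <- crossprod(m$coefs, m$SV)
      dv <- as.numeric(sc$te %*% t(w)) - m$rho
      pos <- m$levels[m$labels[1]]
      neg <- m$levels[m$labels[2]]
      pred <- ifelse(dv > 0, pos, ifelse(dv < 0, neg, levels(y)[1]))
      correct <- correct + sum(pred == as.character(y_rep)[te])
    }
    acc[rep_i] <- 100 * correct / n
  }
  mean(acc)
}

#' Cross-validated linear SVR rating prediction (Fisher-Z)
#'
#' Trains a linear epsilon-SVR on training folds and correlates held-out
#' predictions with the true ratings, Fisher-Z transformed and averaged
#' over folds and repetitions. By default the correlation is computed
#' within each held-out fold (`pooling = "fold"`): this keeps the chance
#' level at exactly Z = 0, whereas correlating the predictions pooled
#' across folds (`pooling = "repetition"`) is negatively biased under the
#' null, because each fold's fitted intercept tracks its training-set
#' rating mean, which anti-correlates with the held-out mean in a finite
#' sample. Ratings are used on their native 0-100 scale and predictions
#' are not clipped. Zero-variance predictions leave the correlation
#' undefined; such folds contribute Z = 0 with a warning.
#' `shuffle_ratings` permutes the ratings once per repetition (empirical
#' null).
#'
#' @param features matrix `trials x features`.
#' @param ratings numeric ratings, one per trial.
#' @inheritParams svm_cv_accuracy
#' @param shuffle_ratings run the shuffled-rating null instead.
#' @param pooling correlate per held-out fold (default) or pool
#'   predictions across a repetition's folds first.
#' @return mean Fisher-Z.
#' @export
svr_cv_fisherz <- function(features, ratings, folds = 10, repetitions = 10,
                           cost = 1, seed = 1, shuffle_ratings = FALSE,
                           pooling = c("fold", "repetition")) {
  pooling <- match.arg(pooling)
  n <- nrow(features)
  if (length(ratings) != n) stop_invalid("one rating per trial required")
  if (n < folds) stop_invalid("fewer trials (%d) than folds (%d)", n, folds)
  set.seed(seed)
  zs <- numeric(repetitions)
  degenerate <- FALSE
  z_of <- function(pred, truth) {
    if (stats::sd(pred) < 1e-12 || stats::sd(truth) < 1e-12) {
      degenerate <<- TRUE
      0
    } else fisher_z(stats::cor(pred, truth))
  }
  for (rep_i in seq_len(repetitions)) {
    r_rep <- if (shuffle_ratings) ratings[sample.int(n)] else ratings
    fold <- sample(rep_len(seq_len(folds), n))
    preds <- numeric(n)
    z_fold <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- fold == f
      sc <- scale_train_test(features[!te, , drop = FALSE],
                             features[te, , drop = FALSE])
      m <- e1071::svm(sc$tr, r_rep[!te], kernel = "linear", cost = cost,
                      scale = FALSE, type = "eps-regression",
                      fitted = FALSE, na.action = stats::na.pass)
      w <- crossprod(m$coefs, m$SV)
      preds[te] <- as.numeric(sc$te %*% t(w)) - m$rho
      if (pooling == "fold") z_fold[f] <- z_of(preds[te], r_rep[te])
    }
    zs[rep_i] <- if (pooling == "fold") mean(z_fold) else z_of(preds, r_rep)
  }
  if (degenerate)
    warning("zero-variance predictions or ratings; affected folds scored Z = 0")
  mean(zs)
}

#' Run the full moving-window analysis for one participant
#'
#' Checks eligibility, balances classes (SVM), then loops over the window
#' grid computing the true and shuffled-label (null) statistic per window.
#' Per-window seeds are derived deterministically from the participant
#' seed and the window index, so windows may be computed in any order or
#' in parallel with results identical to a serial run.
#'
#' @param ds an [epoched_dataset], baseline-corrected, with rejection
#'   flags set.
#' @param dimension question dimension to analyse.
#' @param mode `"svm"` (Yes/No classification, percent accuracy) or
#'   `"svr"` (rating regression, Fisher-Z).
#' @param grid a [build_windows()] grid.
#' @param params a [decode_params()].
#' @param seed integer seed for this participant-dimension analysis.
#' @return object of class `participant_decoding_result` (fields:
#'   `participant_id`, `dimension`, `mode`, `times_ms`, `value_true`,
#'   `value_null`, trial counts, CV constants, `seed`), or `NULL` with a
#'   message when the participant is ineligible.
#' @export
run_participant <- function(ds, dimension, mode = c("svm", "svr"), grid,
                            params = decode_params(), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "window_grid"))
  sel <- select_trials(ds, dimension, drop_rejected = TRUE,
                       drop_missing = TRUE)

  if (mode == "svm") {
    if (!eligibility_classification(sel$trials$response, params$min_per_class)) {
      message(sprintf("%s/%s ineligible for svm: need >= %d trials per class (yes = %d, no = %d)",
                      ds$participant_id, dimension, params$min_per_class,
                      sum(sel$trials$response == "yes"),
                      sum(sel$trials$response == "no")))
      return(invisible(NULL))
    }
    keep <- balance_classes(sel$trials$response,
                            derive_seed(seed, "balance"))
    sel$voltages <- sel$voltages[keep, , , drop = FALSE]
    sel$trials <- sel$trials[keep, , drop = FALSE]
    y <- sel$trials$response
    n_info <- min(table(y))
  } else {
    has_rating <- !is.na(sel$trials$rating)
    sel$voltages <- sel$voltages[has_rating, , , drop = FALSE]
    sel$trials <- sel$trials[has_rating, , drop = FALSE]
    if (!eligibility_regression(sel$trials$rating, params$min_unique,
                                params$min_sd) ||
        nrow(sel$trials) < params$folds) {
      message(sprintf("%s/%s ineligible for svr: ratings insufficiently variable or too few rated trials (%d)",
                      ds$participant_id, dimension, nrow(sel$trials)))
      return(invisible(NULL))
    }
    y <- sel$trials$rating
    n_info <- length(y)
  }

  n_win <- grid$n_windows
  v_true <- numeric(n_win)
  v_null <- numeric(n_win)
  null_reps <- params$repetitions * params$n_shuffles_per_repetition
  for (w in seq_len(n_win)) {
    X <- extract_features(sel, grid$windows[w, ], params$feature_mode)
    sw <- derive_seed(seed, "win", w)
    if (mode == "svm") {
      v_true[w] <- svm_cv_accuracy(X, y, params$folds, params$repetitions,
                                   params$cost, derive_seed(sw, "true"))
      v_null[w] <- svm_cv_accuracy(X, y, params$folds, null_reps,
                                   params$cost, derive_seed(sw, "null"),
                                   shuffle_labels = TRUE)
    } else {
      v_true[w] <- svr_cv_fisherz(X, y, params$folds, params$repetitions,
                                  params$cost, derive_seed(sw, "true"))
      v_null[w] <- svr_cv_fisherz(X, y, params$folds, null_reps,
                                  params$cost, derive_seed(sw, "null"),
                                  shuffle_ratings = TRUE)
    }
  }
  structure(list(participant_id = ds$participant_id, dimension = dimension,
                 mode = mode, times_ms = grid$times_ms,
                 value_true = v_true, value_null = v_null,
                 n_trials = nrow(sel$trials), n_per_class = n_info,
                 cv_folds = params$folds, cv_repetitions = params$repetitions,
                 seed = seed),
            class = "participant_decoding_result")
}

#' @export
print.participant_decoding_result <- function(x, ...) {
  cat(sprintf("<participant_decoding_result> %s / %s / %s: %d windows, %d trials\n",
              x$participant_id, x$dimension, x$mode, length(x$times_ms),
              x$n_trials))
  cat(sprintf("  mean true = %.3f, mean null = %.3f, peak true = %.3f @ %.0f ms\n",
              mean(x$value_true), mean(x$value_null), max(x$value_true),
              x$times_ms[which.max(x$value_true)]))
  invisible(x)
}

#' Tidy a decoding result into a data.frame
#' @param x a `participant_decoding_result`.
#' @return data.frame: participant, dimension, mode, window_time_ms,
#'   value_true, value_null.
#' @export
as.data.frame.participant_decoding_result <- function(x, ...) {
  data.frame(participant = x$participant_id, dimension = x$dimension,
             mode = x$mode, window_time_ms = x$times_ms,
             value_true = x$value_true, value_null = x$value_null,
             stringsAsFactors = FALSE)
}
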