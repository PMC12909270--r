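test_that("eligibility rules reproduce the stated trial-count thresholds", {
  resp <- function(yes, no) c(rep("yes", yes), rep("no", no))
  expect_false(eligibility_classification(resp(19, 101)))
  expect_true(eligibility_classification(resp(20, 20)))
  expect_false(eligibility_classification(resp(0, 120)))
  expect_true(eligibility_classification(resp(5, 5), min_per_class = 5))
  # missing responses do not count toward either class
  expect_false(eligibility_classification(c(resp(19, 30), rep("none", 10))))

  expect_false(eligibility_regression(rep(0, 50)))
  expect_true(eligibility_regression(seq(0, 100, length.out = 50)))
  set.seed(1)
  expect_false(eligibility_regression(rnorm(50, 50, 0.5)))   # SD below 1
  expect_false(eligibility_regression(rep(c(10, 90), 25), min_unique = 5))
})

test_that("class balancing subsamples the majority deterministically", {
  labels <- c(rep("yes", 30), rep("no", 90))
  keep <- balance_classes(labels, seed = 5)
  expect_length(keep, 60)
  expect_equal(unname(table(labels[keep])), c(30L, 30L),
               ignore_attr = TRUE)
  expect_identical(keep, balance_classes(labels, seed = 5))
  # balanced input passes through unchanged
  bal <- rep(c("yes", "no"), 10)
  expect_identical(balance_classes(bal, 1), 1:20)
  expect_error(balance_classes(rep("yes", 10), 1), "two classes")
})

test_that("SVM cross-validation separates separable clouds and is at chance otherwise", {
  sep <- separable_features(n_per_class = 30, sep = 10, sd = 0.1)
  acc <- svm_cv_accuracy(sep$X, sep$y, folds = 5, repetitions = 2, seed = 1)
  expect_gt(acc, 99)

  # labels independent of features: accuracy ~= 50% within binomial error
  set.seed(7)
  X <- matrix(rnorm(200 * 6), 200, 6)
  y <- rep(c("no", "yes"), 100)
  acc0 <- svm_cv_accuracy(X, y, folds = 5, repetitions = 4, seed = 2)
  expect_lt(abs(acc0 - 50), 3 * 100 * sqrt(0.25 / 200))  # 3 binomial SEs

  # shuffled labels destroy a strong signal
  accn <- svm_cv_accuracy(sep$X, sep$y, folds = 5, repetitions = 4,
                          seed = 3, shuffle_labels = TRUE)
  expect_lt(abs(accn - 50), 15)

  expect_identical(svm_cv_accuracy(X, y, folds = 5, repetitions = 2, seed = 9),
                   svm_cv_accuracy(X, y, folds = 5, repetitions = 2, seed = 9))
  expect_error(svm_cv_accuracy(X[1:12, ], y[1:12], folds = 10), "fewer trials")
})

test_that("fold-level predictions agree with a direct LIBSVM oracle on a tiny split", {
  # dual route: the engine's manual decision-value predictions must equal
  # predict.svm on the same scaled split
  set.seed(4)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- factor(rep(c("no", "yes"), 6))
  tr <- c(1:4, 7:10)
  m_tr <- colMeans(X[tr, ]); s_tr <- apply(X[tr, ], 2, sd)
  Xtr <- scale(X[tr, ], m_tr, s_tr); Xte <- scale(X[-tr, ], m_tr, s_tr)
  m <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = 1, scale = FALSE)
  w <- crossprod(m$coefs, m$SV)
  dv <- as.numeric(Xte %*% t(w)) - m$rho
  manual <- ifelse(dv > 0, m$levels[m$labels[1]], m$levels[m$labels[2]])
  expect_identical(manual, as.character(predict(m, Xte)))
})

test_that("SVR recovers a noiseless linear rating map and is at chance for noise", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60, 4)
  ratings <- 50 + 20 * X[, 2]          # exact linear function of a feature
  z <- svr_cv_fisherz(X, ratings, folds = 5, repetitions = 2, seed = 1)
  expect_gt(z, 2)

  ratings0 <- sample(0:100, 60, replace = TRUE)
  z0 <- svr_cv_fisherz(X, ratings0, folds = 5, repetitions = 4, seed = 2)
  expect_lt(abs(z0), 0.3)

  zn <- svr_cv_fisherz(X, ratings, folds = 5, repetitions = 4, seed = 3,
                       shuffle_ratings = TRUE)
  expect_lt(abs(zn), 0.3)

  # Fisher-Z reference points
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0), 0)
  expect_true(is.finite(fisher_z(1)))

  # constant features give zero-variance predictions -> Z = 0 with warning
  Xc <- matrix(1, 30, 3)
  expect_warning(zc <- svr_cv_fisherz(Xc, ratings0[1:30], folds = 3,
                                      repetitions = 1, seed = 4),
                 "zero-variance")
  expect_equal(zc, 0)
})

test_that("run_participant localizes an injected late signal and skips ineligible data", {
  cfg <- tiny_config(n_participants = 2, group_sizes = c(0, 2, 0),
                     n_images = 60, signal_amplitude = 40,
                     early_amplitude_frac = 0, noise_sd = 8,
                     behavior_params = list(group_mean = c(never = 0, current = 0, past = 0),
                                            yes_intercept = 0, yes_slope = 6))
  st <- generate_study(cfg, seed = 45)
  ds <- baseline_correct(st$datasets[[1]])
  grid <- build_windows(ds$times, ds$sampling_rate, 10)
  params <- decode_params(folds = 5, repetitions = 2, min_per_class = 10)
  res <- run_participant(ds, "appealing", "svm", grid, params, seed = 3)

  expect_s3_class(res, "participant_decoding_result")
  expect_length(res$value_true, grid$n_windows)
  expect_length(res$value_null, grid$n_windows)
  expect_true(all(res$value_true >= 0 & res$value_true <= 100))

  sig <- res$times_ms >= 100 & res$times_ms < 260
  base <- res$times_ms < 0
  # decodable only where the signal was injected
  expect_gt(mean(res$value_true[sig]), mean(res$value_true[base]) + 10)
  expect_lt(abs(mean(res$value_true[base]) - 50), 8)
  expect_lt(abs(mean(res$value_null) - 50), 5)

  # determinism of the full per-participant loop
  res2 <- run_participant(ds, "appealing", "svm", grid, params, seed = 3)
  expect_identical(res$value_true, res2$value_true)
  expect_identical(res$value_null, res2$value_null)

  # ineligible participant is skipped with a message
  few <- ds
  few$trials$response[few$trials$dimension == "appealing"][1:35] <- "no"
  expect_message(
    out <- run_participant(few, "appealing", "svm", grid,
                           decode_params(folds = 4, repetitions = 1,
                                         min_per_class = 20), seed = 1),
    "ineligible")
  expect_null(out)
})

test_that("per-window seeding makes window order irrelevant", {
  cfg <- tiny_config(n_participants = 1, group_sizes = c(0, 1, 0),
                     n_images = 20, signal_amplitude = 0,
                     behavior_params = list(group_mean = c(never = 0, current = 0, past = 0)))
  st <- generate_study(cfg, seed = 8)
  ds <- baseline_correct(st$datasets[[1]])
  grid <- build_windows(ds$times, ds$sampling_rate, 10)
  params <- decode_params(folds = 3, repetitions = 1, min_per_class = 5)
  full <- run_participant(ds, "appealing", "svm", grid, params, seed = 21)

  # recompute one window in isolation through the same seed derivation
  sel <- select_trials(ds, "appealing", drop_missing = TRUE)
  keep <- balance_classes(sel$trials$response, derive_seed(21, "balance"))
  sel$voltages <- sel$voltages[keep, , , drop = FALSE]
  sel$trials <- sel$trials[keep, , drop = FALSE]
  w <- 17
  X <- extract_features(sel, grid$windows[w, ])
  sw <- derive_seed(21, "win", w)
  expect_identical(full$value_true[w],
                   svm_cv_accuracy(X, sel$trials$response, 3, 1, 1,
                                   derive_seed(sw, "true")))
  expect_identical(full$value_null[w],
                   svm_cv_accuracy(X, sel$trials$response, 3, 1, 1,
                                   derive_seed(sw, "null"),
                                   shuffle_labels = TRUE))
})
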