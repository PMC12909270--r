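#' One-tailed paired-samples t test (true vs null)
#'
#' Tests whether the true-label decoding statistic exceeds the
#' shuffled-label (null) statistic across participants: t on the paired
#' differences `d = true - null`, upper-tail p from Student's t with
#' `n - 1` degrees of freedom. Zero-variance differences are flagged
#' degenerate, with p = 0 when the common difference is positive and
#' p = 1 otherwise.
#'
#' @param values_true,values_null equal-length per-participant vectors.
#' @return list: `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_onetailed <- function(values_true, values_null) {
  stopifnot(length(values_true) == length(values_null),
            length(values_true) >= 2)
  d <- values_true - values_null
  n <- length(d)
  s <- stats::sd(d)
  if (s < 1e-14) {
    m <- mean(d)
    return(list(t = if (m > 0) Inf else if (m < 0) -Inf else 0,
                p = if (m > 0) 0 else 1, df = n - 1, degenerate = TRUE))
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, p = stats::pt(tval, n - 1, lower.tail = FALSE),
       df = n - 1, degenerate = FALSE)
}

# vectorized one-sample upper-tail t over the columns of a matrix
col_onetailed_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D * D) - n * m^2) / (n - 1)
  s <- sqrt(pmax(v, 0) / n)
  tval <- ifelse(s < 1e-14, ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)),
                 m / s)
  p <- ifelse(is.infinite(tval), ifelse(tval > 0, 0, 1),
              ifelse(s < 1e-14, 1, stats::pt(tval, n - 1, lower.tail = FALSE)))
  list(t = tval, p = p)
}

#' Find supra-threshold clusters along the window axis
#'
#' Clusters are maximal runs of contiguous windows with uncorrected
#' `p < alpha_forming` and positive t; the cluster mass is the sum of t
#' over member windows.
#'
#' @param p_uncorrected,t aligned per-window series.
#' @param alpha_forming cluster-forming threshold.
#' @return data.frame with one row per cluster: `cluster_id`, `start`,
#'   `end` (window indices, inclusive), `mass`. Zero rows when nothing is
#'   supra-threshold.
#' @export
find_clusters <- function(p_uncorrected, t, alpha_forming = 0.05) {
  stopifnot(length(p_uncorrected) == length(t))
  supra <- (p_uncorrected < alpha_forming) & (t > 0)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ki <- which(r$values)
  data.frame(cluster_id = seq_along(ki),
             start = starts[ki], end = ends[ki],
             mass = vapply(ki, function(i)
               sum(t[starts[i]:ends[i]]), numeric(1)))
}

all_sign_matrix <- function(n) {
  if (n > 20) stop_invalid("exhaustive enumeration limited to n <= 20 participants")
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(m) <- NULL
  m
}

max_cluster_mass <- function(tval, p, alpha_forming) {
  cl <- find_clusters(p, tval, alpha_forming)
  if (nrow(cl) == 0) 0 else max(cl$mass)
}

#' Cluster-based permutation test across analysis windows
#'
#' Familywise-error-corrected group inference on a participants x windows
#' matrix of paired differences (true minus null decoding statistic). The
#' observed per-window one-tailed t series is thresholded at
#' `alpha_forming` and summarised by cluster mass; the null distribution
#' of the maximum cluster mass is built by randomly sign-flipping each
#' participant's difference series (exchangeable under the global null)
#' and re-running the identical threshold-and-cluster step. Cluster p
#' values use the permutation-inclusive estimator
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`; in exhaustive
#' mode all `2^n` sign assignments are enumerated and
#' `p = #\{null >= observed\} / 2^n` (the identity assignment is part of
#' the enumeration).
#'
#' @param diffs numeric matrix `participants x windows`.
#' @param n_permutations random sign flips (>= 1; a warning below 100).
#' @param alpha_forming cluster-forming (uncorrected, one-tailed)
#'   threshold.
#' @param alpha_cluster corrected significance level for clusters.
#' @param seed integer seed for the sign flips.
#' @param exhaustive enumerate all sign assignments (n <= 20).
#' @param times_ms optional per-window times carried into the result.
#' @return object of class `group_stat_result`: per-window `t` and
#'   `p_uncorrected`, `clusters` (with `cluster_p`), logical
#'   `significant` mask, `null_max_mass`, and the test constants.
#' @export
cluster_permutation_test <- function(diffs, n_permutations = 1000,
                                     alpha_forming = 0.05,
                                     alpha_cluster = 0.05, seed = 1,
                                     exhaustive = FALSE, times_ms = NULL) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2) stop_invalid("need at least 2 participants")
  if (!exhaustive) {
    if (n_permutations < 1) stop_invalid("n_permutations must be >= 1")
    if (n_permutations < 100)
      warning("fewer than 100 permutations gives a coarse null distribution")
  }

  obs <- col_onetailed_t(diffs)
  clusters <- find_clusters(obs$p, obs$t, alpha_forming)

  ss <- colSums(diffs * diffs)   # invariant under sign flips
  perm_max <- function(signs) {
    m <- as.numeric(signs %*% diffs) / n
    v <- (ss - n * m^2) / (n - 1)
    s <- sqrt(pmax(v, 0) / n)
    tval <- ifelse(s < 1e-14, ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)), m / s)
    p <- ifelse(is.infinite(tval), ifelse(tval > 0, 0, 1),
                ifelse(s < 1e-14, 1, stats::pt(tval, n - 1, lower.tail = FALSE)))
    max_cluster_mass(tval, p, alpha_forming)
  }

  if (exhaustive) {
    S <- all_sign_matrix(n)
    null_max <- apply(S, 1, perm_max)
    denom <- nrow(S)
    cluster_p <- vapply(seq_len(nrow(clusters)), function(i)
      sum(null_max >= clusters$mass[i]) / denom, numeric(1))
  } else {
    set.seed(seed)
    null_max <- vapply(seq_len(n_permutations), function(i)
      perm_max(sample(c(-1, 1), n, replace = TRUE)), numeric(1))
    cluster_p <- vapply(seq_len(nrow(clusters)), function(i)
      (1 + sum(null_max >= clusters$mass[i])) / (1 + n_permutations),
      numeric(1))
  }
  clusters$cluster_p <- if (nrow(clusters)) cluster_p else numeric(0)

  mask <- logical(ncol(diffs))
  for (i in seq_len(nrow(clusters)))
    if (clusters$cluster_p[i] < alpha_cluster)
      mask[clusters$start[i]:clusters$end[i]] <- TRUE

  structure(list(t = obs$t, p_uncorrected = obs$p, clusters = clusters,
                 significant = mask, null_max_mass = null_max,
                 n_participants = n,
                 n_cluster_permutations = if (exhaustive) length(null_max) else n_permutations,
                 alpha_forming = alpha_forming,
                 alpha_cluster = alpha_cluster, exhaustive = exhaustive,
                 times_ms = times_ms, seed = seed),
            class = "group_stat_result")
}

#' @export
print.group_stat_result <- function(x, ...) {
  cat(sprintf("<group_stat_result> %d participants, %d windows, %d permutations%s\n",
              x$n_participants, length(x$t), x$n_cluster_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      rng <- if (!is.null(x$times_ms))
        sprintf(" (%.0f..%.0f ms)", x$times_ms[x$clusters$start[i]],
                x$times_ms[x$clusters$end[i]]) else ""
      cat(sprintf("  cluster %d: windows %d-%d%s, mass %.2f, p = %.4f%s\n",
                  i, x$clusters$start[i], x$clusters$end[i], rng,
                  x$clusters$mass[i], x$clusters$cluster_p[i],
                  if (x$clusters$cluster_p[i] < x$alpha_cluster) " *" else ""))
    }
  }
  invisible(x)
}

#' Feature-weight topography over a significant cluster
#'
#' Quantifies which channels carry the discriminative signal in a cluster
#' of significant windows. Per participant and window, the linear SVM is
#' trained once on all eligible (balanced) trials, the absolute feature
#' weights are averaged over the in-window samples of each channel,
#' z-standardized across channels (mean 0, SD 1 within participant), then
#' averaged across the cluster's windows. Group inference per channel is a
#' one-tailed one-sample t of the standardized weights against zero;
#' channels with p < `alpha` form the significant set (uncorrected).
#'
#' @param datasets list of [epoched_dataset] objects (baseline-corrected,
#'   rejection flags set).
#' @param dimension question dimension.
#' @param cluster_windows integer vector of window indices (a cluster).
#' @param grid the [build_windows()] grid the indices refer to.
#' @param params a [decode_params()]; weights always use spatiotemporal
#'   features.
#' @param seed integer seed (class balancing).
#' @param alpha per-channel significance level.
#' @return object of class `feature_weight_map`: `channel_labels`,
#'   `weight_z` (group mean standardized |weight|), `t`, `p`,
#'   `significant`, `window_range_ms`, `n_participants`.
#' @export
feature_weight_map <- function(datasets, dimension, cluster_windows, grid,
                               params = decode_params(), seed = 1,
                               alpha = 0.05) {
  stopifnot(length(cluster_windows) >= 1)
  labels <- datasets[[1]]$channel_labels
  nc <- length(labels)
  rows <- list()
  for (ds in datasets) {
    sel <- select_trials(ds, dimension, drop_rejected = TRUE,
                         drop_missing = TRUE)
    if (!eligibility_classification(sel$trials$response, params$min_per_class))
      next
    keep <- balance_classes(sel$trials$response,
                            derive_seed(seed, "fw", ds$participant_id))
    sel$voltages <- sel$voltages[keep, , , drop = FALSE]
    sel$trials <- sel$trials[keep, , drop = FALSE]
    y <- factor(sel$trials$response)
    per_win <- matrix(0, length(cluster_windows), nc)
    for (j in seq_along(cluster_windows)) {
      X <- extract_features(sel, grid$windows[cluster_windows[j], ],
                            "spatiotemporal")
      X <- scale(X)
      X[, !is.finite(colSums(X))] <- 0
      m <- e1071::svm(X, y, kernel = "linear", cost = params$cost,
                      scale = FALSE, fitted = FALSE,
                      na.action = stats::na.pass)
      w <- abs(as.numeric(crossprod(m$coefs, m$SV)))
      cw <- colMeans(matrix(w, nrow = grid$samples_per_window))  # per channel
      per_win[j, ] <- (cw - mean(cw)) / stats::sd(cw)
    }
    rows[[length(rows) + 1L]] <- colMeans(per_win)
  }
  if (length(rows) < 2)
    stop_invalid("feature_weight_map needs at least 2 eligible participants")
  W <- do.call(rbind, rows)
  g <- col_onetailed_t(W)
  structure(list(channel_labels = labels, weight_z = colMeans(W),
                 t = g$t, p = g$p, significant = g$p < alpha,
                 window_range_ms = range(grid$times_ms[cluster_windows]),
                 n_participants = nrow(W), alpha = alpha),
            class = "feature_weight_map")
}

#' @export
print.feature_weight_map <- function(x, ...) {
  cat(sprintf("<feature_weight_map> %d channels, cluster %.0f..%.0f ms, n = %d\n",
              length(x$channel_labels), x$window_range_ms[1],
              x$window_range_ms[2], x$n_participants))
  sig <- x$channel_labels[x$significant]
  cat(sprintf("  significant channels (p < %g): %s\n", x$alpha,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}
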