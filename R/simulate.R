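#' Simulate ongoing-EEG noise epochs
#'
#' Each trial is an independent realization of spatially correlated
#' 1/f^`pink_exponent` noise (shared across channels through an AR(1)-type
#' channel correlation) plus independent white sensor noise, mixed so the
#' per-channel standard deviation is approximately `noise_sd` microvolts.
#' `noise_sd = 0` returns an all-zero array.
#'
#' @param n_trials number of epochs to draw (>= 1).
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical arrays.
#' @return numeric array `trials x channels x samples` (microvolts).
#' @export
simulate_noise_epochs <- function(n_trials, config, seed) {
  stopifnot(n_trials >= 1)
  if (config$noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  times <- make_times(config$epoch_span, config$sampling_rate)
  ns <- length(times); nc <- config$n_channels
  out <- array(0, dim = c(n_trials, nc, ns))
  if (config$noise_sd == 0) return(out)

  set.seed(seed)
  # spectral shaping filter for unit-variance pink noise
  f <- pmin(0:(ns - 1), ns - (0:(ns - 1)))
  g <- ifelse(f == 0, 0, f^(-config$pink_exponent / 2))
  g <- g * sqrt(ns / sum(g^2))

  # channel mixing: C_ij = rho^|i-j|, A'A = C keeps unit channel variance
  rho <- config$channel_corr
  C <- rho^abs(outer(seq_len(nc), seq_len(nc), "-"))
  A <- chol(C)

  pink <- matrix(0, ns, n_trials * nc)
  chunk <- max(1L, floor(4e6 / ns))
  for (i0 in seq(1L, n_trials * nc, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n_trials * nc)
    w <- matrix(stats::rnorm(ns * (i1 - i0 + 1L)), ns)
    pink[, i0:i1] <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / ns
  }
  # columns are (channel fastest, trial slowest); mix channels within trial
  pink <- array(pink, dim = c(ns, nc, n_trials))
  pm <- matrix(aperm(pink, c(1, 3, 2)), ncol = nc) %*% A
  pink <- aperm(array(pm, dim = c(ns, n_trials, nc)), c(2, 3, 1))

  white <- array(stats::rnorm(n_trials * nc * ns), dim = c(n_trials, nc, ns))
  sd_p <- sqrt(config$pink_frac) * config$noise_sd
  sd_w <- sqrt(1 - config$pink_frac) * config$noise_sd
  sd_p * pink + sd_w * white
}

#' Inject a patterned signal component into epochs
#'
#' Adds `amplitude[t] * pattern[c] * envelope[s]` to every trial t, channel
#' c and in-window sample s; samples outside the window are untouched. The
#' half-cosine envelope tapers to zero at the window edges, avoiding step
#' discontinuities that would make decoding artificially easy at window
#' borders; the boxcar is available for exact-additivity checks.
#'
#' @param epochs array `trials x channels x samples`.
#' @param amplitudes per-trial amplitude in microvolts.
#' @param pattern per-channel weight vector.
#' @param window `[start, end)` interval in ms.
#' @param times per-sample time axis in ms.
#' @param envelope `"halfcosine"` or `"boxcar"`.
#' @return the epochs array with the component added.
#' @export
inject_signal <- function(epochs, amplitudes, pattern, window, times,
                          envelope = c("halfcosine", "boxcar")) {
  envelope <- match.arg(envelope)
  d <- dim(epochs)
  stopifnot(length(d) == 3, length(times) == d[3],
            length(pattern) == d[2])
  if (length(amplitudes) != d[1])
    stop_invalid("amplitudes length (%d) must equal n_trials (%d)",
                 length(amplitudes), d[1])
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  if (window[1] < times[1] || window[2] > times[length(times)] + dt ||
      window[1] >= window[2])
    stop_invalid("window [%g, %g) outside epoch span", window[1], window[2])
  idx <- ms_to_samples(times, window)
  if (length(idx) == 0) stop_invalid("window contains no samples")
  m <- length(idx)
  env <- if (envelope == "boxcar") rep(1, m) else sin(pi * (seq_len(m) - 0.5) / m)
  delta <- outer(amplitudes, pattern)           # trials x channels
  epochs[, , idx] <- epochs[, , idx, drop = FALSE] + outer(delta, env)
  epochs
}

#' Draw the latent appeal structure of a study
#'
#' Latent appeal (standardized units) of participant p for image i is
#' `group_mean[g(p)] + b_p + c_i` with participant and image random
#' effects; it simultaneously drives the Yes/No responses, the 0-100
#' ratings and the injected EEG amplitude, which is what makes the
#' behavioral and neural measures mutually consistent.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `ground_truth`: `latent_appeal`
#'   (participants x images), `amplitude` (the affine map to microvolts),
#'   `signal_channels`, `groups` (per-participant factor).
#' @export
draw_ground_truth <- function(config, seed) {
  set.seed(seed)
  bp <- config$behavior_params
  np <- config$n_participants; ni <- config$n_images
  groups <- factor(rep(c("never", "current", "past"), times = config$group_sizes),
                   levels = c("never", "current", "past"))
  b <- stats::rnorm(np, 0, bp$participant_sd)
  cimg <- stats::rnorm(ni, 0, bp$image_sd)
  latent <- matrix(bp$group_mean[as.character(groups)] + b, np, ni) +
    matrix(cimg, np, ni, byrow = TRUE)
  dimnames(latent) <- list(sprintf("P%02d", seq_len(np)),
                           sprintf("img%03d", seq_len(ni)))
  labels <- channel_labels(config$n_channels)
  structure(list(
    latent_appeal = latent,
    amplitude = config$signal_amplitude * latent,
    signal_channels = labels[abs(config$spatial_pattern) > 1e-12],
    groups = groups
  ), class = "ground_truth")
}

#' Simulate behavioral responses from the latent appeal
#'
#' Yes/No responses arise from a logistic model on latent appeal
#' (independent noise per question dimension); 0-100 ratings are an affine
#' transform of latent appeal with Gaussian noise, clipped to the slider
#' range and rounded to integers. A small `p_missing` fraction of trials
#' can be recorded as `"none"` (no button press).
#'
#' @param config a [sim_config()].
#' @param truth a [draw_ground_truth()] result consistent with `config`.
#' @param seed integer seed.
#' @return list with `responses` (long data.frame: participant, group,
#'   image_id, dimension, response, rating, latent) and `table`
#'   (a [behavioral_table()]).
#' @export
simulate_behavior <- function(config, truth, seed) {
  stopifnot(inherits(truth, "ground_truth"),
            nrow(truth$latent_appeal) == config$n_participants,
            ncol(truth$latent_appeal) == config$n_images)
  set.seed(seed)
  bp <- config$behavior_params
  np <- config$n_participants; ni <- config$n_images
  dims <- c("appealing", "curiosity", "wanting")

  df <- expand.grid(participant = rownames(truth$latent_appeal),
                    image_id = colnames(truth$latent_appeal),
                    dimension = dims,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lat <- as.vector(truth$latent_appeal)      # participant fastest
  df$latent <- rep(lat, times = length(dims))
  df$group <- as.character(truth$groups)[match(df$participant,
                                               rownames(truth$latent_appeal))]
  p_yes <- stats::plogis(bp$yes_intercept + bp$yes_slope * df$latent)
  df$response <- ifelse(stats::runif(nrow(df)) < p_yes, "yes", "no")
  if (bp$p_missing > 0)
    df$response[stats::runif(nrow(df)) < bp$p_missing] <- "none"
  rating <- bp$rating_intercept + bp$rating_slope * df$latent +
    stats::rnorm(nrow(df), 0, bp$rating_noise_sd)
  df$rating <- as.integer(round(pmin(100, pmax(0, rating))))

  list(responses = df, table = behavioral_table(df))
}

#' Generate a complete synthetic study
#'
#' One epoched dataset per participant (each image shown once per question
#' dimension, trial order randomized per participant), behavioral table,
#' and ground truth. The per-trial injected EEG amplitude is
#' `signal_amplitude x latent_appeal` of the presented image, applied in
#' the late window at full strength and in the early window at
#' `early_amplitude_frac` strength, over `spatial_pattern`. Bit-identical
#' across runs for a given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @param dimensions question dimensions to realize as EEG trials;
#'   behavioral responses are always generated for all three, but
#'   restricting the epoched data to the dimension(s) under analysis
#'   keeps large simulation batteries light.
#' @return list with `datasets` (list of [epoched_dataset] objects),
#'   `behavior` (behavioral_table), `responses` (long data.frame) and
#'   `truth` (ground_truth).
#' @export
generate_study <- function(config, seed = config$seed,
                           dimensions = c("appealing", "curiosity",
                                          "wanting")) {
  validate_sim_config(config)
  dims <- match.arg(dimensions, several.ok = TRUE)
  truth <- draw_ground_truth(config, derive_seed(seed, "latent"))
  beh <- simulate_behavior(config, truth, derive_seed(seed, "behavior"))
  times <- make_times(config$epoch_span, config$sampling_rate)
  labels <- channel_labels(config$n_channels)

  datasets <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    pid <- rownames(truth$latent_appeal)[p]
    rows <- beh$responses[beh$responses$participant == pid &
                            beh$responses$dimension %in% dims, ]
    set.seed(derive_seed(seed, "trials", p))
    ord <- sample.int(nrow(rows))
    rows <- rows[ord, ]
    n_tr <- nrow(rows)
    trials <- data.frame(
      image_id = rows$image_id,
      dimension = rows$dimension,
      response = rows$response,
      rating = rows$rating,
      response_side = sample(c("left", "right"), n_tr, replace = TRUE),
      rejected = FALSE,
      stringsAsFactors = FALSE
    )
    v <- simulate_noise_epochs(n_tr, config, derive_seed(seed, "noise", p))
    if (config$signal_amplitude != 0) {
      amps <- truth$amplitude[p, trials$image_id]
      v <- inject_signal(v, amps, config$spatial_pattern,
                         config$signal_window, times, config$envelope)
      if (config$early_amplitude_frac > 0)
        v <- inject_signal(v, amps * config$early_amplitude_frac,
                           config$spatial_pattern, config$early_window,
                           times, config$envelope)
    }
    datasets[[p]] <- epoched_dataset(
      participant_id = pid, voltages = v, times = times,
      channel_labels = labels, sampling_rate = config$sampling_rate,
      trials = trials, group = as.character(truth$groups)[p]
    )
  }
  list(datasets = datasets, behavior = beh$table,
       responses = beh$responses, truth = truth)
}
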