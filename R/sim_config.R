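#' Simulation configuration
#'
#' Holds the study-design constants of the emulated experiment: 38
#' participants split 12/16/10 into never / currently / past-vaping groups,
#' 120 product images probed on three question dimensions (360 trials), 64
#' recording channels at 512 Hz, epochs spanning -100..1000 ms around image
#' onset. The decodable signal is injected in a sustained late component
#' (440-860 ms, full amplitude) and a weaker early component (100-300 ms,
#' `early_amplitude_frac` of the amplitude), both riding on spatially
#' correlated pink noise plus white sensor noise.
#'
#' @param n_participants number of simulated participants.
#' @param group_sizes named integer triple `(never, current, past)`; must
#'   sum to `n_participants`.
#' @param n_images distinct product images; each appears once per
#'   dimension, so trials per participant = `3 * n_images`.
#' @param n_channels EEG channels.
#' @param sampling_rate Hz.
#' @param epoch_span epoch limits in ms relative to image onset, half-open
#'   `[start, end)`.
#' @param signal_window late signal component interval, ms.
#' @param early_window early (weak) signal component interval, ms.
#' @param signal_amplitude injected microvolts per unit of standardized
#'   latent appeal. The late component uses the full amplitude, the early
#'   component `early_amplitude_frac` of it. Zero disables injection.
#' @param early_amplitude_frac relative strength of the early component.
#' @param spatial_pattern per-channel weight vector with unit Euclidean
#'   norm; `NULL` uses [default_spatial_pattern()].
#' @param noise_sd per-channel ongoing-noise standard deviation, microvolts.
#' @param pink_exponent spectral exponent of the 1/f^a noise component.
#' @param pink_frac fraction of noise variance carried by the spatially
#'   correlated pink component (the remainder is white sensor noise).
#' @param channel_corr neighbour correlation of the pink component across
#'   the channel index (AR(1)-type decay).
#' @param envelope temporal envelope of the injected components.
#' @param behavior_params list of behavioral-generator constants, see
#'   Details.
#' @param seed default master seed used by [generate_study()].
#'
#' @details `behavior_params` fields (all on the standardized latent-appeal
#' scale unless noted): `group_mean` -- named means for never / current /
#' past groups, ordered current > past >= never by default; `participant_sd`,
#' `image_sd` -- random-effect SDs; `yes_intercept`, `yes_slope` -- logistic
#' model of a Yes response; `rating_intercept`, `rating_slope`,
#' `rating_noise_sd` -- affine map of latent appeal to the 0-100 rating
#' scale, noise added before clipping; `p_missing` -- probability of no
#' button press (response recorded as `"none"`). Defaults are calibrated so
#' seeded studies qualitatively reproduce the behavioral group structure:
#' currently-vaping participants give the most Yes responses and the
#' highest ratings, never-vaped the fewest/lowest.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 38,
                       group_sizes = c(never = 12, current = 16, past = 10),
                       n_images = 120,
                       n_channels = 64,
                       sampling_rate = 512,
                       epoch_span = c(-100, 1000),
                       signal_window = c(440, 860),
                       early_window = c(100, 300),
                       signal_amplitude = 1.5,
                       early_amplitude_frac = 0.4,
                       spatial_pattern = NULL,
                       noise_sd = 10,
                       pink_exponent = 1.0,
                       pink_frac = 0.8,
                       channel_corr = 0.6,
                       envelope = c("halfcosine", "boxcar"),
                       behavior_params = list(),
                       seed = 1L) {
  envelope <- match.arg(envelope)
  bp <- utils::modifyList(list(
    group_mean     = c(never = -1.0, current = 0.6, past = -0.55),
    participant_sd = 0.35,
    image_sd       = 0.5,
    yes_intercept  = -0.8,
    yes_slope      = 1.1,
    rating_intercept = 35,
    rating_slope     = 28,
    rating_noise_sd  = 10,
    p_missing        = 0
  ), behavior_params)

  cfg <- list(
    n_participants = as.integer(n_participants),
    group_sizes = group_sizes, n_images = as.integer(n_images),
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    epoch_span = epoch_span, signal_window = signal_window,
    early_window = early_window, signal_amplitude = signal_amplitude,
    early_amplitude_frac = early_amplitude_frac,
    spatial_pattern = spatial_pattern %||% default_spatial_pattern(n_channels),
    noise_sd = noise_sd, pink_exponent = pink_exponent,
    pink_frac = pink_frac, channel_corr = channel_corr,
    envelope = envelope, behavior_params = bp, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 1 || cfg$n_images < 1 || cfg$n_channels < 1)
    stop_invalid("n_participants, n_images and n_channels must be positive")
  if (length(cfg$group_sizes) != 3 || any(cfg$group_sizes < 0))
    stop_invalid("group_sizes must be a non-negative triple (never, current, past)")
  if (sum(cfg$group_sizes) != cfg$n_participants)
    stop_invalid("group_sizes must sum to n_participants (%d != %d)",
                 sum(cfg$group_sizes), cfg$n_participants)
  if (cfg$noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (cfg$pink_frac < 0 || cfg$pink_frac > 1)
    stop_invalid("pink_frac must lie in [0, 1]")
  within_span <- function(w)
    w[1] >= cfg$epoch_span[1] && w[2] <= cfg$epoch_span[2] && w[1] < w[2]
  if (!within_span(cfg$signal_window))
    stop_invalid("signal_window must lie within epoch_span")
  if (!within_span(cfg$early_window))
    stop_invalid("early_window must lie within epoch_span")
  if (length(cfg$spatial_pattern) != cfg$n_channels)
    stop_invalid("spatial_pattern length must equal n_channels")
  nrm <- sqrt(sum(cfg$spatial_pattern^2))
  if (abs(nrm - 1) > 1e-6)
    stop_invalid("spatial_pattern must have unit Euclidean norm (got %.4f)", nrm)
  gm <- cfg$behavior_params$group_mean
  if (!all(c("never", "current", "past") %in% names(gm)))
    stop_invalid("behavior_params$group_mean needs never/current/past entries")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d participants (never/current/past = %s), %d images x 3 dimensions\n",
              x$n_participants, paste(x$group_sizes, collapse = "/"),
              x$n_images))
  cat(sprintf("  %d channels @ %g Hz, epochs [%g, %g) ms\n",
              x$n_channels, x$sampling_rate, x$epoch_span[1], x$epoch_span[2]))
  cat(sprintf("  signal %g uV/latent-unit in [%g, %g) ms (+%g x in [%g, %g) ms), noise sd %g uV\n",
              x$signal_amplitude, x$signal_window[1], x$signal_window[2],
              x$early_amplitude_frac, x$early_window[1], x$early_window[2],
              x$noise_sd))
  invisible(x)
}
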