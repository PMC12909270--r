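# Fixture builders shared across the suite. Everything is generated in
# code at test time; sizes are kept small so the full suite stays fast.

# a compact simulation config: few participants, short epochs, few channels
tiny_config <- function(n_participants = 4,
                        group_sizes = c(never = 1, current = 2, past = 1),
                        n_images = 20, n_channels = 8,
                        epoch_span = c(-100, 300),
                        signal_window = c(100, 260),
                        early_window = c(-50, 50),
                        signal_amplitude = 0, noise_sd = 10, seed = 1, ...) {
  sim_config(n_participants = n_participants, group_sizes = group_sizes,
             n_images = n_images, n_channels = n_channels,
             epoch_span = epoch_span, signal_window = signal_window,
             early_window = early_window,
             signal_amplitude = signal_amplitude, noise_sd = noise_sd,
             seed = seed, ...)
}

# an epoched dataset with hand-specified voltages (trials x channels x samples)
manual_dataset <- function(voltages, sampling_rate = 512,
                           span = c(-100, 100),
                           dimension = "appealing", responses = NULL,
                           ratings = NULL) {
  d <- dim(voltages)
  times <- make_times(span, sampling_rate)
  stopifnot(length(times) == d[3])
  n <- d[1]
  trials <- data.frame(
    image_id = sprintf("img%03d", seq_len(n)),
    dimension = rep_len(dimension, n),
    response = responses %||% rep_len(c("yes", "no"), n),
    rating = ratings %||% rep_len(c(10L, 90L), n),
    response_side = rep_len(c("left", "right"), n),
    rejected = FALSE, stringsAsFactors = FALSE)
  epoched_dataset("T01", voltages, times, channel_labels(d[2]),
                  sampling_rate, trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two well-separated Gaussian point clouds for classifier checks
separable_features <- function(n_per_class = 30, n_features = 4,
                               sep = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * n_features, -sep, sd), n_per_class),
             matrix(rnorm(n_per_class * n_features, sep, sd), n_per_class))
  list(X = X, y = rep(c("no", "yes"), each = n_per_class))
}
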