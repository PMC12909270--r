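#' Epoched EEG dataset for one participant
#'
#' The package's central container: a `trials x channels x samples` voltage
#' array (microvolts) with a uniform time axis in ms relative to stimulus
#' onset, fixed channel labels, and one metadata row per trial (image,
#' question dimension, Yes/No/none response, 0-100 rating, response side,
#' rejection flag). Channel order is the label order and is never
#' rearranged.
#'
#' @param participant_id character scalar.
#' @param voltages numeric array `trials x channels x samples`.
#' @param times per-sample times, ms; strictly increasing, uniform spacing
#'   `1000 / sampling_rate`.
#' @param channel_labels character vector matching dim 2.
#' @param sampling_rate Hz.
#' @param trials data.frame with columns `image_id`, `dimension`,
#'   `response`, `rating`, `response_side`, `rejected`; one row per trial.
#' @param group optional participant-level group label (vaping status).
#' @param baseline_corrected logical flag.
#' @return object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(participant_id, voltages, times, channel_labels,
                            sampling_rate, trials, group = NA_character_,
                            baseline_corrected = FALSE) {
  d <- dim(voltages)
  if (length(d) != 3) stop_invalid("voltages must be trials x channels x samples")
  if (nrow(trials) != d[1])
    stop_invalid("trials has %d rows but voltages has %d trials", nrow(trials), d[1])
  if (length(channel_labels) != d[2])
    stop_invalid("%d channel labels for %d channels", length(channel_labels), d[2])
  if (length(times) != d[3])
    stop_invalid("%d time points for %d samples", length(times), d[3])
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1000 / sampling_rate)) > 1e-6))
    stop_invalid("times must increase uniformly at 1000/sampling_rate ms")
  need <- c("image_id", "dimension", "response", "rating", "response_side",
            "rejected")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop_invalid("trials lacks columns: %s",
                                 paste(miss, collapse = ", "))
  bad <- setdiff(unique(trials$dimension),
                 c("appealing", "curiosity", "wanting"))
  if (length(bad)) stop_invalid("unknown dimension label(s): %s",
                                paste(bad, collapse = ", "))
  structure(list(participant_id = participant_id, voltages = voltages,
                 times = times, channel_labels = channel_labels,
                 sampling_rate = sampling_rate, trials = trials,
                 group = group, baseline_corrected = baseline_corrected),
            class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$voltages)
  cat(sprintf("<epoched_dataset> %s: %d trials x %d channels x %d samples, [%.1f, %.1f] ms @ %g Hz\n",
              x$participant_id, d[1], d[2], d[3],
              x$times[1], x$times[length(x$times)], x$sampling_rate))
  cat(sprintf("  baseline-corrected: %s; rejected trials: %d; group: %s\n",
              x$baseline_corrected, sum(x$trials$rejected), x$group))
  invisible(x)
}

#' Subtract the pre-stimulus baseline
#'
#' Per trial and channel, subtracts the mean voltage over the baseline
#' interval (default the 100-ms pre-stimulus period) from the whole epoch.
#' Applying it twice is an error.
#'
#' @param ds an [epoched_dataset].
#' @param baseline `[start, end)` interval in ms.
#' @return the corrected dataset with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(ds, baseline = c(-100, 0)) {
  stopifnot(inherits(ds, "epoched_dataset"))
  if (isTRUE(ds$baseline_corrected))
    stop_invalid("dataset is already baseline-corrected")
  idx <- ms_to_samples(ds$times, baseline)
  if (length(idx) == 0)
    stop_invalid("baseline [%g, %g) contains no samples", baseline[1], baseline[2])
  # mean over baseline samples, per trial x channel
  mu <- rowMeans(ds$voltages[, , idx, drop = FALSE], dims = 2)
  ds$voltages <- ds$voltages - array(mu, dim = dim(ds$voltages))
  ds$baseline_corrected <- TRUE
  ds
}

#' Reject epochs by absolute amplitude
#'
#' Marks `rejected = TRUE` for every trial whose absolute voltage exceeds
#' the threshold at any channel or sample (strictly greater: a sample at
#' exactly the threshold is kept). Already-rejected trials stay rejected.
#'
#' @param ds an [epoched_dataset]; by convention already
#'   baseline-corrected (rejection is applied after baseline subtraction in
#'   the pipeline).
#' @param threshold microvolts, positive.
#' @return list with `dataset` (flags updated) and `report` (data.frame:
#'   participant_id, n_trials, n_rejected).
#' @export
reject_amplitude <- function(ds, threshold = 150) {
  stopifnot(inherits(ds, "epoched_dataset"))
  if (threshold <= 0) stop_invalid("threshold must be positive")
  a <- matrix(abs(ds$voltages), nrow = dim(ds$voltages)[1])
  mx <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  ds$trials$rejected <- ds$trials$rejected | (mx > threshold)
  list(dataset = ds,
       report = data.frame(participant_id = ds$participant_id,
                           n_trials = nrow(ds$trials),
                           n_rejected = sum(ds$trials$rejected),
                           stringsAsFactors = FALSE))
}

#' Select trials of one question dimension
#'
#' Returns a view of the dataset restricted to one dimension, preserving
#' trial order, optionally dropping rejected trials and trials without a
#' button press.
#'
#' @param ds an [epoched_dataset].
#' @param dimension `"appealing"`, `"curiosity"` or `"wanting"`.
#' @param drop_rejected drop trials flagged by [reject_amplitude()].
#' @param drop_missing drop trials with `response == "none"`.
#' @return an [epoched_dataset] with the selected trials (possibly zero).
#' @export
select_trials <- function(ds, dimension,
                          drop_rejected = TRUE, drop_missing = FALSE) {
  stopifnot(inherits(ds, "epoched_dataset"))
  dimension <- match.arg(dimension, c("appealing", "curiosity", "wanting"))
  keep <- ds$trials$dimension == dimension
  if (drop_rejected) keep <- keep & !ds$trials$rejected
  if (drop_missing) keep <- keep & ds$trials$response != "none"
  ds$voltages <- ds$voltages[keep, , , drop = FALSE]
  ds$trials <- ds$trials[keep, , drop = FALSE]
  rownames(ds$trials) <- NULL
  ds
}
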