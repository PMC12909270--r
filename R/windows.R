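#' Build the moving analysis-window grid
#'
#' Tiles the epoch (baseline period included) with consecutive
#' non-overlapping windows of `window_ms` duration. Each window spans
#' `floor(window_ms * sampling_rate / 1000)` samples (5 samples at the
#' default 10 ms / 512 Hz); a trailing partial window is dropped. The
#' representative time of a window is the mean of its member sample times.
#'
#' @param times per-sample time axis, ms.
#' @param sampling_rate Hz.
#' @param window_ms window duration, ms; at least one sample period.
#' @return object of class `window_grid`: `windows` (matrix `n x 2` of
#'   first/last sample indices), `times_ms`, `samples_per_window`,
#'   `n_windows`, `window_ms`.
#' @export
build_windows <- function(times, sampling_rate, window_ms = 10) {
  ns <- length(times)
  spw <- floor(window_ms * sampling_rate / 1000)
  if (spw < 1)
    stop_invalid("window_ms (%g) is shorter than one sample period", window_ms)
  if (spw > ns)
    stop_invalid("window (%d samples) longer than the epoch (%d samples)",
                 spw, ns)
  n_win <- floor(ns / spw)
  start <- (seq_len(n_win) - 1L) * spw + 1L
  windows <- cbind(start = start, end = start + spw - 1L)
  structure(list(windows = windows,
                 times_ms = vapply(seq_len(n_win), function(i)
                   mean(times[windows[i, 1]:windows[i, 2]]), numeric(1)),
                 samples_per_window = spw, n_windows = n_win,
                 window_ms = window_ms),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g ms (%d samples each), %.1f to %.1f ms\n",
              x$n_windows, x$window_ms, x$samples_per_window,
              x$times_ms[1], x$times_ms[x$n_windows]))
  invisible(x)
}

#' Extract the feature matrix for one analysis window
#'
#' Spatiotemporal mode (default): one feature per channel x in-window
#' sample, columns ordered channel-major (all samples of channel 1, then
#' channel 2, ...), so 64 channels x 5 samples give 320 features per
#' trial. Channel-mean mode averages the in-window samples per channel,
#' one feature per channel -- the lighter variant used for large
#' simulation batteries.
#'
#' @param ds an [epoched_dataset]; rejected and response-less trials must
#'   already have been excluded.
#' @param window length-2 integer: first and last sample index.
#' @param mode `"spatiotemporal"` or `"chanmean"`.
#' @return numeric matrix `trials x features`, baseline-corrected
#'   microvolts.
#' @export
extract_features <- function(ds, window, mode = c("spatiotemporal", "chanmean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "epoched_dataset"), length(window) == 2)
  d <- dim(ds$voltages)
  if (window[1] < 1 || window[2] > d[3] || window[1] > window[2])
    stop_invalid("window samples [%d, %d] outside epoch (1..%d)",
                 window[1], window[2], d[3])
  if (any(ds$trials$rejected) || any(ds$trials$response == "none"))
    stop_invalid("rejected or response-less trials must be excluded before feature extraction")
  a <- ds$voltages[, , window[1]:window[2], drop = FALSE]
  if (mode == "chanmean") {
    out <- rowMeans(a, dims = 2)
    colnames(out) <- ds$channel_labels
    return(out)
  }
  s <- dim(a)[3]
  # trials x samples x channels -> columns are (sample minor, channel major)
  x <- matrix(aperm(a, c(1, 3, 2)), nrow = d[1])
  colnames(x) <- paste(rep(ds$channel_labels, each = s),
                       rep(seq_len(s), times = d[2]), sep = ".")
  x
}
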