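#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the master seed plus a sequence of stage keys
#' (strings or integers), so that stages and windows can be re-run in any
#' order -- or in parallel -- with results identical to a serial run.
#'
#' @param seed master seed, a single integer.
#' @param ... stage keys: character scalars or integers. Order matters.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "decode", "svm", 12)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (k in list(...)) {
    if (is.character(k)) {
      ci <- utf8ToInt(k)
      k <- sum(ci * seq_along(ci))
    }
    h <- (h * 48271 + as.numeric(k) + 11) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a millisecond interval to sample indices
#'
#' Intervals are closed on the left and open on the right, matching the
#' epoch coordinate convention (sample 0 is the first sample at or after
#' the epoch start; onset t = 0 falls on the post-stimulus side).
#'
#' @param times numeric vector of per-sample times in ms.
#' @param interval length-2 numeric, `[start, end)` in ms.
#' @return integer vector of sample indices (1-based).
#' @keywords internal
ms_to_samples <- function(times, interval) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  which(times >= interval[1] & times < interval[2])
}

#' Time axis for an epoch span
#'
#' Samples sit on the grid k / sampling_rate with k integer; the epoch
#' `[start, end)` contains every grid point in that half-open interval.
#'
#' @param epoch_span length-2 numeric, ms.
#' @param sampling_rate Hz.
#' @return numeric vector of times in ms, strictly increasing, uniform.
#' @export
make_times <- function(epoch_span, sampling_rate) {
  stopifnot(length(epoch_span) == 2, epoch_span[1] < epoch_span[2],
            sampling_rate > 0)
  k0 <- ceiling(epoch_span[1] * sampling_rate / 1000 - 1e-9)
  k1 <- ceiling(epoch_span[2] * sampling_rate / 1000 - 1e-9) - 1
  if (k1 < k0) stop("epoch span shorter than one sample period")
  (k0:k1) * 1000 / sampling_rate
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
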