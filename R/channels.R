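#' Standard 64-channel montage labels
#'
#' Channel names of the common 64-electrode extended 10-20 layout, in the
#' fixed A1--A32 / B1--B32 head-cap ordering used throughout the package.
#' Channel order is never rearranged after construction.
#'
#' @return character vector of length 64.
#' @export
montage64 <- function() {
  c("Fp1", "AF7", "AF3", "F1",  "F3",  "F5",  "F7",  "FT7",
    "FC5", "FC3", "FC1", "C1",  "C3",  "C5",  "T7",  "TP7",
    "CP5", "CP3", "CP1", "P1",  "P3",  "P5",  "P7",  "P9",
    "PO7", "PO3", "O1",  "Iz",  "Oz",  "POz", "Pz",  "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz",  "F2",  "F4",
    "F6",  "F8",  "FT8", "FC6", "FC4", "FC2", "FCz", "Cz",
    "C2",  "C4",  "C6",  "T8",  "TP8", "CP6", "CP4", "CP2",
    "P2",  "P4",  "P6",  "P8",  "P10", "PO8", "PO4", "O2")
}

#' Channel labels for an n-channel montage
#'
#' The full 64-channel montage when `n_channels == 64`, otherwise generic
#' `Ch01 ...` labels (reduced montages are used for desk-scale
#' simulations).
#' @param n_channels positive integer.
#' @return character vector of length `n_channels`.
#' @export
channel_labels <- function(n_channels) {
  if (n_channels == 64) montage64() else sprintf("Ch%02d", seq_len(n_channels))
}

#' Default unit-norm spatial pattern of the injected signal
#'
#' A smooth posterior-weighted pattern: a half-cosine bump over a block of
#' channels centred at three quarters of the channel list (occipito-parietal
#' electrodes in the 64-channel montage), with a weaker frontal bump at one
#' tenth of the list. Normalised to unit Euclidean norm; channels outside
#' the bumps carry exactly zero weight, which defines the ground-truth
#' signal channel set.
#'
#' @param n_channels number of channels.
#' @return numeric vector, unit norm, length `n_channels`.
#' @export
default_spatial_pattern <- function(n_channels) {
  stopifnot(n_channels >= 2)
  w <- numeric(n_channels)
  bump <- function(center, width, height) {
    idx <- seq(max(1, round(center - width / 2)),
               min(n_channels, round(center + width / 2)))
    u <- seq_along(idx) / (length(idx) + 1)
    w[idx] <<- w[idx] + height * sin(pi * u)
  }
  post_w <- max(2, round(n_channels / 8))
  bump(0.75 * n_channels, post_w, 1.0)
  if (n_channels >= 8) bump(0.10 * n_channels, max(2, post_w / 2), 0.5)
  w / sqrt(sum(w^2))
}
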