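#' Write an epoched dataset to an on-disk container
#'
#' The container is a directory holding `header.json` (all metadata: ids,
#' channel labels, sampling rate, time axis, per-trial metadata, flags and
#' array dimensions) and `voltages.bin`, little-endian 32-bit floats in
#' trials-major, channels-middle, samples-minor order. Reading back yields
#' the stored values exactly; note that storage is single precision, so a
#' double-precision array is reproduced to float32 resolution on the first
#' write and bit-exactly from then on.
#'
#' @param ds an [epoched_dataset].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_container <- function(ds, path) {
  stopifnot(inherits(ds, "epoched_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ds$voltages)
  header <- list(
    format = "erpdecode-epochs", version = 1L,
    participant_id = ds$participant_id, group = ds$group,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    channel_labels = ds$channel_labels, sampling_rate = ds$sampling_rate,
    times = ds$times, baseline_corrected = ds$baseline_corrected,
    trials = ds$trials
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  con <- file(file.path(path, "voltages.bin"), "wb")
  on.exit(close(con))
  # samples fastest, then channels, then trials
  writeBin(as.vector(aperm(ds$voltages, c(3, 2, 1))), con,
           size = 4L, endian = "little")
  invisible(path)
}

#' Read an epoched dataset container
#'
#' @param path directory written by [write_container()].
#' @return an [epoched_dataset].
#' @export
read_container <- function(path) {
  hf <- file.path(path, "header.json")
  bf <- file.path(path, "voltages.bin")
  if (!file.exists(hf)) stop_invalid("missing container header: %s", hf)
  if (!file.exists(bf)) stop_invalid("missing container binary: %s", bf)
  h <- jsonlite::read_json(hf, simplifyVector = TRUE)
  if (!identical(h$format, "erpdecode-epochs"))
    stop_invalid("corrupt container: unrecognized header format in %s", hf)
  n <- as.integer(c(h$n_trials, h$n_channels, h$n_samples))
  expected <- prod(n) * 4
  actual <- file.info(bf)$size
  if (is.na(actual) || actual != expected)
    stop_invalid("corrupt container: %s holds %s bytes, header implies %d",
                 bf, format(actual), expected)
  con <- file(bf, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = prod(n), size = 4L,
               endian = "little")
  voltages <- aperm(array(v, dim = rev(n)), c(3, 2, 1))
  trials <- as.data.frame(h$trials, stringsAsFactors = FALSE)
  trials$rating <- as.integer(trials$rating)
  epoched_dataset(participant_id = h$participant_id, voltages = voltages,
                  times = as.numeric(h$times),
                  channel_labels = as.character(h$channel_labels),
                  sampling_rate = h$sampling_rate, trials = trials,
                  group = h$group %||% NA_character_,
                  baseline_corrected = isTRUE(h$baseline_corrected))
}

#' Export trial metadata as CSV
#'
#' One row per trial with the participant id and group prepended; the
#' behavioral arm consumes these files.
#'
#' @param ds an [epoched_dataset].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_trial_csv <- function(ds, file) {
  df <- cbind(participant = ds$participant_id, group = ds$group, ds$trials,
              stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
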