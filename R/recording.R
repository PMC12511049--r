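#' Multichannel EEG recording container
#'
#' A `Recording` holds a continuous multichannel potential matrix together
#' with its sampling rate and channel metadata. Channel kinds distinguish
#' scalp EEG channels from ocular (EOG) channels so that the latter can be
#' excluded before connectivity analysis.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling frequency in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel.
#' @param channel_kinds character vector of `"EEG"`/`"EOG"`, one per channel.
#'   Defaults to all `"EEG"`.
#' @param subject_id subject identifier.
#' @param sensor_positions optional numeric matrix (channels x 2) of 2-D
#'   layout coordinates, used only for plotting.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channel_labels,
                          channel_kinds = rep("EEG", nrow(samples)),
                          subject_id = "subject",
                          sensor_positions = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive scalar (Hz)")
  if (length(channel_labels) != nrow(samples))
    stop("`channel_labels` length (", length(channel_labels),
         ") must equal channel count (", nrow(samples), ")")
  channel_kinds <- match.arg(channel_kinds, c("EEG", "EOG"), several.ok = TRUE)
  if (length(channel_kinds) != nrow(samples))
    stop("`channel_kinds` must have one entry per channel")
  if (sum(channel_kinds == "EEG") < 2L)
    stop("a recording needs at least 2 EEG channels")
  if (!is.null(sensor_positions)) {
    sensor_positions <- as.matrix(sensor_positions)
    if (nrow(sensor_positions) != nrow(samples) || ncol(sensor_positions) != 2L)
      stop("`sensor_positions` must be a channels x 2 matrix")
  }
  rownames(samples) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id),
         samples = samples,
         rate = rate,
         channel_labels = as.character(channel_labels),
         channel_kinds = channel_kinds,
         sensor_positions = sensor_positions),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n_eog <- sum(x$channel_kinds == "EOG")
  cat(sprintf("<eeg_recording> subject '%s': %d channels (%d EOG), %.6g s at %g Hz\n",
              x$subject_id, nrow(x$samples), n_eog,
              ncol(x$samples) / x$rate, x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return numeric scalar.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$rate

#' Epoched EEG container
#'
#' An `EpochSet` holds fixed-length, artifact-screened segments of a
#' recording as an epoch x channel x time array. All epochs have identical
#' length `epoch_duration * rate`.
#'
#' @param epochs numeric array epoch x channel x time (microvolts).
#' @param rate sampling frequency (Hz).
#' @param epoch_duration epoch length in seconds.
#' @param channel_labels channel labels (analysis channels only).
#' @param subject_id subject identifier.
#' @param dropped integer indices of epochs removed by artifact screening
#'   (bookkeeping only).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, rate, epoch_duration, channel_labels,
                       subject_id = "subject", dropped = integer(0)) {
  if (length(dim(epochs)) != 3L)
    stop("`epochs` must be a 3-d array: epoch x channel x time")
  if (dim(epochs)[3] != round(epoch_duration * rate))
    stop("epoch length (", dim(epochs)[3], " samples) does not match ",
         "epoch_duration * rate = ", round(epoch_duration * rate))
  if (dim(epochs)[2] != length(channel_labels))
    stop("`channel_labels` must have one entry per channel")
  structure(
    list(subject_id = as.character(subject_id),
         epochs = epochs,
         rate = rate,
         epoch_duration = epoch_duration,
         channel_labels = as.character(channel_labels),
         dropped = as.integer(dropped)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> subject '%s': %d epochs x %d channels x %d samples (%g s at %g Hz), %d dropped\n",
              x$subject_id, d[1], d[2], d[3], x$epoch_duration, x$rate,
              length(x$dropped)))
  invisible(x)
}

#' Number of epochs
#' @param es an `eeg_epochs` object.
#' @return integer scalar.
#' @export
n_epochs <- function(es) dim(es$epochs)[1]
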