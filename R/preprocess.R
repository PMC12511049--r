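# Preprocessing chain: drop EOG -> average reference -> broad band-pass ->
# downsample -> per-band band-pass -> epoch -> amplitude-based rejection.

#' Drop ocular channels
#'
#' Removes all channels whose kind is `EOG`, preserving channel order. With
#' the default 64-electrode montage (62 scalp + 2 ocular) this leaves the 62
#' analysis channels.
#'
#' @param rec an [eeg_recording()].
#' @return an [eeg_recording()] containing only EEG-kind channels.
#' @export
drop_eog <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- rec$channel_kinds == "EEG"
  if (all(keep)) return(rec)
  eeg_recording(rec$samples[keep, , drop = FALSE], rate = rec$rate,
                channel_labels = rec$channel_labels[keep],
                channel_kinds = rec$channel_kinds[keep],
                subject_id = rec$subject_id,
                sensor_positions = rec$sensor_positions[keep, , drop = FALSE])
}

#' Re-reference to the global average
#'
#' Subtracts, at every time sample, the instantaneous mean across EEG
#' channels. Afterwards the cross-channel mean is zero; the operation is
#' idempotent and removes any common-mode (reference) signal.
#'
#' @param rec an [eeg_recording()] with at least 2 EEG channels.
#' @return re-referenced [eeg_recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  eeg <- rec$channel_kinds == "EEG"
  if (sum(eeg) < 2L) stop("average reference requires at least 2 EEG channels")
  m <- colMeans(rec$samples[eeg, , drop = FALSE])
  out <- rec
  out$samples[eeg, ] <- sweep(rec$samples[eeg, , drop = FALSE], 2L, m)
  out
}

# Hamming-windowed linear-phase FIR band-pass. The window method gives
# approximately unity passband gain and ~53 dB stop-band attenuation; the
# -6 dB points sit at the stated cutoffs.
fir_bandpass_taps <- function(low, high, rate, transition) {
  ntaps <- ceiling(3.3 * rate / transition)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- (ntaps - 1L) / 2L
  k <- seq(-m, m)
  fl <- low / rate; fh <- high / rate
  h <- ifelse(k == 0L, 2 * (fh - fl),
              (sin(2 * pi * fh * k) - sin(2 * pi * fl * k)) / (pi * k))
  w <- 0.54 + 0.46 * cos(pi * k / m)    # Hamming
  h * w
}

# Zero-phase FIR filtering by FFT convolution with group-delay removal and
# reflection padding; output has the input's length.
apply_fir <- function(x, h) {
  ntaps <- length(h)
  m <- (ntaps - 1L) %/% 2L
  n <- ncol(x)
  pad <- min(m, n - 1L)
  L <- n + 2L * pad + ntaps - 1L
  nfft <- stats::nextn(L, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(nfft - ntaps)))
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(rev(xi[seq_len(pad) + 1L]), xi, rev(xi[n - seq_len(pad)]))
    X <- stats::fft(c(xp, numeric(nfft - length(xp))))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    out[i, ] <- y[(pad + m + 1L):(pad + m + n)]
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase (linear-phase FIR with group-delay compensation)
#' Hamming-windowed sinc band-pass to every channel. Pure tones well inside
#' the passband are preserved in amplitude; tones beyond the transition band
#' are attenuated by the window's ~53 dB stop-band.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; `0 < low < high < rate/2` required.
#' @param transition transition width in Hz (sets the filter order via the
#'   Hamming design rule). Default: `min(low, 2)` so that the broad 0.5 Hz
#'   high-pass edge remains sharp.
#' @return filtered [eeg_recording()].
#' @export
bandpass <- function(rec, low, high, transition = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stop("invalid band: need 0 < low < high")
  if (high >= rec$rate / 2)
    stop("band edge ", high, " Hz violates the Nyquist limit (",
         rec$rate / 2, " Hz)")
  if (is.null(transition)) transition <- min(low, 2)
  h <- fir_bandpass_taps(low, high, rec$rate, transition)
  out <- rec
  out$samples <- apply_fir(rec$samples, h)
  out
}

#' Downsample a recording
#'
#' Integer-factor decimation (every k-th sample) when `target_rate` divides
#' the rate evenly — safe under the default pipeline because the preceding
#' 0.5–48 Hz band-pass already removed everything above the new Nyquist.
#' Non-integer factors require `allow_resample = TRUE` and use Fourier-domain
#' resampling (spectral truncation).
#'
#' @param rec an [eeg_recording()].
#' @param target_rate new sampling rate (Hz), at most the current rate.
#' @param allow_resample permit non-integer decimation factors.
#' @return downsampled [eeg_recording()].
#' @export
downsample <- function(rec, target_rate, allow_resample = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate)
    stop("target rate ", target_rate, " exceeds the recording rate ", rec$rate)
  if (target_rate == rec$rate) return(rec)
  factor <- rec$rate / target_rate
  out <- rec
  if (abs(factor - round(factor)) < 1e-9) {
    idx <- seq(1L, ncol(rec$samples), by = as.integer(round(factor)))
    out$samples <- rec$samples[, idx, drop = FALSE]
  } else {
    if (!allow_resample)
      stop("target rate ", target_rate, " does not divide ", rec$rate,
           " evenly; set allow_resample = TRUE for Fourier resampling")
    n <- ncol(rec$samples)
    n_out <- floor(n * target_rate / rec$rate)
    out$samples <- t(apply(rec$samples, 1L, function(xi) {
      X <- stats::fft(xi)
      keep <- ceiling(n_out / 2)
      Y <- complex(n_out)
      Y[1:keep] <- X[1:keep]
      Y[(n_out - keep + 2):n_out] <- X[(n - keep + 2):n]
      # inverse transform of the truncated spectrum; 1/n keeps amplitudes
      Re(stats::fft(Y, inverse = TRUE)) / n
    }))
  }
  out$rate <- target_rate
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into non-overlapping consecutive epochs of `duration`
#' seconds; a trailing remainder shorter than one epoch is discarded.
#'
#' @param rec an [eeg_recording()] (EEG channels only).
#' @param duration epoch length in seconds (default 2).
#' @return an [eeg_epochs()] object.
#' @export
epoch_recording <- function(rec, duration = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(duration * rec$rate)
  n <- ncol(rec$samples)
  if (n < len)
    stop("recording (", n / rec$rate, " s) shorter than one ",
         duration, " s epoch")
  n_ep <- n %/% len
  keep <- rec$channel_kinds == "EEG"
  x <- rec$samples[keep, seq_len(n_ep * len), drop = FALSE]
  # channels x (time within epoch) x epoch -> epoch x channel x time
  arr <- array(x, dim = c(sum(keep), len, n_ep))
  eeg_epochs(aperm(arr, c(3, 1, 2)), rate = rec$rate,
             epoch_duration = duration,
             channel_labels = rec$channel_labels[keep],
             subject_id = rec$subject_id)
}

#' Reject high-amplitude epochs
#'
#' Automated surrogate for visual artifact screening: an epoch is rejected
#' when its peak-to-peak amplitude on any channel exceeds
#' `peak_to_peak_limit`. At least `min_epochs` epochs must survive.
#'
#' @param es an [eeg_epochs()] object.
#' @param peak_to_peak_limit rejection threshold in microvolts (default 100).
#' @param min_epochs minimum number of surviving epochs (default 40).
#' @return an [eeg_epochs()] with rejected epochs removed; dropped indices
#'   are recorded in `$dropped`.
#' @export
reject_epochs <- function(es, peak_to_peak_limit = 100, min_epochs = 40) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (n_epochs(es) == 0L) stop("empty epoch set")
  ptp <- apply(es$epochs, 1L, function(e) max(apply(e, 1L, function(ch)
    max(ch) - min(ch))))
  keep <- ptp <= peak_to_peak_limit
  if (sum(keep) < min_epochs)
    stop("quality error: subject '", es$subject_id, "' has only ", sum(keep),
         " artifact-free epochs (minimum ", min_epochs, ")")
  eeg_epochs(es$epochs[keep, , , drop = FALSE], rate = es$rate,
             epoch_duration = es$epoch_duration,
             channel_labels = es$channel_labels,
             subject_id = es$subject_id,
             dropped = c(es$dropped, which(!keep)))
}

#' Default preprocessing configuration
#'
#' @param broad_band broad filter edges in Hz (default 0.5–48).
#' @param target_rate analysis sampling rate (default 250 Hz).
#' @param epoch_duration epoch length in seconds (default 2).
#' @param peak_to_peak_limit rejection threshold in microvolts (default 100).
#' @param min_epochs minimum artifact-free epochs (default 40).
#' @param eog_labels ocular label list; see [default_eog_labels()].
#' @return a named list of configuration values.
#' @export
preprocess_config <- function(broad_band = c(0.5, 48), target_rate = 250,
                              epoch_duration = 2, peak_to_peak_limit = 100,
                              min_epochs = 40,
                              eog_labels = default_eog_labels()) {
  list(broad_band = broad_band, target_rate = target_rate,
       epoch_duration = epoch_duration,
       peak_to_peak_limit = peak_to_peak_limit, min_epochs = min_epochs,
       eog_labels = eog_labels)
}

#' Run the full preprocessing chain for one subject
#'
#' Applies, in fixed order: EOG removal, average re-referencing, broad
#' band-pass, downsampling, band-specific filtering on the continuous signal,
#' epoching, and amplitude-based rejection. Band filtering precedes epoching
#' so that filter edge effects do not contaminate the short 2 s windows.
#'
#' @param rec an [eeg_recording()].
#' @param bands a band table from [eeg_bands()] (name, low, high).
#' @param config a [preprocess_config()] list.
#' @return named list of [eeg_epochs()], one per band.
#' @export
preprocess_recording <- function(rec, bands = eeg_bands(),
                                 config = preprocess_config()) {
  rec <- drop_eog(rec)
  rec <- rereference_average(rec)
  rec <- bandpass(rec, config$broad_band[1], config$broad_band[2])
  rec <- downsample(rec, config$target_rate)
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    bp <- bandpass(rec, bands$low[i], bands$high[i])
    es <- epoch_recording(bp, config$epoch_duration)
    out[[i]] <- reject_epochs(es, config$peak_to_peak_limit,
                              config$min_epochs)
  }
  out
}
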