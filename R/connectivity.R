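#' The five classical EEG frequency bands
#'
#' Delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 and gamma 30–48 Hz.
#'
#' @param names optional subset of band names to return.
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function(names = NULL) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0.5, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 48),
    stringsAsFactors = FALSE)
  if (!is.null(names)) {
    miss <- setdiff(names, b$name)
    if (length(miss)) stop("unknown band(s): ", paste(miss, collapse = ", "))
    b <- b[match(names, b$name), , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

# analytic signal of a real vector by the FFT method: zero the negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited epochs
#'
#' Computes the angle of the analytic signal (Hilbert transform) of every
#' channel in every epoch. The input must already be band-limited to a single
#' frequency band. A fraction of samples at each epoch edge is flagged for
#' exclusion from downstream PLI averaging, to suppress transform edge
#' effects.
#'
#' @param es an [eeg_epochs()] object, band-limited.
#' @param edge_fraction fraction of samples flagged at each epoch boundary
#'   (default 0.05).
#' @return an object of class `eeg_phases` with elements `phases` (epoch x
#'   channel x time array, radians in (-pi, pi]), `retain` (logical time
#'   index of samples kept for averaging), `degenerate` (epoch x channel
#'   logical marking zero-variance channels), and the channel labels.
#' @export
instantaneous_phase <- function(es, edge_fraction = 0.05) {
  stopifnot(inherits(es, "eeg_epochs"))
  d <- dim(es$epochs)
  n_t <- d[3]
  n_edge <- floor(edge_fraction * n_t)
  if (n_t <= 2L * n_edge)
    stop("epoch length (", n_t, " samples) is not larger than twice the ",
         "edge-exclusion window (", n_edge, " samples per side)")
  # batch analytic signal: one multi-column FFT over all epoch x channel
  # traces (time in rows)
  X <- matrix(aperm(es$epochs, c(3, 1, 2)), nrow = n_t)
  v <- colMeans(X^2) - colMeans(X)^2
  degenerate <- matrix(v < (.Machine$double.eps * 1e3)^2, d[1], d[2])
  h <- numeric(n_t)
  if (n_t %% 2L == 0L) {
    h[c(1L, n_t / 2L + 1L)] <- 1
    h[2:(n_t / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n_t + 1L) / 2L)] <- 2
  }
  A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / n_t
  if (any(degenerate)) A[, which(degenerate)] <- 0   # undefined phase -> 0
  phases <- aperm(array(Arg(A), dim = c(n_t, d[1], d[2])), c(2, 3, 1))
  retain <- rep(TRUE, n_t)
  if (n_edge > 0L) retain[c(seq_len(n_edge), n_t - seq_len(n_edge) + 1L)] <- FALSE
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance channel-epoch(s) flagged; ",
            "affected epochs are skipped for pairs involving those channels")
  structure(list(phases = phases, retain = retain, degenerate = degenerate,
                 channel_labels = es$channel_labels,
                 subject_id = es$subject_id),
            class = "eeg_phases")
}

#' Phase Lag Index connectivity matrix
#'
#' For each channel pair the PLI is the absolute value of the time-average of
#' `sign(sin(phase difference))`, computed per epoch over the retained
#' (non-edge) samples and then averaged across epochs. `sign(0)` is 0, so
#' identical (zero-lag) signals yield PLI exactly 0 — the volume-conduction
#' insensitivity that motivates the index. Values range from 0 (no coupling)
#' to 1 (perfect phase locking at a consistent nonzero lag).
#'
#' @param ph an `eeg_phases` object from [instantaneous_phase()].
#' @param band optional band name or one-row band table attached to the
#'   result for bookkeeping.
#' @param pool_samples if `TRUE`, pool all retained samples across epochs
#'   into a single average instead of averaging per-epoch PLIs.
#' @return an object of class `pli_matrix`: list with `values` (symmetric
#'   channel x channel matrix, zero diagonal), `channel_labels`, `band`,
#'   `n_epochs`.
#' @export
pli_matrix <- function(ph, band = NULL, pool_samples = FALSE) {
  stopifnot(inherits(ph, "eeg_phases"))
  d <- dim(ph$phases)
  n_ep <- d[1]; n_ch <- d[2]
  if (n_ep < 1L) stop("need at least 1 epoch")
  if (n_ch < 2L) stop("need at least 2 channels")
  keep_t <- which(ph$retain)
  n_t <- length(keep_t)

  # stack epochs: (epoch*time) x channel matrices of cos/sin of the phase;
  # the pairwise sign(sin(phase difference)) accumulation runs in compiled
  # code (sign(sin(a-b)) = sign(sin_a cos_b - cos_a sin_b))
  P <- matrix(aperm(ph$phases[, , keep_t, drop = FALSE], c(3, 1, 2)),
              nrow = n_ep * n_t, ncol = n_ch)
  vals <- .pli_accumulate(sin(P), cos(P), n_ep, n_t, ph$degenerate,
                          pool_samples)
  dimnames(vals) <- list(ph$channel_labels, ph$channel_labels)
  if (is.data.frame(band)) band <- band$name[1]
  structure(list(values = vals, channel_labels = ph$channel_labels,
                 band = band, n_epochs = n_ep,
                 subject_id = ph$subject_id),
            class = "pli_matrix")
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf("<pli_matrix> %d channels, band %s, %d epochs, mean PLI %.4f\n",
              nrow(x$values), x$band %||% "?", x$n_epochs, mean_pli(x)))
  invisible(x)
}

#' Mean PLI across all channel pairs
#'
#' Arithmetic mean over the strict upper triangle — the global
#' synchronization summary per band.
#'
#' @param cm a `pli_matrix` (or a plain symmetric matrix).
#' @return numeric scalar in \[0, 1\].
#' @export
mean_pli <- function(cm) {
  v <- if (inherits(cm, "pli_matrix")) cm$values else as.matrix(cm)
  if (nrow(v) < 2L) stop("need at least 2 channels")
  mean(v[upper.tri(v)])
}

#' Write a connectivity matrix as CSV with a JSON sidecar
#'
#' @param cm a `pli_matrix`.
#' @param path output CSV path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "pli_matrix"))
  utils::write.csv(as.data.frame(cm$values), path, row.names = TRUE)
  jsonlite::write_json(
    list(subject_id = cm$subject_id, band = cm$band, n_epochs = cm$n_epochs,
         n_channels = length(cm$channel_labels)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#' @param path CSV path.
#' @return a `pli_matrix`.
#' @export
read_connectivity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  v <- as.matrix(df)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json")) else list()
  structure(list(values = v, channel_labels = rownames(v),
                 band = meta$band %||% NULL,
                 n_epochs = meta$n_epochs %||% NA_integer_,
                 subject_id = meta$subject_id %||% NA_character_),
            class = "pli_matrix")
}
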