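# European Data Format (EDF), 16-bit standard: fixed-width ASCII header of
# 256 + 256*ns bytes, then data records of little-endian int16 samples,
# signal-sequential within each record.

edf_field <- function(x, width) {
  s <- formatC(as.character(x)[1], width = -width)
  substr(s, 1L, width)
}

edf_num <- function(x, width) {
  # shortest decimal representation that fits the fixed-width field
  for (digits in seq(8L, 0L)) {
    s <- formatC(x, format = "f", digits = digits)
    s <- sub("\\.?0+$", "", s)
    if (nchar(s) <= width) return(edf_field(s, width))
  }
  stop("numeric value ", x, " does not fit in ", width, " EDF header bytes")
}

#' Write a recording to an EDF file
#'
#' Writes standard 16-bit EDF with one-second data records. The recording is
#' truncated to a whole number of seconds (EDF records must tile evenly).
#' Channel kinds are not stored in EDF; EOG channels are recovered on read
#' from their labels (see [read_recording()]).
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% rate
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$samples[, seq_len(n_rec * rate), drop = FALSE]

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$subject_id, 80),
    edf_field("eegmst", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 + 256 * ns, 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(ns, 4),
    paste(vapply(rec$channel_labels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(rate, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeBin(charToRaw(hdr), con)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    dig <- round((x[, idx, drop = FALSE] - pmin) * scale + dmin)
    # byrow: signal-sequential within the record
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, eog_labels) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("EDF format error: file shorter than the 256-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", 256L)
  take <- function(raw, from, len) {
    trimws(rawToChar(raw[from:(from + len - 1L)]))
  }
  ns <- suppressWarnings(as.integer(take(raw_hdr, 253, 4)))
  n_rec <- suppressWarnings(as.integer(take(raw_hdr, 237, 8)))
  if (is.na(ns) || ns < 1L || is.na(n_rec))
    stop("EDF format error: unparseable header")
  hdr_bytes <- suppressWarnings(as.integer(take(raw_hdr, 185, 8)))
  if (is.na(hdr_bytes) || hdr_bytes != 256 + 256 * ns)
    stop("EDF format error: header byte count inconsistent with signal count")
  rec_dur <- suppressWarnings(as.numeric(take(raw_hdr, 245, 8)))
  subject_id <- take(raw_hdr, 9, 80)

  sig_hdr <- readBin(con, "raw", 256L * ns)
  if (length(sig_hdr) < 256L * ns) stop("EDF format error: truncated signal header")
  # cumulative field offsets within the signal header block:
  # label 16, transducer 80, physdim 8, physmin 8, physmax 8, digmin 8,
  # digmax 8, prefilter 80, samples-per-record 8
  off <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8))
  g <- function(k, width) vapply(seq_len(ns), function(i)
    take(sig_hdr, off[k] * ns + (i - 1L) * width + 1L, width), "")
  labels <- g(1, 16)
  pmin <- as.numeric(g(4, 8)); pmax <- as.numeric(g(5, 8))
  dmin <- as.numeric(g(6, 8)); dmax <- as.numeric(g(7, 8))
  spr  <- as.integer(g(9, 8))
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("EDF format error: unparseable signal header fields")
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only")
  rate <- spr[1] / rec_dur

  n_vals <- n_rec * sum(spr)
  dig <- readBin(con, "integer", n_vals, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dig) < n_vals) stop("EDF format error: truncated data records")
  # records x (signal-sequential samples) -> channels x time
  dim(dig) <- c(spr[1], ns, n_rec)
  x <- matrix(0, ns, spr[1] * n_rec)
  for (i in seq_len(ns)) x[i, ] <- as.vector(dig[, i, ])
  x <- (x - dmin) * (pmax - pmin) / (dmax - dmin) + pmin

  kinds <- ifelse(toupper(labels) %in% toupper(eog_labels), "EOG", "EEG")
  if (sum(kinds == "EEG") == 0L)
    stop("EDF content error: no EEG channels after EOG labelling")
  eeg_recording(x, rate = rate, channel_labels = labels,
                channel_kinds = kinds, subject_id = subject_id)
}
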