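# BrainVision triplet: INI-style .vhdr header, .vmrk marker file, and a raw
# binary .eeg payload (multiplexed, IEEE_FLOAT_32 or INT_16 with per-channel
# resolution).

parse_vhdr_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- gsub("[][]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

read_brainvision <- function(path, eog_labels) {
  if (!file.exists(path)) stop("BrainVision format error: header file not found")
  ini <- parse_vhdr_ini(readLines(path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chs <- ini[["Channel Infos"]]
  if (is.null(ci) || is.null(chs))
    stop("BrainVision format error: missing [Common Infos] or [Channel Infos]")
  if (!identical(toupper(ci$DataFormat %||% "BINARY"), "BINARY"))
    stop("BrainVision reader supports BINARY data only")
  if (!identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED"))
    stop("BrainVision reader supports MULTIPLEXED orientation only")
  nch <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)   # interval is in microseconds
  fmt <- toupper(bi$BinaryFormat %||% "IEEE_FLOAT_32")

  ord <- order(as.integer(sub("^Ch", "", names(chs))))
  chs <- chs[ord]
  info <- lapply(chs, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  labels <- vapply(info, `[`, "", 1)
  resolution <- vapply(info, function(v) {
    r <- suppressWarnings(as.numeric(v[3]))
    if (is.na(r)) 1 else r
  }, 0)
  if (length(labels) != nch)
    stop("BrainVision format error: channel count mismatch")

  data_file <- file.path(dirname(path), ci$DataFile)
  if (!file.exists(data_file))
    stop("BrainVision format error: data file '", ci$DataFile, "' not found")
  sz <- file.info(data_file)$size
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    n <- sz %/% 4L
    vals <- readBin(con, "numeric", n, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    n <- sz %/% 2L
    vals <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                    endian = "little")
  } else stop("BrainVision format error: unsupported BinaryFormat ", fmt)
  n_t <- length(vals) %/% nch
  x <- matrix(vals[seq_len(n_t * nch)], nrow = nch)   # multiplexed
  x <- x * resolution

  kinds <- ifelse(toupper(labels) %in% toupper(eog_labels), "EOG", "EEG")
  if (sum(kinds == "EEG") == 0L)
    stop("BrainVision content error: no EEG channels after EOG labelling")
  eeg_recording(x, rate = rate, channel_labels = labels,
                channel_kinds = kinds,
                subject_id = sub("\\.vhdr$", "", basename(path)))
}

#' Write a recording as a BrainVision triplet
#'
#' Emits `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` with multiplexed
#' IEEE_FLOAT_32 samples. Used by the fixture generator and round-trip tests.
#'
#' @param rec an [eeg_recording()].
#' @param stem output path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  nch <- nrow(rec$samples)
  vhdr <- paste0(stem, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(stem), ".eeg"),
    paste0("MarkerFile=", basename(stem), ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_labels)
  ), vhdr, useBytes = FALSE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(stem), ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  ), paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4L, endian = "little")
  invisible(vhdr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
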