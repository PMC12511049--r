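#' Default ocular channel labels
#'
#' Labels matched (case-insensitively) against channel names to mark EOG
#' channels. Covers common BrainVision ocular montages, including the
#' horizontal/vertical pair used with 64-channel caps.
#'
#' @return character vector of labels.
#' @export
default_eog_labels <- function() {
  c("HEOG", "VEOG", "EOG", "EOG1", "EOG2", "EOGH", "EOGV",
    "HEOGL", "HEOGR", "VEOGU", "VEOGL", "IO1", "IO2", "LO1", "LO2")
}

#' Read a raw EEG recording
#'
#' Reads an EDF (16-bit standard) or BrainVision (`.vhdr`/`.vmrk`/`.eeg`)
#' recording. Channel kinds are assigned by matching labels against
#' `eog_labels`.
#'
#' @param path path to the `.edf` file or the BrainVision `.vhdr` header.
#' @param format `"edf"` or `"brainvision"`; default guesses from the
#'   extension.
#' @param eog_labels labels treated as ocular channels;
#'   see [default_eog_labels()].
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision"),
                           eog_labels = default_eog_labels()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     stop("cannot guess format from extension '", ext,
                          "'; pass `format` explicitly"))
  }
  switch(format,
         edf = read_edf(path, eog_labels),
         brainvision = read_brainvision(path, eog_labels))
}

#' Read a subject metadata table
#'
#' Reads a delimited table with one row per subject. Required columns are
#' `subject_id` and `group`; `group` must be one of `HC`, `MCI-AD`, `AD`.
#' Optional columns (age, sex, education, clinical scores, CSF biomarkers)
#' are carried through unchanged.
#'
#' @param path CSV/TSV file path (delimiter guessed from the header line).
#' @return a data.frame with `group` as a factor with levels
#'   `HC`, `MCI-AD`, `AD`.
#' @export
read_subject_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("subject_id", "group")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("subject table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subject table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), group_levels())
  if (length(bad))
    stop("unrecognized group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(group_levels(), collapse = "/"), ")")
  df$group <- factor(df$group, levels = group_levels())
  num_cols <- setdiff(names(df), c("subject_id", "group", "sex"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.infinite(v), na.rm = TRUE))
      stop("non-finite value in column '", cl, "'")
    df[[cl]] <- v
  }
  df
}

#' Diagnostic group levels
#' @return `c("HC", "MCI-AD", "AD")`.
#' @export
group_levels <- function() c("HC", "MCI-AD", "AD")
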