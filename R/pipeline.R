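#' End-to-end analysis of one subject
#'
#' Runs preprocessing, phase extraction, PLI connectivity and MST metrics
#' for every requested band and returns the result in the long format
#' consumed by the group statistics and ROC modules.
#'
#' @param rec an [eeg_recording()].
#' @param bands band table from [eeg_bands()].
#' @param config a [preprocess_config()].
#' @param edge_fraction epoch-edge exclusion for phase averaging.
#' @return data.frame with columns `subject_id`, `band`, `metric`, `value`
#'   (8 metrics per band; see [metric_names()]).
#' @export
analyze_subject <- function(rec, bands = eeg_bands(),
                            config = preprocess_config(),
                            edge_fraction = 0.05) {
  per_band <- preprocess_recording(rec, bands, config)
  rows <- lapply(names(per_band), function(b) {
    ph <- instantaneous_phase(per_band[[b]], edge_fraction)
    cm <- pli_matrix(ph, band = b)
    tm <- metrics_for_subject(cm)
    data.frame(subject_id = rec$subject_id, band = b,
               metric = metric_names(),
               value = unlist(tm[metric_names()], use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analyze every subject of a synthetic cohort in memory
#'
#' Generates each planned subject, runs [analyze_subject()], and discards
#' the raw signals — the memory-friendly route for simulation studies.
#'
#' @param spec a [cohort_spec()].
#' @param bands band table (defaults to the spec's bands; pass a subset to
#'   save time).
#' @param config a [preprocess_config()].
#' @param plan optional precomputed [cohort_plan()].
#' @return data.frame in long format (as [analyze_subject()]), all subjects.
#' @export
analyze_cohort <- function(spec, bands = spec$bands,
                           config = preprocess_config(), plan = cohort_plan(spec)) {
  res <- lapply(seq_len(nrow(plan)), function(i) {
    rec <- generate_subject(spec, plan$group[i], plan$subject_seed[i],
                            subject_id = plan$subject_id[i])
    analyze_subject(rec, bands, config)
  })
  do.call(rbind, res)
}

#' Pivot long-format metrics to one feature column per (band, metric)
#'
#' Column names are `<band>_<metric>`, e.g. `beta_mean_pli` — the feature
#' identifiers used by the ROC module.
#'
#' @param metrics long-format table from [analyze_subject()].
#' @param subjects optional subject table merged in by `subject_id`.
#' @return wide data.frame, one row per subject.
#' @export
metrics_wide <- function(metrics, subjects = NULL) {
  metrics$feature <- paste(metrics$band, metrics$metric, sep = "_")
  wide <- stats::reshape(
    metrics[, c("subject_id", "feature", "value")],
    idvar = "subject_id", timevar = "feature", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  if (!is.null(subjects)) wide <- merge(subjects, wide, by = "subject_id")
  wide
}
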