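# Synthetic cohort generator. Signal model per subject: for every band a
# latent narrowband process (band-filtered white noise) is mixed into each
# channel with a channel-specific constant phase offset (rotation of the
# latent analytic signal, exact at all frequencies) and amplitude
# proportional to the subject's coupling strength in that band; independent
# broadband Gaussian noise is added per channel, plus occasional broadband
# artifact bursts and two low-frequency ocular channels.

#' Default group-by-band coupling strengths
#'
#' The disease signature the pipeline must recover: elevated theta coupling
#' and reduced beta coupling in AD relative to HC, with MCI-AD intermediate
#' in theta and close to AD in beta. Rows are groups, columns band names.
#'
#' @return a 3 x 5 numeric matrix.
#' @export
default_coupling <- function() {
  m <- rbind(
    HC       = c(delta = 0.30, theta = 0.32, alpha = 0.42, beta = 0.34, gamma = 0.22),
    `MCI-AD` = c(delta = 0.33, theta = 0.36, alpha = 0.42, beta = 0.25, gamma = 0.22),
    AD       = c(delta = 0.33, theta = 0.46, alpha = 0.42, beta = 0.21, gamma = 0.20))
  m
}

#' Synthetic cohort specification
#'
#' Defaults emulate the clinical acquisition: 62 scalp + 2 ocular channels,
#' 1000 Hz, 8 minutes eyes-closed, with group sizes 30 HC / 14 MCI-AD /
#' 21 AD and an AD signature of elevated theta and reduced beta
#' phase coupling. A fixed seed makes cohort generation byte-identical.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param n_channels number of scalp EEG channels (default 62).
#' @param n_eog number of ocular channels appended (default 2).
#' @param rate sampling rate in Hz (default 1000).
#' @param duration recording length in seconds (default 480).
#' @param bands band table from [eeg_bands()].
#' @param coupling group x band matrix of coupling strengths in \[0, 1\];
#'   see `eegmst:::default_coupling()`.
#' @param coupling_sd between-subject SD of coupling (default 0.03).
#' @param band_amplitude named vector of per-band latent RMS amplitudes
#'   (microvolts) before coupling scaling.
#' @param lag optional channels x bands matrix of constant phase offsets
#'   (radians); `NULL` (default) draws a cohort-level template from the seed,
#'   avoiding the PLI-blind offsets 0 and pi.
#' @param noise_sd per-channel broadband noise SD in microvolts (default 8).
#' @param artifact_rate probability that any 2 s block receives a broadband
#'   artifact burst (default 0.04).
#' @param artifact_sd SD of the artifact burst in microvolts (default 200).
#' @param seed integer master seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HC = 30, `MCI-AD` = 14, AD = 21),
                        n_channels = 62, n_eog = 2, rate = 1000,
                        duration = 480, bands = eeg_bands(),
                        coupling = default_coupling(),
                        coupling_sd = 0.03,
                        band_amplitude = c(delta = 3, theta = 2.8,
                                           alpha = 3.2, beta = 5, gamma = 10),
                        lag = NULL, noise_sd = 8, artifact_rate = 0.04,
                        artifact_sd = 200, seed = 42L) {
  stopifnot(all(group_sizes > 0), n_channels >= 2, rate > 0, duration > 0,
            all(coupling >= 0 & coupling <= 1))
  if (!all(rownames(coupling) %in% names(group_sizes)) ||
      !all(bands$name %in% colnames(coupling)))
    stop("`coupling` must have groups as rows and band names as columns")
  if (!is.null(lag) && (nrow(lag) != n_channels || ncol(lag) != nrow(bands)))
    stop("`lag` must be a channels x bands matrix")
  structure(list(group_sizes = group_sizes, n_channels = n_channels,
                 n_eog = n_eog, rate = rate, duration = duration,
                 bands = bands, coupling = coupling,
                 coupling_sd = coupling_sd, band_amplitude = band_amplitude,
                 lag = lag, noise_sd = noise_sd, artifact_rate = artifact_rate,
                 artifact_sd = artifact_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Fast preset for CI-speed runs
#'
#' 19 scalp channels (classic 10–20 montage), 250 Hz, 100 s — small enough
#' for replicate pipeline runs in tests while keeping at least 40 usable
#' 2 s epochs.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
fast_cohort_spec <- function(...) {
  cohort_spec(n_channels = 19, rate = 250, duration = 100, ...)
}

scalp_labels <- function(n) {
  classic <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
               "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  if (n <= length(classic)) classic[seq_len(n)]
  else c(classic, paste0("E", seq_len(n - length(classic))))
}

# channel x band matrix of constant phase offsets, a cohort-level template
# derived from the master seed. Offsets avoid the neighbourhoods of 0 and pi
# where the PLI is blind by construction.
lag_template <- function(spec) {
  if (!is.null(spec$lag)) {
    out <- spec$lag
    colnames(out) <- spec$bands$name
    return(out)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 7L)
  nb <- nrow(spec$bands)
  th <- matrix(stats::runif(spec$n_channels * nb, 0.35, pi - 0.35) *
                 sample(c(-1, 1), spec$n_channels * nb, replace = TRUE),
               spec$n_channels, nb)
  colnames(th) <- spec$bands$name
  th
}

# fixed-order metadata draws for one subject: coupling jitter, covariates,
# clinical scores, CSF values. generate_subject() replays the same stream.
subject_profile <- function(spec, group, subject_seed) {
  set.seed(subject_seed)
  nb <- nrow(spec$bands)
  coup <- pmin(1, pmax(0.02, spec$coupling[group, spec$bands$name] +
                         stats::rnorm(nb, 0, spec$coupling_sd)))
  names(coup) <- spec$bands$name
  zt <- (coup["theta"] - spec$coupling[group, "theta"]) / spec$coupling_sd
  zb <- (coup["beta"] - spec$coupling[group, "beta"]) / spec$coupling_sd

  demo <- list(
    HC       = list(age = c(64.1, 8.2), edu = c(13.3, 3.2), p_female = 0.60),
    `MCI-AD` = list(age = c(67.2, 9.2), edu = c(11.9, 3.7), p_female = 0.47),
    AD       = list(age = c(63.1, 8.4), edu = c(10.7, 4.4), p_female = 0.64))[[group]]
  age <- round(stats::rnorm(1, demo$age[1], demo$age[2]))
  sex <- if (stats::runif(1) < demo$p_female) "F" else "M"
  edu <- max(6, round(stats::rnorm(1, demo$edu[1], demo$edu[2])))

  # score = group mean + linear link to the subject's coupling deviations
  # (theta up / beta down track worse cognition) + residual noise
  sm <- list( #            HC            MCI-AD        AD            w_t   w_b
    MMSE        = list(c(28.2, 1.0),  c(26.4, 1.3), c(14.9, 4.4), -0.6,  0.6),
    MoCA        = list(c(26.6, 1.4),  c(20.4, 3.3), c(9.3, 4.2),  -0.8,  0.8),
    `HDS-R`     = list(c(31.2, 1.1),  c(28.6, 2.4), c(13.0, 7.0), -0.7,  0.7),
    CDR         = list(c(0.0, 0.05),  c(0.33, 0.18), c(1.05, 0.47), 0.05, -0.05),
    `AVLT-delay` = list(c(5.7, 2.0),  c(1.9, 1.6),  c(0.15, 0.4), -0.3,  0.3),
    `AVLT-recog` = list(c(22.3, 1.3), c(17.1, 3.5), c(11.6, 6.6), -0.5,  0.5),
    HAMA        = list(c(4, 2),       c(6, 3),      c(8, 4),       0.3, -0.3),
    HAMD        = list(c(3, 2),       c(5, 3),      c(7, 4),       0.3, -0.3),
    ADL         = list(c(14, 1),      c(16, 2),     c(30, 6),      0.5, -0.5))
  gi <- match(group, c("HC", "MCI-AD", "AD"))
  scores <- vapply(sm, function(s) {
    s[[gi]][1] + s[[4]] * zt + s[[5]] * zb + stats::rnorm(1, 0, s[[gi]][2])
  }, 0)

  # synthetic CSF panel (all groups drawn to keep the RNG stream fixed;
  # reported for MCI-AD/AD only, as in clinical practice). Signs: t-Tau
  # rises with beta coupling, p-Tau falls with theta coupling, Abeta42
  # rises with theta coupling.
  cm <- list(`Abeta42` = list(c(900, 150), c(417, 120), c(449, 130)),
             `Abeta40` = list(c(9000, 3000), c(8641, 3400), c(10386, 4400)),
             `t-Tau`   = list(c(250, 100), c(566, 330), c(719, 290)),
             `p-Tau`   = list(c(35, 15), c(74, 50), c(121, 90)))
  csf <- vapply(cm, function(s) {
    max(1, s[[gi]][1] + stats::rnorm(1, 0, s[[gi]][2]))
  }, 0)
  # apply the coupling links with the documented signs
  csf["Abeta42"] <- max(1, csf["Abeta42"] + 40 * zt)
  csf["t-Tau"] <- max(1, csf["t-Tau"] + 60 * zb)
  csf["p-Tau"] <- max(1, csf["p-Tau"] - 20 * zt)
  if (group == "HC") csf[] <- NA_real_

  list(coupling = coup, age = age, sex = sex, education = edu,
       scores = scores, csf = csf)
}

#' Generate one synthetic subject recording
#'
#' Draws the subject's coupling strengths (group mean plus jitter), then
#' synthesizes the multichannel recording under the latent-oscillator model
#' described above. Deterministic for a fixed `subject_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param group group label (`HC`, `MCI-AD`, `AD`).
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier (default derived from group and seed).
#' @return an [eeg_recording()]; the drawn per-band couplings are attached
#'   as attribute `"coupling"`.
#' @export
generate_subject <- function(spec, group, subject_seed,
                             subject_id = sprintf("%s_%06d", group,
                                                  subject_seed %% 1000000L)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% rownames(spec$coupling)) stop("unknown group: ", group)
  lags <- lag_template(spec)
  prof <- subject_profile(spec, group, subject_seed)   # seeds + metadata draws

  n_t <- round(spec$duration * spec$rate)
  n_ch <- spec$n_channels
  x <- matrix(stats::rnorm(n_ch * n_t, 0, spec$noise_sd), n_ch, n_t)

  for (b in seq_len(nrow(spec$bands))) {
    bname <- spec$bands$name[b]
    taps <- fir_bandpass_taps(spec$bands$low[b], spec$bands$high[b],
                              spec$rate, min(spec$bands$low[b], 2))
    latent <- apply_fir(matrix(stats::rnorm(n_t), 1L), taps)[1L, ]
    za <- analytic_signal(latent)
    za <- za * sqrt(2 / mean(Mod(za)^2))      # real part has unit RMS
    amp <- spec$band_amplitude[[bname]] * prof$coupling[[bname]]
    th <- lags[, b]
    # Re(za * e^{i theta}) per channel, vectorized as an outer product
    x <- x + amp * (cos(th) %o% Re(za) - sin(th) %o% Im(za))
  }

  # broadband artifact bursts in random 2 s blocks on a random channel
  n_block <- floor(spec$duration / 2)
  block_len <- round(2 * spec$rate)
  hit <- which(stats::runif(n_block) < spec$artifact_rate)
  for (blk in hit) {
    ch <- sample.int(n_ch, 1L)
    t0 <- (blk - 1L) * block_len + sample.int(block_len %/% 2L, 1L)
    burst_len <- round(0.3 * spec$rate)
    idx <- t0:min(t0 + burst_len - 1L, n_t)
    x[ch, idx] <- x[ch, idx] + stats::rnorm(length(idx), 0, spec$artifact_sd)
  }

  labels <- scalp_labels(n_ch)
  kinds <- rep("EEG", n_ch)
  if (spec$n_eog > 0L) {
    taps_eog <- fir_bandpass_taps(0.3, 3, spec$rate, 0.3)
    eog <- apply_fir(matrix(stats::rnorm(spec$n_eog * n_t, 0, 1),
                            spec$n_eog), taps_eog) * 60 +
      matrix(stats::rnorm(spec$n_eog * n_t, 0, 5), spec$n_eog)
    x <- rbind(x, eog)
    labels <- c(labels, c("HEOG", "VEOG", paste0("EOG", seq_len(max(0, spec$n_eog - 2L))))[seq_len(spec$n_eog)])
    kinds <- c(kinds, rep("EOG", spec$n_eog))
  }
  rec <- eeg_recording(x, rate = spec$rate, channel_labels = labels,
                       channel_kinds = kinds, subject_id = subject_id)
  attr(rec, "coupling") <- prof$coupling
  rec
}

#' Deterministic subject plan for a cohort
#'
#' Expands the group sizes into one row per subject with a per-subject seed
#' derived from the master seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `subject_id`, `group`, `subject_seed`.
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
  data.frame(subject_id = sprintf("S%03d_%s", seq_along(groups), groups),
             group = groups, subject_seed = seeds,
             stringsAsFactors = FALSE)
}

#' Build the subject metadata table for a cohort
#'
#' Covariates, clinical scores and synthetic CSF values for every planned
#' subject, consistent with what [generate_subject()] draws for the same
#' seeds (the metadata occupy the head of each subject's RNG stream).
#'
#' @param spec a [cohort_spec()].
#' @param plan optionally a precomputed [cohort_plan()].
#' @return data.frame, one row per subject.
#' @export
cohort_subject_table <- function(spec, plan = cohort_plan(spec)) {
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    pr <- subject_profile(spec, plan$group[i], plan$subject_seed[i])
    data.frame(subject_id = plan$subject_id[i], group = plan$group[i],
               age = pr$age, sex = pr$sex, education = pr$education,
               as.list(round(pr$scores, 2)),
               as.list(round(pr$csf, 2)),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a full cohort on disk
#'
#' Writes one EDF recording per subject, a CSV subject table, and a JSON
#' manifest recording the specification and all seeds. Byte-identical for a
#' fixed spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the plan data.frame with a `path` column added.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(spec)
  plan$path <- file.path(out_dir, paste0(plan$subject_id, ".edf"))
  for (i in seq_len(nrow(plan))) {
    rec <- generate_subject(spec, plan$group[i], plan$subject_seed[i],
                            subject_id = plan$subject_id[i])
    write_edf(rec, plan$path[i])
  }
  tab <- cohort_subject_table(spec, plan)
  utils::write.csv(tab, file.path(out_dir, "subjects.csv"), row.names = FALSE)
  manifest <- list(spec = spec[setdiff(names(spec), "bands")],
                   bands = spec$bands, plan = plan)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(plan)
}

#' Independent Monte-Carlo oracle for the expected PLI
#'
#' Estimates, by direct simulation that shares no code with the connectivity
#' module, the PLI value the estimator should report for two channels
#' carrying a common narrowband oscillation with a constant phase lag plus
#' independent broadband noise. The oracle band-limits with its own Fourier
#' amplitude mask and extracts phase differences directly from the complex
#' spectra.
#'
#' @param coupling amplitude of the shared oscillation (same units as
#'   `noise_sd`).
#' @param noise_sd SD of the independent white noise on each channel.
#' @param lag constant phase offset between the channels (radians).
#' @param n_samples samples per replicate.
#' @param n_reps Monte-Carlo replicates (>= 100).
#' @param rate sampling rate (Hz).
#' @param band band edges in Hz.
#' @param transition transition width of the band-limiting model in Hz. The
#'   oracle's Fourier mask mirrors the declared filter contract — amplitude
#'   0.5 at the cutoffs with a raised-cosine roll-off of this width — so
#'   that the oracle and the estimator see the same in-band noise power.
#' @param edge_fraction fraction of samples discarded at each edge, matching
#'   the estimator's exclusion window.
#' @return list with `estimate`, `se`, `tolerance` (3 standard errors).
#' @export
expected_pli_oracle <- function(coupling, noise_sd, lag, n_samples,
                                n_reps = 200, rate = 250, band = c(4, 8),
                                transition = min(band[1], 2),
                                edge_fraction = 0.05) {
  if (n_reps < 100) stop("n_reps must be at least 100")
  n <- n_samples
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)            # two-sided frequency axis
  # amplitude mask: 1 inside the band proper, raised-cosine roll-off of
  # width `transition` centred on each cutoff (0.5 at the cutoff itself)
  ramp <- function(f, fc) {                     # 0 below fc-T/2, 1 above fc+T/2
    x <- pmin(pmax((f - fc + transition / 2) / transition, 0), 1)
    0.5 * (1 - cos(pi * x))
  }
  mask <- ramp(freqs, band[1]) * (1 - ramp(freqs, band[2]))
  keep <- (floor(edge_fraction * n) + 1):(n - floor(edge_fraction * n))
  f0 <- sqrt(band[1] * band[2])                 # carrier at the geometric centre
  tt <- (seq_len(n) - 1) / rate

  one_rep <- function() {
    phi0 <- stats::runif(1, 0, 2 * pi)
    s1 <- coupling * cos(2 * pi * f0 * tt + phi0)
    s2 <- coupling * cos(2 * pi * f0 * tt + phi0 - lag)
    y1 <- s1 + stats::rnorm(n, 0, noise_sd)
    y2 <- s2 + stats::rnorm(n, 0, noise_sd)
    # brick-wall band-limit and analytic signal in one Fourier pass:
    # zero everything out of band, zero the negative half, double the rest
    az <- function(y) {
      Y <- stats::fft(y) * mask
      half <- seq(floor(n / 2) + 2, n)
      Y[half] <- 0
      stats::fft(2 * Y, inverse = TRUE) / n
    }
    dphi <- Arg(az(y1) * Conj(az(y2)))[keep]
    abs(mean(sign(sin(dphi))))
  }
  reps <- vapply(seq_len(n_reps), function(i) one_rep(), 0)
  est <- mean(reps)
  se <- stats::sd(reps) / sqrt(n_reps)
  list(estimate = est, se = se, tolerance = 3 * se)
}
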