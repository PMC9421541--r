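#' Configuration for the synthetic two-group EEG cohort
#'
#' Describes a cohort of multichannel resting-state EEG recordings generated
#' from a semi-Markov sequence of quasi-stable topographic states. Each state
#' carries one of the five canonical microstate templates; while a state is
#' active its template is modulated by a band-limited oscillatory carrier and
#' a random polarity (microstates are polarity-invariant). Spatially
#' correlated pink background noise is added at a configured signal-to-noise
#' ratio. Group 2 receives a deficit in map E only: its dwell times are
#' scaled by `group2_mapE_duration_scale` and its transition probability by
#' `group2_mapE_occurrence_scale`.
#'
#' @param n_channels number of electrodes (default 19, 10-20 montage).
#' @param sfreq sampling rate in Hz (default 250).
#' @param duration seconds of data per subject (default 180).
#' @param templates k x channels matrix of average-referenced unit-norm
#'   state topographies (default [make_canonical_templates]).
#' @param mean_dwell mean state dwell time in ms (default 80, within the
#'   50-120 ms range typical of microstates).
#' @param dwell_shape gamma shape of the dwell-time law (default 2).
#' @param subject_dwell_cv between-subject coefficient of variation of the
#'   per-subject mean dwell time (default 0.3); models individual differences
#'   in state stability.
#' @param subject_amp_cv between-subject coefficient of variation of each
#'   map's carrier amplitude (default 0.3); models individual differences in
#'   band power (alpha power in particular varies widely across people).
#' @param subject_snr_cv between-subject coefficient of variation of the
#'   signal-to-noise ratio (default 0.3); models heterogeneous recording
#'   quality and background activity.
#' @param carrier_bands list (one per map) of c(low, high) Hz carrier bands;
#'   default: every map oscillates in the alpha band (8-12 Hz).
#' @param distractor_weight RMS of an optional second, band-separated state
#'   process relative to the primary one (default 0 = off). When positive, an
#'   independent semi-Markov sequence over the same templates, carried by
#'   `distractor_band` oscillations and free of any group effect, is
#'   superposed on the primary process. Broadband EEG then reflects a mixture
#'   of two generators with different spectral signatures and different
#'   dynamics, so band-pass filtering genuinely isolates band-specific
#'   microstate dynamics; the ground truth always refers to the primary
#'   process.
#' @param distractor_band c(low, high) Hz carrier band of the background
#'   process (default 1-8 Hz).
#' @param snr ratio of state-signal RMS to noise RMS (default 5).
#' @param group2_mapE_duration_scale multiplier in (0, 1] applied to map E
#'   dwell times in group 2 (default 1 = no effect).
#' @param group2_mapE_occurrence_scale multiplier in (0, 1] applied to map E
#'   transition probability in group 2 (default 1 = no effect).
#' @param n_per_group subjects per group (default 30).
#' @param seed integer master seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_channels = 19L, sfreq = 250, duration = 180,
                             templates = NULL, mean_dwell = 80,
                             dwell_shape = 2, subject_dwell_cv = 0.3,
                             subject_amp_cv = 0.3, subject_snr_cv = 0.3,
                             carrier_bands = NULL, snr = 5,
                             distractor_weight = 0, distractor_band = c(1, 8),
                             group2_mapE_duration_scale = 1,
                             group2_mapE_occurrence_scale = 1,
                             n_per_group = 30L, seed = 1L) {
  if (is.null(templates)) {
    templates <- make_canonical_templates(n_channels)$maps
  }
  if (inherits(templates, "ms_mapset")) templates <- templates$maps
  templates <- normalize_rows(as.matrix(templates))
  k <- nrow(templates)
  if (is.null(carrier_bands)) {
    carrier_bands <- rep(list(c(8, 12)), k)
  }
  cfg <- structure(list(
    n_channels = as.integer(n_channels), sfreq = sfreq, duration = duration,
    templates = templates, mean_dwell = mean_dwell,
    dwell_shape = dwell_shape, subject_dwell_cv = subject_dwell_cv,
    subject_amp_cv = subject_amp_cv, subject_snr_cv = subject_snr_cv,
    carrier_bands = carrier_bands, snr = snr,
    distractor_weight = distractor_weight, distractor_band = distractor_band,
    group2_mapE_duration_scale = group2_mapE_duration_scale,
    group2_mapE_occurrence_scale = group2_mapE_occurrence_scale,
    n_per_group = as.integer(n_per_group), seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$mean_dwell <= 0) stop("mean_dwell must be > 0")
  if (cfg$snr <= 0) stop("snr must be > 0")
  if (cfg$group2_mapE_duration_scale <= 0 ||
      cfg$group2_mapE_duration_scale > 1 ||
      cfg$group2_mapE_occurrence_scale <= 0 ||
      cfg$group2_mapE_occurrence_scale > 1) {
    stop("group-2 scales must lie in (0, 1]")
  }
  if (ncol(cfg$templates) != cfg$n_channels) {
    stop("templates do not match n_channels")
  }
  if (max(abs(rowMeans(cfg$templates))) > 1e-8) {
    stop("templates must be average-referenced")
  }
  if (any(abs(sqrt(rowSums(cfg$templates^2)) - 1) > 1e-8)) {
    stop("templates must be unit-norm")
  }
  cc <- abs_corr_matrix(cfg$templates, cfg$templates)
  diag(cc) <- 0
  if (max(cc) >= 0.95) stop("templates must be pairwise non-collinear (|r| < 0.95)")
  if (length(cfg$carrier_bands) != nrow(cfg$templates)) {
    stop("one carrier band per template is required")
  }
  invisible(cfg)
}

# Semi-Markov state sequence: states drawn with per-state selection weights
# (no self-transitions), gamma dwell times with per-state means. Returns the
# per-sample label vector of length n.
simulate_state_sequence <- function(n, sfreq, dwell_means_ms, dwell_shape,
                                    select_weights) {
  k <- length(dwell_means_ms)
  labels <- integer(n)
  pos <- 1L
  state <- sample.int(k, 1L, prob = select_weights)
  while (pos <= n) {
    dwell_ms <- stats::rgamma(1L, shape = dwell_shape,
                              scale = dwell_means_ms[state] / dwell_shape)
    len <- max(1L, as.integer(round(dwell_ms / 1000 * sfreq)))
    end <- min(n, pos + len - 1L)
    labels[pos:end] <- state
    pos <- end + 1L
    w <- select_weights
    w[state] <- 0                       # no self-transition
    state <- sample.int(k, 1L, prob = w)
  }
  labels
}

# Band-limited oscillatory carrier: white noise band-passed with a 4th-order
# Butterworth, scaled to unit RMS.
simulate_carrier <- function(n, sfreq, band) {
  bf <- signal::butter(4, band / (sfreq / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2L * sfreq))
  x <- x[(sfreq + 1L):(sfreq + n)]      # drop filter edge transients
  x / sqrt(mean(x^2))
}

# Spatially correlated pink (1/f) noise, channels x samples, unit overall RMS.
# The spatial mixing matrix is a random smooth mixture fixed per call.
simulate_noise <- function(n_channels, n, sfreq) {
  mix <- matrix(stats::rnorm(n_channels^2), n_channels)
  mix <- mix + diag(n_channels)         # keep it well-conditioned
  white <- matrix(stats::rnorm(n_channels * (n + 2L * sfreq)), n_channels)
  # 1/f shaping by a leaky integrator (AR(1) with coefficient near 1)
  pink <- t(apply(white, 1L, function(x) {
    stats::filter(x, 0.95, method = "recursive")
  }))
  pink <- pink[, (sfreq + 1L):(sfreq + n), drop = FALSE]
  noise <- mix %*% pink
  noise / sqrt(mean(noise^2))
}

#' Simulate one subject's EEG recording with known microstate dynamics
#'
#' Draws a semi-Markov state sequence (gamma dwell times; map E dwell and
#' transition probability scaled for group 2), modulates the active template
#' by its band-limited carrier and a random per-segment polarity, adds
#' spatially correlated pink noise at the configured SNR, and returns both
#' the recording and the ground truth (per-sample labels plus the temporal
#' measures computed from them by the same code path as backfitting).
#'
#' @param cfg a [synthetic_config].
#' @param group 1 or 2.
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier (default derived from group and seed).
#' @return List with `recording` ([eeg_recording]) and `truth` (list with
#'   `label_sequence`, `measures`, `mean_dwell_ms`).
#' @export
simulate_subject <- function(cfg, group, subject_seed,
                             subject_id = sprintf("g%d_s%d", group, subject_seed)) {
  validate_synthetic_config(cfg)
  if (!group %in% c(1L, 2L)) stop("group must be 1 or 2")
  k <- nrow(cfg$templates)
  n <- as.integer(round(cfg$duration * cfg$sfreq))
  map_e <- k                            # deficit map: last template (E)
  rlnorm_cv <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(subject_seed, {
    # per-subject mean dwell, per-map carrier amplitude, and snr: lognormal
    # around the configured values (individual differences)
    subj_dwell <- cfg$mean_dwell * rlnorm_cv(1L, cfg$subject_dwell_cv)
    subj_amp <- rlnorm_cv(k, cfg$subject_amp_cv)
    subj_snr <- cfg$snr * rlnorm_cv(1L, cfg$subject_snr_cv)
    dwell_means <- rep(subj_dwell, k)
    select_w <- rep(1, k)
    if (group == 2L) {
      dwell_means[map_e] <- dwell_means[map_e] * cfg$group2_mapE_duration_scale
      select_w[map_e] <- select_w[map_e] * cfg$group2_mapE_occurrence_scale
    }
    labels <- simulate_state_sequence(n, cfg$sfreq, dwell_means,
                                      cfg$dwell_shape, select_w)
    carriers <- vapply(seq_len(k), function(m) {
      subj_amp[m] * simulate_carrier(n, cfg$sfreq, cfg$carrier_bands[[m]])
    }, numeric(n))                      # n x k
    # per-segment random polarity
    r <- rle(labels)
    signs <- rep(sample(c(-1, 1), length(r$lengths), replace = TRUE),
                 r$lengths)
    amp <- carriers[cbind(seq_len(n), labels)] * signs
    sig <- t(cfg$templates[labels, , drop = FALSE] * amp)   # channels x samples
    sig_rms <- sqrt(mean(sig^2))
    if (cfg$distractor_weight > 0) {
      # independent background process in its own band, no group effect
      d_labels <- simulate_state_sequence(n, cfg$sfreq, rep(subj_dwell, k),
                                          cfg$dwell_shape, rep(1, k))
      d_carrier <- simulate_carrier(n, cfg$sfreq, cfg$distractor_band)
      d_amp <- rlnorm_cv(k, cfg$subject_amp_cv)
      dr <- rle(d_labels)
      d_signs <- rep(sample(c(-1, 1), length(dr$lengths), replace = TRUE),
                     dr$lengths)
      d_sig <- t(cfg$templates[d_labels, , drop = FALSE] *
                   (d_carrier * d_amp[d_labels] * d_signs))
      d_sig <- d_sig * (cfg$distractor_weight * sig_rms / sqrt(mean(d_sig^2)))
      sig <- sig + d_sig
    }
    noise <- simulate_noise(cfg$n_channels, n, cfg$sfreq)
    data <- sig + noise * (sig_rms / subj_snr)
  })
  montage <- colnames(cfg$templates)
  rec <- eeg_recording(data, cfg$sfreq, channel_labels = montage,
                       subject_id = subject_id, group = as.integer(group))
  truth_seg <- structure(
    list(labels = labels, corr = rep(1, n),
         map_labels = rownames(cfg$templates), k = k, sfreq = cfg$sfreq,
         seams = integer(0), params = list(assign_threshold = 0)),
    class = "ms_segmentation")
  truth <- list(label_sequence = labels,
                measures = compute_measures(truth_seg),
                mean_dwell_ms = subj_dwell)
  list(recording = rec, truth = truth)
}

#' Simulate a two-group cohort
#'
#' Generates `2 * n_per_group` subjects (group 1 first), each under a
#' distinct subject seed derived deterministically from `cfg$seed`.
#'
#' @param cfg a [synthetic_config].
#' @return List of per-subject lists as returned by [simulate_subject].
#' @export
simulate_cohort <- function(cfg) {
  validate_synthetic_config(cfg)
  if (cfg$n_per_group < 2L) stop("n_per_group must be at least 2")
  subjects <- vector("list", 2L * cfg$n_per_group)
  i <- 0L
  for (group in 1:2) {
    for (s in seq_len(cfg$n_per_group)) {
      i <- i + 1L
      subjects[[i]] <- simulate_subject(
        cfg, group, derive_seed(cfg$seed, "subject", group, s),
        subject_id = sprintf("g%d_s%02d", group, s))
    }
  }
  subjects
}
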