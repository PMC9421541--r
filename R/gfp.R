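#' Global field power
#'
#' Per-sample spatial standard deviation across channels, using the
#' population (divide-by-n) form: after average-referencing the sample, GFP
#' equals its root-mean-square. Peaks of the GFP series mark moments of high
#' topographic signal-to-noise.
#'
#' @param rec an [eeg_recording]; re-referenced internally if needed.
#' @return Numeric vector, one nonnegative value per sample.
#' @export
gfp <- function(rec) {
  validate_recording(rec)
  if (!is_average_referenced(rec)) rec <- average_reference(rec)
  sqrt(colMeans(rec$data^2))
}

#' Extract (a random subset of) GFP peaks
#'
#' Finds strict interior local maxima of the GFP series. If more than
#' `max_peaks` exist, a uniformly random subset of size `max_peaks` is drawn
#' under `seed`. Indices are returned sorted ascending.
#'
#' @param rec an [eeg_recording].
#' @param max_peaks maximum number of peaks to keep (default 1000).
#' @param seed integer seed for the random subset.
#' @return Integer vector of sample indices.
#' @export
extract_gfp_peaks <- function(rec, max_peaks = 1000L, seed = 1L) {
  g <- gfp(rec)
  n <- length(g)
  if (n < 3L) stop("recording must have at least 3 samples")
  idx <- which(g[-c(1L, n)] > g[-c(n - 1L, n)] &
               g[-c(1L, n)] > g[-c(1L, 2L)]) + 1L
  if (length(idx) == 0L) {
    warning("no GFP peaks found")
    return(integer(0))
  }
  if (is.finite(max_peaks) && length(idx) > max_peaks) {
    idx <- sort(with_seed(seed, sample(idx, max_peaks)))
  }
  idx
}

#' Reject outlier epochs by amplitude z-score
#'
#' Splits the recording into consecutive fixed-length epochs, summarizes each
#' epoch by its mean absolute amplitude across channels, z-scores the
#' summaries across epochs, and drops epochs with |z| above the threshold.
#' Surviving epochs are concatenated; the seam positions are recorded on the
#' returned recording so that downstream run-length statistics can treat
#' segments spanning a seam as boundary-truncated.
#'
#' @param rec an [eeg_recording].
#' @param epoch_len epoch length in seconds (default 1).
#' @param z_thresh rejection threshold on |z| (default 2).
#' @return List with `recording` (cleaned) and `mask` (logical, TRUE = kept),
#'   one element per whole epoch.
#' @export
reject_epochs_zscore <- function(rec, epoch_len = 1, z_thresh = 2) {
  validate_recording(rec)
  len <- as.integer(round(epoch_len * rec$sfreq))
  n_epochs <- ncol(rec$data) %/% len
  if (n_epochs < 2L) stop("recording must contain at least 2 whole epochs")
  stat <- vapply(seq_len(n_epochs), function(i) {
    cols <- ((i - 1L) * len + 1L):(i * len)
    mean(abs(rec$data[, cols]))
  }, numeric(1))
  z <- (stat - mean(stat)) / stats::sd(stat)
  keep <- abs(z) <= z_thresh
  if (!any(keep)) stop("all epochs rejected")
  cols_keep <- unlist(lapply(which(keep), function(i) {
    ((i - 1L) * len + 1L):(i * len)
  }))
  out <- rec
  out$data <- rec$data[, cols_keep, drop = FALSE]
  # a seam occurs wherever two kept epochs were not adjacent originally
  kept <- which(keep)
  seam_after <- which(diff(kept) > 1L)  # index into kept epochs
  out$seams <- as.integer(seam_after * len)
  list(recording = out, mask = keep)
}
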