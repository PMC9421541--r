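#' Construct an EEG recording
#'
#' Container for one subject's multichannel EEG: a channels x samples numeric
#' matrix in microvolts, plus sampling rate, channel labels, and optional
#' group membership (1 = control, 2 = patient by convention).
#'
#' @param data numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz.
#' @param channel_labels character vector, one label per channel (row).
#' @param subject_id subject identifier string.
#' @param group optional group tag, 1 or 2.
#' @param seams optional integer vector of sample indices immediately after
#'   which an epoch-concatenation seam occurs (a label run crossing a seam is
#'   treated as boundary-truncated downstream).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_labels = NULL,
                          subject_id = "subject", group = NULL,
                          seams = integer(0)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(nrow(data)))
    }
  }
  rec <- structure(
    list(data = data, sfreq = sfreq, channel_labels = channel_labels,
         subject_id = subject_id, group = group,
         seams = as.integer(seams)),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (anyNA(rec$data)) stop("recording contains NaN/NA values")
  if (nrow(rec$data) < 2L) stop("recording needs at least 2 channels")
  if (length(rec$channel_labels) != nrow(rec$data)) {
    stop("channel_labels length does not match channel count")
  }
  if (!is.numeric(rec$sfreq) || rec$sfreq <= 0) stop("sfreq must be > 0")
  if (!is.null(rec$group) && !rec$group %in% c(1L, 2L)) {
    stop("group must be 1 or 2")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$sfreq,
    ncol(x$data) / x$sfreq,
    if (is.null(x$group)) "" else sprintf(", group %d", x$group)))
  invisible(x)
}

#' Re-reference a recording to the common average
#'
#' Subtracts each sample's mean across channels, so every column of the data
#' matrix has zero mean. Idempotent.
#'
#' @param rec an [eeg_recording].
#' @return The recording, average-referenced.
#' @export
average_reference <- function(rec) {
  validate_recording(rec)
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec
}

is_average_referenced <- function(rec, tol = 1e-8) {
  max(abs(colMeans(rec$data))) <= tol * max(1, max(abs(rec$data)))
}
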