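#' Frequency band specification
#'
#' @param name band name.
#' @param low lower passband edge, Hz.
#' @param high upper passband edge, Hz.
#' @return A `band_spec` list.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L, low > 0, low < high)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Canonical analysis bands
#'
#' The five bands used throughout: broadband 1-30 Hz, delta 1-4 Hz,
#' theta 4-8 Hz, alpha 8-12 Hz, beta 15-30 Hz.
#'
#' @return Named list of [band_spec] objects.
#' @export
default_bands <- function() {
  list(
    broadband = band_spec("broadband", 1, 30),
    delta     = band_spec("delta", 1, 4),
    theta     = band_spec("theta", 4, 8),
    alpha     = band_spec("alpha", 8, 12),
    beta      = band_spec("beta", 15, 30)
  )
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass filter forward and backward
#' (`signal::filtfilt`), giving zero phase shift so topography timing is
#' preserved.
#'
#' @param rec an [eeg_recording].
#' @param band a [band_spec].
#' @return The filtered recording.
#' @export
bandpass <- function(rec, band) {
  validate_recording(rec)
  nyq <- rec$sfreq / 2
  if (band$high >= nyq) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band$high, nyq))
  }
  bf <- signal::butter(4, c(band$low, band$high) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  rec
}
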