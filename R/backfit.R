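#' Assign every sample to its best-matching microstate map
#'
#' Per sample, the label is the map with the highest absolute spatial
#' correlation to the observed topography; when that maximum falls below
#' `threshold` (or the sample has zero spatial variance) the sample is left
#' unassigned (`NA`). Ties are broken by the lowest map index.
#'
#' @param rec an [eeg_recording]; re-referenced internally if needed.
#' @param maps an [ms_mapset] with the same channels.
#' @param threshold minimum |r| for assignment (default 0.50).
#' @return An object of class `ms_segmentation`: per-sample `labels`
#'   (integer map index or NA), `corr` (best |r|), plus map labels, sfreq,
#'   seams and the parameters used.
#' @export
assign_labels <- function(rec, maps, threshold = 0.50) {
  validate_recording(rec)
  if (nrow(rec$data) != ncol(maps$maps)) {
    stop("channel count of recording and maps differ")
  }
  if (!is_average_referenced(rec)) rec <- average_reference(rec)
  cr <- sample_map_abs_corr(rec$data, maps$maps)   # samples x k
  labels <- max.col(cr, ties.method = "first")
  best <- cr[cbind(seq_along(labels), labels)]
  labels[best < threshold] <- NA_integer_
  structure(
    list(labels = labels, corr = best, map_labels = maps$labels,
         k = maps$k, sfreq = rec$sfreq, seams = rec$seams,
         params = list(assign_threshold = threshold)),
    class = "ms_segmentation")
}

# samples x k matrix of |Pearson r| between each data column (centered) and
# each map row; zero-variance samples get 0 against every map.
sample_map_abs_corr <- function(data, maps) {
  x <- t(data)                     # samples x channels
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x[!nz, ] <- 0
  abs(x %*% t(normalize_rows(maps)))
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, k = %d, %.1f%% unassigned\n",
              length(x$labels), x$sfreq, x$k,
              100 * mean(is.na(x$labels))))
  invisible(x)
}

#' Temporally smooth a segmentation
#'
#' Iterative window-count smoothing: each sample's fit score for map m is its
#' spatial correlation with m plus `factor / (2 * window)` times the number
#' of other samples within +/- `window` samples currently labeled m. Labels
#' are re-chosen by maximum adjusted score until a fixed point (or 50
#' iterations). Unassigned samples may gain a label only when their best
#' adjusted score reaches the assignment threshold. With `factor = 0` the
#' segmentation is returned unchanged.
#'
#' @param seg an `ms_segmentation` from [assign_labels] on the same recording.
#' @param rec the [eeg_recording] that was segmented.
#' @param maps the [ms_mapset] used.
#' @param window half-width of the smoothing window in samples (default 7).
#' @param factor smoothing strength (default 10); 0 disables smoothing.
#' @return The smoothed `ms_segmentation`.
#' @export
smooth_labels <- function(seg, rec, maps, window = 7L, factor = 10) {
  stopifnot(inherits(seg, "ms_segmentation"))
  seg$params$smooth_window <- window
  seg$params$smooth_factor <- factor
  if (factor == 0) return(seg)
  if (!is_average_referenced(rec)) rec <- average_reference(rec)
  cr <- sample_map_abs_corr(rec$data, maps$maps)   # samples x k
  n <- nrow(cr); k <- ncol(cr)
  lambda <- factor / (2 * window)
  threshold <- seg$params$assign_threshold
  labels <- seg$labels
  originally_na <- is.na(labels)
  for (iter in seq_len(50L)) {
    score <- cr
    for (m in seq_len(k)) {
      ind <- as.numeric(!is.na(labels) & labels == m)
      cs <- c(0, cumsum(ind))
      hi <- pmin(n, seq_len(n) + window)
      lo <- pmax(1L, seq_len(n) - window)
      cnt <- cs[hi + 1L] - cs[lo] - ind     # neighbors only, not self
      score[, m] <- score[, m] + lambda * cnt
    }
    new_labels <- max.col(score, ties.method = "first")
    best <- score[cbind(seq_len(n), new_labels)]
    # unassigned samples are re-assigned only if their adjusted score
    # crosses the original assignment threshold
    new_labels[originally_na & is.na(labels) & best < threshold] <- NA_integer_
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  seg$labels <- labels
  seg
}

#' Enforce a minimum microstate duration
#'
#' Every labeled run shorter than `min_samples` is split at its midpoint: the
#' left half takes the left neighbor's label and the right half the right
#' neighbor's (a run touching a sequence boundary is absorbed entirely into
#' its single neighbor). The rule is applied repeatedly until no short run
#' remains. Unassigned gaps are left untouched and act as neighbors with the
#' unassigned label.
#'
#' @param seg an `ms_segmentation`.
#' @param min_samples minimum run length in samples (default 3).
#' @return The corrected `ms_segmentation`.
#' @export
enforce_min_duration <- function(seg, min_samples = 3L) {
  stopifnot(inherits(seg, "ms_segmentation"))
  seg$params$min_duration_samples <- min_samples
  labels <- seg$labels
  n <- length(labels)
  if (n < min_samples) {
    warning("recording shorter than the minimum duration; left unchanged")
    return(seg)
  }
  code <- ifelse(is.na(labels), 0L, labels)   # 0 = unassigned for rle
  for (iter in seq_len(100L)) {
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < min_samples & r$values != 0L)
    if (length(short) == 0L) break
    for (j in short) {
      len <- r$lengths[j]
      left_lab <- if (j > 1L) r$values[j - 1L] else NA_integer_
      right_lab <- if (j < length(r$values)) r$values[j + 1L] else NA_integer_
      if (is.na(left_lab) && is.na(right_lab)) next   # whole sequence is one run
      if (is.na(left_lab)) {                          # run at sequence start
        code[starts[j]:ends[j]] <- right_lab
      } else if (is.na(right_lab)) {                  # run at sequence end
        code[starts[j]:ends[j]] <- left_lab
      } else {
        n_left <- len %/% 2L
        if (n_left > 0L) {
          code[starts[j]:(starts[j] + n_left - 1L)] <- left_lab
        }
        code[(starts[j] + n_left):ends[j]] <- right_lab
      }
    }
  }
  labels <- code
  labels[labels == 0L] <- NA_integer_
  seg$labels <- as.integer(labels)
  seg
}

#' Temporal microstate measures
#'
#' Run-length encodes the label sequence and computes, per map: occurrence
#' (runs per second of total recording time), mean duration (mean run length
#' in ms), and time coverage (fraction of all samples). Runs touching the
#' recording boundaries or an epoch-concatenation seam are censored — they
#' count toward occurrence and coverage but are excluded from the mean
#' duration. Unassigned samples break runs.
#'
#' @param seg a finalized `ms_segmentation`.
#' @return A `data.frame` (class `ms_measures`) with columns `map`,
#'   `occurrence`, `mean_duration`, `coverage`, `present`, and attribute
#'   `unassigned_fraction`.
#' @export
compute_measures <- function(seg) {
  stopifnot(inherits(seg, "ms_segmentation"))
  labels <- seg$labels
  n <- length(labels)
  total_s <- n / seg$sfreq
  code <- ifelse(is.na(labels), 0L, labels)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # boundary runs: touch sample 1 or n, or span/touch a seam (seam s sits
  # between samples s and s+1)
  boundary <- starts == 1L | ends == n
  for (s in seg$seams) {
    boundary <- boundary | (starts <= s & ends >= s + 1L) |
      ends == s | starts == s + 1L
  }
  out <- data.frame(map = seg$map_labels,
                    occurrence = 0, mean_duration = 0, coverage = 0,
                    present = FALSE, stringsAsFactors = FALSE)
  for (m in seq_len(seg$k)) {
    is_m <- r$values == m
    n_runs <- sum(is_m)
    out$occurrence[m] <- n_runs / total_s
    out$coverage[m] <- sum(r$lengths[is_m]) / n
    interior <- is_m & !boundary
    if (any(interior)) {
      out$mean_duration[m] <- mean(r$lengths[interior]) / seg$sfreq * 1000
    }
    out$present[m] <- n_runs > 0L
  }
  attr(out, "unassigned_fraction") <- mean(code == 0L)
  class(out) <- c("ms_measures", "data.frame")
  out
}

#' Backfit grand-mean maps across frequency bands
#'
#' For each band: band-pass filter, average-reference, assign labels against
#' the shared broadband grand-mean maps, smooth, enforce the minimum
#' duration, and compute temporal measures. Backfitting the same maps to
#' every band keeps features comparable across bands.
#'
#' @param rec an [eeg_recording].
#' @param grand_maps grand-mean [ms_mapset] (from broadband clustering).
#' @param bands list of [band_spec]s (default [default_bands()]).
#' @param threshold assignment threshold (default 0.50).
#' @param window smoothing half-window in samples (default 7).
#' @param factor smoothing factor (default 10).
#' @param min_samples minimum run length in samples (default 3).
#' @return A tidy `data.frame`: subject_id, group, band, map, occurrence,
#'   mean_duration, coverage, unassigned_fraction.
#' @export
band_pipeline <- function(rec, grand_maps, bands = default_bands(),
                          threshold = 0.50, window = 7L, factor = 10,
                          min_samples = 3L) {
  validate_recording(rec)
  rows <- lapply(bands, function(band) {
    filtered <- average_reference(bandpass(rec, band))
    seg <- assign_labels(filtered, grand_maps, threshold = threshold)
    seg <- smooth_labels(seg, filtered, grand_maps,
                         window = window, factor = factor)
    seg <- enforce_min_duration(seg, min_samples = min_samples)
    meas <- compute_measures(seg)
    data.frame(subject_id = rec$subject_id,
               group = if (is.null(rec$group)) NA_integer_ else rec$group,
               band = band$name,
               map = meas$map,
               occurrence = meas$occurrence,
               mean_duration = meas$mean_duration,
               coverage = meas$coverage,
               unassigned_fraction = attr(meas, "unassigned_fraction"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
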