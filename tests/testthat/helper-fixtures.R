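# Shared fixtures: tiny recordings and cohorts built in code.

random_recording <- function(n_channels = 19L, n_samples = 500L, sfreq = 250,
                             seed = 1L, group = NULL) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_channels * n_samples), n_channels),
                sfreq, channel_labels = montage_1020_19()[seq_len(n_channels)],
                subject_id = paste0("rand", seed), group = group)
}

# Segmentation object from a bare label vector (NA = unassigned).
segmentation_from_labels <- function(labels, sfreq = 250, k = max(labels, na.rm = TRUE),
                                     seams = integer(0)) {
  structure(
    list(labels = as.integer(labels), corr = rep(1, length(labels)),
         map_labels = LETTERS[seq_len(k)], k = as.integer(k), sfreq = sfreq,
         seams = as.integer(seams),
         params = list(assign_threshold = 0.5)),
    class = "ms_segmentation")
}

# Small synthetic cohort config used across tests (short recordings).
quick_config <- function(duration = 20, n_per_group = 4, seed = 7, ...) {
  synthetic_config(duration = duration, n_per_group = n_per_group,
                   seed = seed, ...)
}

# Tidy measures table drawn directly from per-cell normal distributions (no
# EEG simulation), optionally with a standardized group deficit planted in
# every measure of one (band, map) cell.
make_toy_measures <- function(n_per_group, effect_map = NULL,
                              effect_band = NULL, effect_size = 0, seed = 1) {
  set.seed(seed)
  bands <- c("broadband", "delta", "theta", "alpha", "beta")
  maps <- c("A", "B", "C", "D", "E")
  rows <- expand.grid(subject = seq_len(2 * n_per_group), band = bands,
                      map = maps, stringsAsFactors = FALSE)
  rows$subject_id <- sprintf("s%03d", rows$subject)
  rows$group <- ifelse(rows$subject <= n_per_group, 1L, 2L)
  n <- nrow(rows)
  rows$occurrence <- rnorm(n, 1.5, 0.3)
  rows$mean_duration <- rnorm(n, 80, 12)
  rows$coverage <- rnorm(n, 0.2, 0.04)
  rows$unassigned_fraction <- 0
  hit <- rows$group == 2L & rows$band %in% effect_band & rows$map %in% effect_map
  rows$occurrence[hit] <- rows$occurrence[hit] - effect_size * 0.3
  rows$mean_duration[hit] <- rows$mean_duration[hit] - effect_size * 12
  rows$coverage[hit] <- rows$coverage[hit] - effect_size * 0.04
  rows[, c("subject_id", "group", "band", "map", "occurrence",
           "mean_duration", "coverage", "unassigned_fraction")]
}

# Exhaustive two-sided permutation p-value for the mean-difference statistic.
exhaustive_perm_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- mean(x) - mean(y)
  splits <- utils::combn(length(pooled), nx)
  stats <- apply(splits, 2L, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}
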