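#' Write a recording as CSV plus JSON sidecar
#'
#' The CSV holds samples in rows and channels in columns, with a header row
#' of channel labels. The sidecar records subject id, group, sampling rate,
#' and (when ground truth is supplied) a run-length encoding of the true
#' label sequence.
#'
#' @param rec an [eeg_recording].
#' @param path CSV path to write; the sidecar gets the same path with
#'   `.json` appended.
#' @param truth optional ground-truth list from [simulate_subject].
#' @return Invisibly, the two paths written.
#' @export
write_recording_csv <- function(rec, path, truth = NULL) {
  validate_recording(rec)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(subject_id = rec$subject_id, sfreq = rec$sfreq,
               group = rec$group)
  if (!is.null(truth)) {
    r <- rle(ifelse(is.na(truth$label_sequence), 0L, truth$label_sequence))
    side$truth_rle <- list(lengths = r$lengths, values = r$values)
  }
  side_path <- paste0(path, ".json")
  jsonlite::write_json(side, side_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side_path))
}

#' Load recordings from CSV files
#'
#' Reads every `*.csv` in a directory (or an explicit file list) written in
#' the [write_recording_csv] layout. Group and sampling rate come from the
#' JSON sidecar when present, else from `sfreq`.
#'
#' @param path directory or character vector of CSV paths.
#' @param sfreq fallback sampling rate when a sidecar is absent.
#' @return List of [eeg_recording]s.
#' @export
load_recordings <- function(path, sfreq = NULL) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else path
  if (length(files) == 0L) stop("no CSV recordings found")
  recs <- lapply(files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    side_path <- paste0(f, ".json")
    side <- if (file.exists(side_path)) jsonlite::read_json(side_path)
            else list()
    fs <- if (!is.null(side$sfreq)) side$sfreq else sfreq
    if (is.null(fs)) stop("no sampling rate for ", f, "; pass sfreq")
    eeg_recording(t(as.matrix(df)), fs, channel_labels = names(df),
                  subject_id = if (!is.null(side$subject_id)) side$subject_id
                               else sub("\\.csv$", "", basename(f)),
                  group = if (!is.null(side$group)) as.integer(side$group)
                          else NULL)
  })
  labs <- vapply(recs, function(r) paste(r$channel_labels, collapse = ","),
                 character(1))
  if (length(unique(labs)) > 1L) {
    stop("inconsistent channel sets across subjects: ",
         paste(basename(files[labs != labs[1L]]), collapse = ", "))
  }
  fss <- vapply(recs, function(r) r$sfreq, numeric(1))
  if (length(unique(fss)) > 1L) stop("inconsistent sampling rates across subjects")
  recs
}

#' Run the full microstate analysis on a cohort
#'
#' Orchestrates the complete analysis: simulate (or accept) a two-group
#' cohort, band-pass to the broadband analysis band and average-reference,
#' cluster GFP-peak topographies per subject, average maps per group, check
#' topographic group equivalence, average the group maps into grand-mean
#' maps labeled by the canonical templates, backfit the grand-mean maps per
#' band for every subject, run the group test family, and (optionally)
#' evaluate frequency-specific classification models.
#'
#' @param cohort list of subject lists from [simulate_cohort], or a list of
#'   [eeg_recording]s with `group` set.
#' @param k number of maps (default 5); when `k_range` is given instead,
#'   k is chosen by split-level reliability.
#' @param k_range optional candidate k values for reliability selection.
#' @param bands list of [band_spec]s (default [default_bands()]).
#' @param cluster a [cluster_config].
#' @param backfit list of backfitting parameters (threshold, window, factor,
#'   min_samples).
#' @param family a [test_family] for the group statistics.
#' @param classify NULL to skip model evaluation, or a list of
#'   [evaluate_model] arguments (n_runs, n_folds, k_range, seed, ...); the
#'   frequency-specific model of every band is evaluated.
#' @param equivalence_cutoff matched-map correlation for the group
#'   equivalence check (default 0.95).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed global seed; all stage seeds are derived from it.
#' @return List with `grand_maps`, `group_maps`, `equivalence`, `k`,
#'   `reliability`, `measures`, `stats`, `models` (when requested), and the
#'   `manifest`.
#' @export
run_full <- function(cohort, k = 5L, k_range = NULL,
                     bands = default_bands(),
                     cluster = cluster_config(),
                     backfit = list(threshold = 0.50, window = 7L,
                                    factor = 10, min_samples = 3L),
                     family = test_family(),
                     classify = NULL,
                     equivalence_cutoff = 0.95,
                     out_dir = NULL, seed = 1L) {
  recs <- lapply(cohort, function(s) {
    if (inherits(s, "eeg_recording")) s else s$recording
  })
  groups <- vapply(recs, function(r) as.integer(r$group), integer(1))
  if (anyNA(groups)) stop("every recording needs a group tag")
  broadband <- bands[[which(vapply(bands, function(b) b$name, character(1)) ==
                            "broadband")[1L]]]

  # --- per-subject clustering on GFP-peak topographies ------------------
  ks <- if (is.null(k_range)) k else as.integer(k_range)
  subject_sets <- lapply(seq_along(recs), function(i) {
    pre <- average_reference(bandpass(recs[[i]], broadband))
    peaks <- extract_gfp_peaks(pre, max_peaks = cluster$max_gfp_peaks,
                               seed = derive_seed(seed, "peaks", i))
    peak_maps <- t(pre$data[, peaks, drop = FALSE])
    cfg_i <- cluster
    cfg_i$seed <- derive_seed(seed, "cluster", i)
    sets <- lapply(ks, function(kk) {
      modified_kmeans(peak_maps, kk, cfg_i,
                      channel_labels = pre$channel_labels)
    })
    names(sets) <- as.character(ks)
    sets
  })

  # --- k selection by reliability (when a range was given) --------------
  reliability <- NULL
  if (!is.null(k_range)) {
    group_sets_by_k <- lapply(as.character(ks), function(key) {
      average_map_sets(lapply(subject_sets, `[[`, key))
    })
    names(group_sets_by_k) <- as.character(ks)
    sel <- select_k_by_reliability(subject_sets, group_sets_by_k)
    k <- sel$k
    reliability <- sel$reliability
  }
  key <- as.character(k)

  # --- group and grand-mean maps ---------------------------------------
  templates <- make_canonical_templates(nrow(recs[[1L]]$data),
                                        recs[[1L]]$channel_labels)
  group_maps <- lapply(1:2, function(g) {
    sets <- lapply(which(groups == g), function(i) subject_sets[[i]][[key]])
    gm <- average_map_sets(sets)
    if (k == templates$k) gm <- label_canonical(gm, templates)
    gm
  })
  equivalence <- check_group_equivalence(group_maps[[1L]], group_maps[[2L]],
                                         cutoff = equivalence_cutoff)
  grand <- average_map_sets(group_maps, reference = group_maps[[1L]])
  if (k == templates$k) grand <- label_canonical(grand, templates)
  grand$level <- "grand"

  # --- per-band backfitting --------------------------------------------
  measures <- do.call(rbind, lapply(recs, function(r) {
    band_pipeline(r, grand, bands = bands,
                  threshold = backfit$threshold, window = backfit$window,
                  factor = backfit$factor, min_samples = backfit$min_samples)
  }))
  rownames(measures) <- NULL

  # --- group statistics -------------------------------------------------
  stats_family <- family
  stats_family$seed <- derive_seed(seed, "stats")
  stats_table <- run_test_family(measures, stats_family)

  # --- classification ----------------------------------------------------
  models <- NULL
  if (!is.null(classify)) {
    band_names <- vapply(bands, function(b) b$name, character(1))
    models <- lapply(band_names, function(bn) {
      tbl <- assemble_features(measures, "frequency_specific", bn)
      do.call(evaluate_model, c(list(table = tbl), classify))
    })
    names(models) <- band_names
  }

  manifest <- list(seed = seed, k = k, n_subjects = length(recs),
                   n_tests = attr(stats_table, "n_tests"),
                   bands = vapply(bands, function(b) b$name, character(1)),
                   backfit = backfit,
                   equivalence_pass = equivalence$pass)
  out <- list(grand_maps = grand, group_maps = group_maps,
              equivalence = equivalence, k = k, reliability = reliability,
              measures = measures, stats = stats_table, models = models,
              manifest = manifest)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

# Serialize a results bundle: maps JSON, measures/stats CSV, manifest JSON.
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(labels = res$grand_maps$labels,
         channel_labels = res$grand_maps$channel_labels,
         level = res$grand_maps$level, k = res$grand_maps$k,
         maps = apply(res$grand_maps$maps, 1L, identity, simplify = FALSE)),
    file.path(out_dir, "grand_maps.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(res$measures, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(res$stats, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  if (!is.null(res$models)) {
    metrics <- do.call(rbind, lapply(names(res$models), function(nm) {
      cbind(model = nm, res$models[[nm]]$metrics)
    }))
    utils::write.csv(metrics, file.path(out_dir, "model_metrics.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
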