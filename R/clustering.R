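#' Microstate map set
#'
#' An ordered set of average-referenced, unit-norm topographies (maps in
#' rows) at a given level of aggregation.
#'
#' @param maps numeric matrix, k x channels; rows are re-centered and
#'   re-normalized on construction.
#' @param labels map labels (unique), default M1..Mk.
#' @param level one of "subject", "group", "grand", "template".
#' @param channel_labels channel names (columns).
#' @param band band name the maps were estimated on (default "broadband").
#' @param gev global explained variance achieved at estimation, if known.
#' @return An object of class `ms_mapset`.
#' @export
ms_mapset <- function(maps, labels = NULL, level = "subject",
                      channel_labels = NULL, band = "broadband", gev = NA_real_) {
  maps <- as.matrix(maps)
  if (is.null(labels)) labels <- paste0("M", seq_len(nrow(maps)))
  if (anyDuplicated(labels)) stop("map labels must be unique")
  if (is.null(channel_labels)) {
    channel_labels <- colnames(maps)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(maps)))
  }
  maps <- normalize_rows(maps)
  dimnames(maps) <- list(labels, channel_labels)
  structure(list(maps = maps, labels = labels, level = level,
                 channel_labels = channel_labels, band = band,
                 k = nrow(maps), gev = gev),
            class = "ms_mapset")
}

#' @export
print.ms_mapset <- function(x, ...) {
  cat(sprintf("<ms_mapset> k = %d (%s), level %s, band %s%s\n",
              x$k, paste(x$labels, collapse = ","), x$level, x$band,
              if (is.na(x$gev)) "" else sprintf(", GEV %.3f", x$gev)))
  invisible(x)
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the average-referenced vectors;
#' the absolute value is taken when `polarity_invariant` (microstates are
#' defined up to polarity). A zero-variance topography yields correlation 0
#' with a warning.
#'
#' @param a,b numeric topography vectors over the same channels.
#' @param polarity_invariant take |r| (default TRUE).
#' @return A number in [0, 1] (or [-1, 1] if not polarity-invariant).
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  if (length(a) != length(b)) stop("topographies have different channel counts")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero-variance topography; correlation defined as 0")
    return(0)
  }
  r <- sum(a * b) / (na * nb)
  r <- max(-1, min(1, r))
  if (polarity_invariant) abs(r) else r
}

# |corr| matrix between rows of two centered/normalized map matrices.
abs_corr_matrix <- function(a, b) {
  abs(normalize_rows(a) %*% t(normalize_rows(b)))
}

#' Clustering configuration
#'
#' @param k_range candidate cluster counts (default 4:7).
#' @param n_repetitions random restarts per k (default 100).
#' @param max_gfp_peaks maximum GFP peaks per subject (default 1000).
#' @param polarity_invariant use absolute spatial correlation (default TRUE).
#' @param convergence_tol relative GEV change declaring convergence.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(k_range = 4:7, n_repetitions = 100L,
                           max_gfp_peaks = 1000L, polarity_invariant = TRUE,
                           convergence_tol = 1e-6, max_iter = 300L,
                           seed = 1L) {
  stopifnot(length(k_range) >= 1L, n_repetitions >= 1L)
  structure(list(k_range = as.integer(k_range),
                 n_repetitions = as.integer(n_repetitions),
                 max_gfp_peaks = max_gfp_peaks,
                 polarity_invariant = polarity_invariant,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Polarity-invariant modified k-means on peak topographies
#'
#' Clusters topographies (rows of `peak_maps`, typically GFP-peak samples)
#' into `k` prototype maps. Assignment labels each topography to the map with
#' the highest absolute spatial correlation; the update step sets each
#' cluster's map to the dominant eigenvector of the outer-product sum of its
#' assigned (average-referenced, unnormalized) topographies, which is the
#' standard polarity-invariant prototype. The best of `n_repetitions` random
#' restarts by global explained variance (GEV) is returned, where
#' GEV = sum_i GFP_i^2 r_i^2 / sum_i GFP_i^2 over the clustered samples.
#'
#' @param peak_maps numeric matrix, observations x channels.
#' @param k number of clusters.
#' @param cfg a [cluster_config].
#' @param channel_labels optional channel names.
#' @return An [ms_mapset] (level "subject") with attributes `assignment`
#'   (per-observation cluster index) and `gev`.
#' @export
modified_kmeans <- function(peak_maps, k, cfg = cluster_config(),
                            channel_labels = NULL) {
  x <- as.matrix(peak_maps)
  x <- x - rowMeans(x)                     # average-reference each map
  n <- nrow(x)
  if (n < k) stop("fewer topographies than clusters")
  canon <- normalize_rows(x)
  flip <- apply(canon, 1L, function(r) {
    nz <- which(abs(r) > 1e-12)[1L]
    if (is.na(nz) || r[nz] >= 0) 1 else -1
  })
  if (nrow(unique(round(canon * flip, 10))) < k) {
    stop("fewer distinct topographies (up to sign and scale) than clusters")
  }
  gfp_w <- sqrt(rowMeans(x^2))             # per-observation GFP
  xn <- normalize_rows(x)
  denom <- sum(gfp_w^2)

  run_once <- function(rep_seed) {
    centers <- xn[with_seed(rep_seed, sample(n, k)), , drop = FALSE]
    gev_prev <- -Inf
    assign_idx <- rep(1L, n)
    for (iter in seq_len(cfg$max_iter)) {
      cr <- if (cfg$polarity_invariant) abs(xn %*% t(centers))
            else xn %*% t(centers)
      assign_idx <- max.col(cr, ties.method = "first")
      best_r <- cr[cbind(seq_len(n), assign_idx)]
      # re-seed empty clusters from the worst-fit observation
      for (c_i in which(tabulate(assign_idx, k) == 0L)) {
        worst <- which.min(best_r)
        assign_idx[worst] <- c_i
        best_r[worst] <- 1
      }
      for (c_i in seq_len(k)) {
        xc <- x[assign_idx == c_i, , drop = FALSE]
        if (nrow(xc) == 1L) {
          centers[c_i, ] <- normalize_topography(xc[1L, ])
        } else {
          ev <- eigen(crossprod(xc), symmetric = TRUE)$vectors[, 1L]
          centers[c_i, ] <- normalize_topography(ev)
        }
      }
      cr <- if (cfg$polarity_invariant) abs(xn %*% t(centers))
            else xn %*% t(centers)
      assign_idx <- max.col(cr, ties.method = "first")
      gev <- sum(gfp_w^2 * cr[cbind(seq_len(n), assign_idx)]^2) / denom
      if (is.finite(gev_prev) &&
          abs(gev - gev_prev) <= cfg$convergence_tol * max(gev_prev, 1e-12)) {
        break
      }
      gev_prev <- gev
    }
    list(centers = centers, gev = gev, assignment = assign_idx)
  }

  best <- NULL
  for (r in seq_len(cfg$n_repetitions)) {
    sol <- run_once(derive_seed(cfg$seed, "kmeans", k, r))
    if (is.null(best) || sol$gev > best$gev) best <- sol
  }
  out <- ms_mapset(best$centers, level = "subject",
                   channel_labels = channel_labels, gev = best$gev)
  attr(out, "assignment") <- best$assignment
  out
}

#' Align one map set to a reference
#'
#' Finds the one-to-one pairing of maps (searched exhaustively over all k!
#' permutations) that maximizes the mean absolute spatial correlation with
#' the reference, and the per-map polarity that makes each signed correlation
#' with its matched reference map positive.
#'
#' @param target,reference [ms_mapset]s with equal k and channels.
#' @return List with `permutation` (target row for each reference slot),
#'   `signs`, and `mean_corr`.
#' @export
align_map_sets <- function(target, reference) {
  if (target$k != reference$k) stop("map sets have different k")
  k <- target$k
  cm <- normalize_rows(reference$maps) %*% t(normalize_rows(target$maps))
  acm <- abs(cm)
  perms <- all_permutations(k)
  scores <- apply(perms, 1L, function(p) sum(acm[cbind(seq_len(k), p)]))
  perm <- perms[which.max(scores), ]
  signs <- ifelse(cm[cbind(seq_len(k), perm)] >= 0, 1, -1)
  list(permutation = perm, signs = signs,
       mean_corr = max(scores) / k)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
  dimnames(out) <- NULL
  out
}

# Apply an alignment: reorder + sign-flip target rows into reference order.
apply_alignment <- function(target, alignment, reference = NULL) {
  m <- target$maps[alignment$permutation, , drop = FALSE] * alignment$signs
  labels <- if (is.null(reference)) target$labels[alignment$permutation]
            else reference$labels
  ms_mapset(m, labels = labels, level = target$level,
            channel_labels = target$channel_labels, band = target$band,
            gev = target$gev)
}

#' Average map sets into a higher-level set
#'
#' Each input set is aligned to the reference (optimal permutation and
#' polarity), then matched maps are averaged element-wise, re-average-
#' referenced and re-normalized. The level is promoted (subject -> group,
#' group -> grand).
#'
#' @param sets list of [ms_mapset]s with equal k and channels.
#' @param reference [ms_mapset] used for alignment (defaults to the first set).
#' @param min_alignment warn when a set aligns to the reference with mean
#'   |r| below this value (default 0.5).
#' @return The averaged [ms_mapset].
#' @export
average_map_sets <- function(sets, reference = sets[[1L]],
                             min_alignment = 0.5) {
  stopifnot(length(sets) >= 1L)
  k <- reference$k
  acc <- matrix(0, k, ncol(reference$maps))
  for (i in seq_along(sets)) {
    al <- align_map_sets(sets[[i]], reference)
    if (al$mean_corr < min_alignment) {
      warning(sprintf("set %d aligns poorly to reference (mean |r| = %.2f)",
                      i, al$mean_corr))
    }
    acc <- acc + apply_alignment(sets[[i]], al, reference)$maps
  }
  level <- switch(sets[[1L]]$level,
                  subject = "group", template = "group", group = "grand",
                  "grand")
  ms_mapset(acc / length(sets), labels = reference$labels, level = level,
            channel_labels = reference$channel_labels,
            band = reference$band)
}

#' Choose the number of microstate maps by split-level reliability
#'
#' For each candidate k, reliability is the mean (over subjects and maps) of
#' the absolute spatial correlation between each subject's maps and the
#' matched group-average maps, after optimal alignment. Returns the k with
#' the highest reliability; ties go to the smaller k.
#'
#' @param subject_map_sets list over subjects; each element a list over k
#'   (named by k) of [ms_mapset]s.
#' @param group_mean_sets list over k (named by k) of group-average
#'   [ms_mapset]s.
#' @return List with `k` (chosen) and `reliability` (data.frame k, reliability).
#' @export
select_k_by_reliability <- function(subject_map_sets, group_mean_sets) {
  ks <- as.integer(names(group_mean_sets))
  rel <- vapply(seq_along(ks), function(j) {
    key <- names(group_mean_sets)[j]
    ref <- group_mean_sets[[key]]
    mean(vapply(subject_map_sets, function(subj) {
      align_map_sets(subj[[key]], ref)$mean_corr
    }, numeric(1)))
  }, numeric(1))
  # max reliability; ties (within numerical noise) go to the smaller k
  best <- rel >= max(rel) - 1e-9
  list(k = min(ks[best]),
       reliability = data.frame(k = ks, reliability = rel))
}

#' Check topographic equivalence of two group map sets
#'
#' Aligns group B's maps to group A's and reports the full k x k absolute
#' spatial correlation matrix (rows: A, columns: aligned B). The sets pass
#' when every matched (diagonal) correlation reaches the cutoff.
#'
#' @param gA,gB group-level [ms_mapset]s with equal k.
#' @param cutoff matched-map correlation required to pass (default 0.95).
#' @return List with `corr_matrix`, `diagonal`, and `pass`.
#' @export
check_group_equivalence <- function(gA, gB, cutoff = 0.95) {
  if (gA$k != gB$k) stop("map sets have different k")
  al <- align_map_sets(gB, gA)
  aligned <- apply_alignment(gB, al, gA)
  cm <- abs_corr_matrix(gA$maps, aligned$maps)
  dimnames(cm) <- list(gA$labels, gA$labels)
  diag_r <- diag(cm)
  list(corr_matrix = cm, diagonal = diag_r,
       pass = all(diag_r >= cutoff))
}

#' Relabel a map set by best match to the canonical A-E templates
#'
#' @param set an [ms_mapset] with k maps.
#' @param templates template [ms_mapset] (default [make_canonical_templates]
#'   on the set's channels). Requires k equal to the template count.
#' @return The set, reordered, polarity-aligned and labeled like the templates.
#' @export
label_canonical <- function(set, templates = NULL) {
  if (is.null(templates)) {
    templates <- make_canonical_templates(length(set$channel_labels),
                                          set$channel_labels)
  }
  if (set$k != templates$k) stop("k does not match template count")
  apply_alignment(set, align_map_sets(set, templates), templates)
}
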