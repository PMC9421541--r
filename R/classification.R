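#' Assemble a feature table from the tidy measures table
#'
#' Builds the subjects x features matrix for one model definition:
#' frequency-specific (3 measures x 5 maps within one band), map-specific
#' (3 measures x 5 bands within one map), or the aggregate model over all
#' band x map cells. Column order is deterministic: measure-major
#' (occurrence, mean_duration, coverage), then map (or band) in table order.
#'
#' @param measures tidy table (subject_id, group, band, map, occurrence,
#'   mean_duration, coverage).
#' @param scheme `"frequency_specific"`, `"map_specific"`, or `"aggregate"`.
#' @param which band name (frequency-specific) or map label (map-specific).
#' @return List of class `feature_table`: `x` (matrix, named columns),
#'   `y` (factor with levels control/patient), `subjects`.
#' @export
assemble_features <- function(measures, scheme = c("frequency_specific",
                                                   "map_specific",
                                                   "aggregate"),
                              which = NULL) {
  scheme <- match.arg(scheme)
  measure_names <- c("occurrence", "mean_duration", "coverage")
  sel <- switch(scheme,
    frequency_specific = {
      if (is.null(which)) stop("frequency_specific scheme needs a band")
      measures[measures$band == which, ]
    },
    map_specific = {
      if (is.null(which)) stop("map_specific scheme needs a map")
      measures[measures$map == which, ]
    },
    aggregate = measures)
  if (nrow(sel) == 0L) stop("no rows match the requested scheme")
  subjects <- unique(measures$subject_id)
  cells <- unique(sel[, c("band", "map")])
  cols <- expand.grid(cell = seq_len(nrow(cells)), measure = measure_names,
                      stringsAsFactors = FALSE)
  cols <- cols[order(match(cols$measure, measure_names), cols$cell), ]
  x <- matrix(NA_real_, length(subjects), nrow(cols))
  colnames(x) <- sprintf("%s.%s.%s", cols$measure,
                         cells$band[cols$cell], cells$map[cols$cell])
  rownames(x) <- subjects
  for (j in seq_len(nrow(cols))) {
    cell <- cells[cols$cell[j], ]
    rows <- sel[sel$band == cell$band & sel$map == cell$map, ]
    vals <- rows[match(subjects, rows$subject_id), cols$measure[j]]
    x[, j] <- vals
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing measure for subject %s, feature %s",
                 subjects[bad[1L]], colnames(x)[bad[2L]]))
  }
  groups <- measures$group[match(subjects, measures$subject_id)]
  y <- factor(ifelse(groups == 2L, "patient", "control"),
              levels = c("control", "patient"))
  structure(list(x = x, y = y, subjects = subjects), class = "feature_table")
}

#' ReliefF feature weights
#'
#' Classical ReliefF for two classes: features are standardized, and for
#' every instance the `n_neighbors` nearest hits (same class, excluding the
#' instance) and nearest misses (other class) by Euclidean distance are
#' found. Each feature's weight accumulates the mean absolute difference to
#' the misses minus the mean absolute difference to the hits, normalized by
#' the feature's range and the number of instances. Higher weight = more
#' class-relevant. Ties in the ranking are broken by column order.
#'
#' @param x numeric matrix, instances x features.
#' @param y two-level factor or vector of class labels.
#' @param n_neighbors hits/misses per instance (default 15); classes with
#'   fewer members use all available with a warning.
#' @return List with `weights` (named) and `ranking` (column indices,
#'   best first).
#' @export
relieff_rank <- function(x, y, n_neighbors = 15L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  stopifnot(nlevels(y) == 2L, n == length(y), min(table(y)) >= 2L)
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0      # constant features
  rng <- apply(xs, 2L, function(v) diff(range(v)))
  if (min(table(y)) - 1L < n_neighbors) {
    warning("a class has fewer members than n_neighbors; using all available")
  }
  dd <- as.matrix(stats::dist(xs))
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(dd[i, same])][seq_len(min(n_neighbors, length(same)))]
    misses <- other[order(dd[i, other])][seq_len(min(n_neighbors, length(other)))]
    dh <- abs(sweep(xs[hits, , drop = FALSE], 2L, xs[i, ]))
    dm <- abs(sweep(xs[misses, , drop = FALSE], 2L, xs[i, ]))
    contrib <- colMeans(dm) - colMeans(dh)
    ok <- rng > 0
    w[ok] <- w[ok] + contrib[ok] / rng[ok] / n
  }
  names(w) <- colnames(x)
  list(weights = w, ranking = order(-w, seq_along(w)))
}

#' Evaluate a feature table with ReliefF + linear SVM under repeated CV
#'
#' Ten-times-repeated stratified 10-fold cross-validation (by default). In
#' every fold, features are standardized with training-fold statistics only,
#' ReliefF is run on the training fold only, and for each candidate feature
#' count k a linear SVM (cost 1) is fit on the top-k features and evaluated
#' on the held-out fold. Accuracy, sensitivity (positive class: patient),
#' specificity and AUC (from decision scores) are averaged over the
#' `n_runs * n_folds` fold evaluations.
#'
#' @param table a `feature_table` from [assemble_features].
#' @param n_runs CV repetitions (default 10).
#' @param n_folds folds per repetition (default 10).
#' @param k_range candidate feature counts (default 1..ncol).
#' @param n_neighbors ReliefF neighbors (default 15).
#' @param cost SVM regularization constant (default 1).
#' @param seed integer seed (fold splits are derived from it).
#' @param leakage_safe when FALSE, ReliefF ranking and standardization use
#'   the full table once before CV (the optimistic whole-data variant kept
#'   for comparison); default TRUE.
#' @return An object of class `ms_model_eval`: `metrics` (data.frame k,
#'   accuracy, sensitivity, specificity, auc), `fold_auc` (folds x k matrix),
#'   `top_feature` (modal rank-1 feature), `model` name, and the CV design.
#' @export
evaluate_model <- function(table, n_runs = 10L, n_folds = 10L,
                           k_range = NULL, n_neighbors = 15L, cost = 1,
                           seed = 1L, leakage_safe = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x; y <- table$y
  n <- nrow(x)
  if (is.null(k_range)) k_range <- seq_len(min(15L, ncol(x)))
  k_range <- as.integer(k_range)
  stopifnot(max(k_range) <= ncol(x))
  global_rank <- if (!leakage_safe) {
    relieff_rank(scale(x), y, n_neighbors)$ranking
  } else NULL
  n_eval <- n_runs * n_folds
  acc <- sens <- spec <- auc <- matrix(NA_real_, n_eval, length(k_range))
  top1 <- character(n_eval)
  e <- 0L
  for (run in seq_len(n_runs)) {
    folds <- with_seed(derive_seed(seed, "cvfold", run),
                       stratified_folds(y, n_folds))
    for (f in seq_len(n_folds)) {
      e <- e + 1L
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      mu <- colMeans(x[train_idx, , drop = FALSE])
      sd_ <- apply(x[train_idx, , drop = FALSE], 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      xtr <- sweep(sweep(x[train_idx, , drop = FALSE], 2L, mu), 2L, sd_, "/")
      xte <- sweep(sweep(x[test_idx, , drop = FALSE], 2L, mu), 2L, sd_, "/")
      ranking <- if (leakage_safe) {
        relieff_rank(xtr, y[train_idx], n_neighbors)$ranking
      } else global_rank
      top1[e] <- colnames(x)[ranking[1L]]
      for (j in seq_along(k_range)) {
        feats <- ranking[seq_len(k_range[j])]
        fit <- e1071::svm(xtr[, feats, drop = FALSE], y[train_idx],
                          kernel = "linear", cost = cost, scale = FALSE)
        pred <- stats::predict(fit, xte[, feats, drop = FALSE],
                               decision.values = TRUE)
        scores <- patient_scores(pred)
        truth <- y[test_idx]
        acc[e, j] <- mean(pred == truth)
        sens[e, j] <- safe_rate(pred == "patient", truth == "patient")
        spec[e, j] <- safe_rate(pred == "control", truth == "control")
        auc[e, j] <- fold_auc(scores, truth)
      }
    }
  }
  metrics <- data.frame(
    k = k_range,
    accuracy = colMeans(acc),
    sensitivity = colMeans(sens, na.rm = TRUE),
    specificity = colMeans(spec, na.rm = TRUE),
    auc = colMeans(auc, na.rm = TRUE))
  structure(list(metrics = metrics, fold_auc = auc, fold_accuracy = acc,
                 k_range = k_range,
                 top_feature = names(sort(table(top1), decreasing = TRUE))[1L],
                 n_runs = n_runs, n_folds = n_folds, seed = seed),
            class = "ms_model_eval")
}

# Stratified fold assignment: shuffles each class and deals it round-robin.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Decision scores oriented so that larger = more patient-like.
patient_scores <- function(pred) {
  dv <- attr(pred, "decision.values")
  s <- dv[, 1L]
  # column name "a/b" means positive score favors class a
  if (!startsWith(colnames(dv)[1L], "patient")) s <- -s
  s
}

safe_rate <- function(correct, relevant) {
  if (!any(relevant)) return(NA_real_)
  sum(correct & relevant) / sum(relevant)
}

# Fold AUC via pROC; NA when the fold lacks one class.
fold_auc <- function(scores, truth) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores,
    levels = c("control", "patient"), direction = "<", quiet = TRUE)))
}

#' @export
print.ms_model_eval <- function(x, ...) {
  cat(sprintf("<ms_model_eval> %dx%d CV, top feature: %s\n",
              x$n_runs, x$n_folds, x$top_feature))
  print(round(x$metrics, 3))
  invisible(x)
}

#' Paired comparison of two model evaluations by AUC
#'
#' Compares fold-wise AUCs of two evaluations run under the same CV design
#' and seed (paired folds) at a given feature count, with a two-sided
#' sign-flip permutation test on the fold-wise AUC differences.
#'
#' @param a,b `ms_model_eval` objects with identical CV design and seed.
#' @param at_k feature count at which to compare.
#' @param n_perm sign-flip permutations (default 10000).
#' @param seed integer seed.
#' @return List with `delta_auc` (mean fold-wise a - b) and `p`.
#' @export
compare_models <- function(a, b, at_k, n_perm = 10000L, seed = 1L) {
  if (a$n_runs != b$n_runs || a$n_folds != b$n_folds || a$seed != b$seed) {
    stop("evaluations were not run under the same CV design and seed")
  }
  ja <- match(at_k, a$k_range); jb <- match(at_k, b$k_range)
  if (is.na(ja) || is.na(jb)) stop("at_k not evaluated in both models")
  d <- a$fold_auc[, ja] - b$fold_auc[, jb]
  d <- d[!is.na(d)]
  obs <- mean(d)
  if (all(d == 0)) return(list(delta_auc = 0, p = 1))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE))
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(delta_auc = obs, p = p)
}

#' Null-model accuracy distribution
#'
#' Re-evaluates the model after permuting the class labels, `n_null` times;
#' the resulting mean accuracies estimate chance-level performance for the
#' same feature table and CV design.
#'
#' @param table a `feature_table`.
#' @param n_null number of label permutations (default 10).
#' @param seed integer seed.
#' @param ... passed to [evaluate_model].
#' @return List with `mean_accuracy` (vector, one per null repetition,
#'   averaged over k) and `per_k` (matrix n_null x k).
#' @export
null_model_suite <- function(table, n_null = 10L, seed = 1L, ...) {
  if (n_null < 1L) stop("n_null must be at least 1")
  per_k <- NULL
  for (i in seq_len(n_null)) {
    tbl <- table
    tbl$y <- with_seed(derive_seed(seed, "null", i), sample(table$y))
    ev <- evaluate_model(tbl, seed = derive_seed(seed, "nulleval", i), ...)
    per_k <- rbind(per_k, ev$metrics$accuracy)
  }
  list(mean_accuracy = rowMeans(per_k), per_k = per_k)
}
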