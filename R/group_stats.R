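#' Two-sided permutation test on the difference of group means
#'
#' The statistic is `mean(x) - mean(y)`. Group labels are shuffled `n_perm`
#' times and the two-sided p-value uses the add-one estimator
#' `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so p is never exactly 0.
#'
#' @param x,y numeric vectors (group 1 and group 2), each of length >= 2.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return List with `statistic` (observed mean difference) and `p`.
#' @export
permutation_test_mean_diff <- function(x, y, n_perm = 10000L, seed = 1L) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  pooled <- c(x, y)
  if (stats::var(pooled) == 0) {
    return(list(statistic = 0, p = 1))
  }
  nx <- length(x); n <- length(pooled)
  obs <- mean(x) - mean(y)
  total <- sum(pooled)
  ny <- n - nx
  pooled <- sort(pooled)   # permutation draws independent of input order
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sx <- sum(pooled[sample.int(n, nx)])
      sx / nx - (total - sx) / ny
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p = p)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled`, with the pooled variance weighted by
#' the group degrees of freedom (n - 1). A zero pooled SD yields `NA`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return Cohen's d (group 1 minus group 2), or `NA` if undefined.
#' @export
cohens_d <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Test-family configuration
#'
#' @param n_permutations permutations per test (default 10000).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed integer seed; per-test seeds are derived from it and the cell
#'   identity, so the family is reproducible and order-invariant.
#' @return A `test_family` list.
#' @export
test_family <- function(n_permutations = 10000L, alpha = 0.05, seed = 1L) {
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "test_family")
}

#' Run the full measure x band x map family of group comparisons
#'
#' One two-sided permutation test of the group-mean difference per cell
#' (measure, band, map), Bonferroni-corrected over the number of cells
#' actually tested (3 measures x 5 bands x 5 maps = 75 under the default
#' design). Cohen's d is reported with the group 1 minus group 2 convention
#' (negative d = smaller in group 2).
#'
#' @param measures tidy measures table from [band_pipeline] rows bound over
#'   subjects: columns subject_id, group, band, map, occurrence,
#'   mean_duration, coverage.
#' @param family a [test_family].
#' @param measure_names measures to test (default all three).
#' @return A `data.frame` sorted by `p_fwe`: measure, band, map, d,
#'   p_uncorrected, p_fwe, n_permutations; attribute `n_tests`.
#' @export
run_test_family <- function(measures, family = test_family(),
                            measure_names = c("occurrence", "mean_duration",
                                              "coverage")) {
  bands <- unique(measures$band)
  maps <- unique(measures$map)
  cells <- expand.grid(measure = measure_names, band = bands, map = maps,
                       stringsAsFactors = FALSE)
  n_tests <- nrow(cells)
  res <- lapply(seq_len(n_tests), function(i) {
    cell <- cells[i, ]
    rows <- measures$band == cell$band & measures$map == cell$map
    x <- measures[rows & measures$group == 1L, cell$measure]
    y <- measures[rows & measures$group == 2L, cell$measure]
    if (length(x) < 2L || length(y) < 2L) {
      stop(sprintf("cell (%s, %s, %s) is missing a group",
                   cell$measure, cell$band, cell$map))
    }
    test <- permutation_test_mean_diff(
      x, y, n_perm = family$n_permutations,
      seed = derive_seed(family$seed, cell$measure, cell$band, cell$map))
    data.frame(measure = cell$measure, band = cell$band, map = cell$map,
               d = cohens_d(x, y), p_uncorrected = test$p,
               p_fwe = min(1, test$p * n_tests),
               n_permutations = family$n_permutations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_fwe, out$p_uncorrected), ]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  attr(out, "d_convention") <- "group1 - group2"
  out
}

#' Permutation test on a Pearson correlation with a clinical score
#'
#' Pearson r between a per-subject feature and a symptom score; the two-sided
#' p-value shuffles one vector and compares |r|, with the add-one estimator.
#'
#' @param feature,symptom paired numeric vectors (>= 3 subjects).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return List with `r` and `p`.
#' @export
clinical_correlation <- function(feature, symptom, n_perm = 1000L, seed = 1L) {
  stopifnot(length(feature) == length(symptom), length(feature) >= 3L)
  if (stats::sd(feature) == 0 || stats::sd(symptom) == 0) {
    stop("constant vector: correlation undefined")
  }
  r <- stats::cor(feature, symptom)
  perm_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(feature, sample(symptom))
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_r) >= abs(r) - 1e-12)) / (n_perm + 1)
  list(r = r, p = p)
}
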