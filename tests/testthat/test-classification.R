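test_that("feature tables have the prescribed shapes and deterministic column order", {
  meas <- make_toy_measures(10, seed = 2)
  fs <- assemble_features(meas, "frequency_specific", "alpha")
  expect_equal(dim(fs$x), c(20L, 15L))
  expect_true(all(grepl("\\.alpha\\.", colnames(fs$x))))
  ms <- assemble_features(meas, "map_specific", "E")
  expect_equal(dim(ms$x), c(20L, 15L))
  expect_setequal(unique(sub("^([a-z_]+)\\..*$", "\\1", colnames(ms$x))),
                  c("occurrence", "mean_duration", "coverage"))
  expect_true(all(grepl("\\.E$", colnames(ms$x))))
  ag <- assemble_features(meas, "aggregate")
  expect_equal(ncol(ag$x), 75L)
  expect_identical(levels(fs$y), c("control", "patient"))
  expect_equal(as.integer(table(fs$y)), c(10L, 10L))
  # measure-major ordering: the first five columns are all occurrence
  expect_true(all(startsWith(colnames(fs$x)[1:5], "occurrence")))
  # a missing subject-cell is reported
  broken <- meas[-which(meas$subject_id == "s003" & meas$band == "alpha" &
                          meas$map == "B")[1], ]
  expect_error(assemble_features(broken, "frequency_specific", "alpha"),
               "s003")
})

test_that("ReliefF ranks a separating feature first and zeroes constants; duplicates tie", {
  set.seed(3)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(sep = ifelse(y == "a", 0, 4) + rnorm(n, sd = 0.1),
             noise1 = rnorm(n), noise2 = rnorm(n), const = rep(1, n))
  rr <- relieff_rank(x, y, n_neighbors = 5)
  expect_equal(rr$ranking[1], 1L)
  expect_equal(unname(rr$weights["const"]), 0)
  expect_gt(rr$weights["sep"], max(rr$weights[c("noise1", "noise2")]))
  # duplicated feature columns receive equal weights
  x2 <- cbind(f = x[, "sep"], f_copy = x[, "sep"], n1 = x[, "noise1"])
  rr2 <- relieff_rank(x2, y, n_neighbors = 5)
  expect_equal(unname(rr2$weights[1]), unname(rr2$weights[2]), tolerance = 1e-12)
})

test_that("ReliefF matches the direct formula on a tiny fixture", {
  # 6 instances, 2 features; small enough to hand-compute neighbors
  x <- rbind(c(0, 0), c(0.1, 1), c(0.2, 0),
             c(1, 1), c(1.1, 0), c(1.2, 1))
  y <- c("a", "a", "a", "b", "b", "b")
  rr <- relieff_rank(x, y, n_neighbors = 1)
  # oracle: direct single-neighbor Relief on standardized features
  xs <- scale(x)
  rng <- apply(xs, 2, function(v) diff(range(v)))
  dd <- as.matrix(dist(xs))
  w <- c(0, 0)
  for (i in 1:6) {
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    hit <- same[which.min(dd[i, same])]
    miss <- other[which.min(dd[i, other])]
    w <- w + (abs(xs[miss, ] - xs[i, ]) - abs(xs[hit, ] - xs[i, ])) / rng / 6
  }
  expect_equal(unname(rr$weights), unname(w), tolerance = 1e-12)
  expect_equal(rr$ranking, order(-w))
})

test_that("widely separated classes classify near-perfectly and runs are reproducible", {
  set.seed(6)
  n <- 60
  y <- rep(c(1L, 2L), each = n / 2)
  x <- cbind(matrix(rnorm(n * 4), n),
             sep = ifelse(y == 1, 0, 5) + rnorm(n))
  tbl <- structure(list(x = x, y = factor(ifelse(y == 2, "patient", "control"),
                                          levels = c("control", "patient")),
                        subjects = paste0("s", 1:n)),
                   class = "feature_table")
  ev <- evaluate_model(tbl, n_runs = 3, n_folds = 5, k_range = 1:5, seed = 21)
  expect_true(all(ev$metrics$accuracy >= 0.95))
  expect_true(all(ev$metrics$auc >= 0.95))
  ev2 <- evaluate_model(tbl, n_runs = 3, n_folds = 5, k_range = 1:5, seed = 21)
  expect_identical(ev$metrics, ev2$metrics)
  expect_identical(ev$top_feature, "sep")
  # metrics bounded in [0, 1]
  expect_true(all(unlist(ev$metrics[, -1]) >= 0 & unlist(ev$metrics[, -1]) <= 1))
})

test_that("null labels give chance-level accuracy and informative tables beat their nulls", {
  set.seed(7)
  n <- 60
  x <- matrix(rnorm(n * 10), n)
  colnames(x) <- paste0("f", 1:10)
  y <- factor(rep(c("control", "patient"), each = n / 2))
  tbl <- structure(list(x = x, y = y, subjects = paste0("s", 1:n)),
                   class = "feature_table")
  ev <- evaluate_model(tbl, n_runs = 3, n_folds = 5, k_range = c(1, 5, 10),
                       seed = 31)
  expect_lt(abs(mean(ev$metrics$accuracy) - 0.5), 0.12)
  nulls <- null_model_suite(tbl, n_null = 3, seed = 5, n_runs = 2,
                            n_folds = 5, k_range = c(1, 10))
  expect_lt(abs(mean(nulls$mean_accuracy) - 0.5), 0.1)
  expect_error(null_model_suite(tbl, n_null = 0), "n_null")
})

test_that("feature selection and scaling do not leak test-fold information", {
  # canary: a feature equal to the labels in test folds only (pure noise in
  # training folds) must not lift accuracy above chance
  set.seed(8)
  n <- 60
  y <- factor(rep(c("control", "patient"), each = n / 2))
  x <- matrix(rnorm(n * 6), n)
  colnames(x) <- paste0("f", 1:6)
  accs <- vapply(1:5, function(run) {
    folds <- microspect:::stratified_folds(y, 5)
    acc_run <- numeric(5)
    for (f in 1:5) {
      xc <- x
      test_idx <- which(folds == f)
      xc[test_idx, 1] <- as.numeric(y[test_idx] == "patient") * 10
      tbl <- structure(list(x = xc, y = y, subjects = paste0("s", 1:n)),
                       class = "feature_table")
      # single split evaluation via the public path: 5-fold, 1 run
      ev <- evaluate_model(tbl, n_runs = 1, n_folds = 5, k_range = 6,
                           seed = run)
      acc_run[f] <- ev$metrics$accuracy[1]
    }
    mean(acc_run)
  }, numeric(1))
  expect_lt(mean(accs), 0.65)
})

test_that("k = max(ncol) selection equals using all features (selection is a no-op)", {
  set.seed(9)
  n <- 40
  x <- matrix(rnorm(n * 5), n)
  colnames(x) <- paste0("f", 1:5)
  y <- factor(rep(c("control", "patient"), each = n / 2))
  tbl <- structure(list(x = x, y = y, subjects = paste0("s", 1:n)),
                   class = "feature_table")
  ev <- evaluate_model(tbl, n_runs = 2, n_folds = 4, k_range = 5,
                       n_neighbors = 10, seed = 3)
  # oracle: same CV loop with no selection at all
  accs <- c()
  for (run in 1:2) {
    folds <- microspect:::with_seed(
      microspect:::derive_seed(3, "cvfold", run),
      microspect:::stratified_folds(y, 4))
    for (f in 1:4) {
      tr <- which(folds != f); te <- which(folds == f)
      mu <- colMeans(x[tr, ]); sd_ <- apply(x[tr, ], 2, sd); sd_[sd_ == 0] <- 1
      xtr <- sweep(sweep(x[tr, ], 2, mu), 2, sd_, "/")
      xte <- sweep(sweep(x[te, ], 2, mu), 2, sd_, "/")
      fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = 1, scale = FALSE)
      accs <- c(accs, mean(predict(fit, xte) == y[te]))
    }
  }
  expect_equal(ev$metrics$accuracy[1], mean(accs), tolerance = 1e-8)
})

test_that("model comparison is symmetric, null on self, and errors on mismatched designs", {
  set.seed(10)
  n <- 60
  y <- factor(rep(c("control", "patient"), each = n / 2))
  mk <- function(informative) {
    x <- matrix(rnorm(n * 5), n)
    if (informative) x[, 1] <- x[, 1] + ifelse(y == "patient", 2.5, 0)
    colnames(x) <- paste0("f", 1:5)
    structure(list(x = x, y = y, subjects = paste0("s", 1:n)),
              class = "feature_table")
  }
  ev_info <- evaluate_model(mk(TRUE), n_runs = 3, n_folds = 5, k_range = 1:2,
                            seed = 17)
  ev_noise <- evaluate_model(mk(FALSE), n_runs = 3, n_folds = 5, k_range = 1:2,
                             seed = 17)
  self <- compare_models(ev_info, ev_info, at_k = 1, n_perm = 500, seed = 1)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p, 1)
  ab <- compare_models(ev_info, ev_noise, at_k = 1, n_perm = 2000, seed = 2)
  ba <- compare_models(ev_noise, ev_info, at_k = 1, n_perm = 2000, seed = 2)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p, ba$p)
  expect_gt(ab$delta_auc, 0)
  expect_lt(ab$p, 0.05)
  ev_other <- evaluate_model(mk(FALSE), n_runs = 2, n_folds = 5, k_range = 1,
                             seed = 18)
  expect_error(compare_models(ev_info, ev_other, at_k = 1), "same CV design")
})
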