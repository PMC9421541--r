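test_that("assign_labels matches templates, thresholds, and ignores scale", {
  tm <- make_canonical_templates()
  sfreq <- 250
  # samples that are exact copies of maps (with scaling / polarity)
  data <- cbind(tm$maps["C", ] * 3, -tm$maps["A", ], tm$maps["E", ] * 7.3,
                tm$maps["E", ])
  rec <- eeg_recording(data, sfreq, tm$channel_labels)
  seg <- assign_labels(rec, tm)
  expect_identical(seg$labels, c(3L, 1L, 5L, 5L))
  expect_equal(seg$corr, rep(1, 4), tolerance = 1e-9)
  # a zero-variance sample is unassigned
  rec0 <- eeg_recording(cbind(tm$maps["B", ], rep(1, 19)), sfreq,
                        tm$channel_labels)
  seg0 <- assign_labels(rec0, tm)
  expect_identical(seg0$labels, c(2L, NA))
  # below-threshold best correlation is unassigned
  set.seed(21)
  v <- microspect:::normalize_topography(residuals(lm(rnorm(19) ~ t(tm$maps))))
  rec1 <- eeg_recording(cbind(v), sfreq, tm$channel_labels)
  expect_identical(assign_labels(rec1, tm)$labels, NA_integer_)
})

test_that("assign_labels equals a brute-force per-sample argmax oracle", {
  tm <- make_canonical_templates()
  set.seed(22)
  rec <- random_recording(19, 1000, seed = 22)
  seg <- assign_labels(rec, tm, threshold = 0.3)
  ref <- average_reference(rec)
  oracle <- vapply(seq_len(1000), function(t) {
    rs <- vapply(1:5, function(m) {
      suppressWarnings(spatial_correlation(ref$data[, t], tm$maps[m, ]))
    }, numeric(1))
    if (max(rs) < 0.3) NA_integer_ else which.max(rs)
  }, integer(1))
  expect_identical(seg$labels, oracle)
})

test_that("labels are invariant to polarity flip and positive rescaling of the data", {
  tm <- make_canonical_templates()
  rec <- random_recording(19, 800, seed = 23)
  seg <- assign_labels(rec, tm, threshold = 0.3)
  flip <- rec; flip$data <- -rec$data
  scl <- rec; scl$data <- rec$data * 40
  expect_identical(assign_labels(flip, tm, threshold = 0.3)$labels, seg$labels)
  expect_identical(assign_labels(scl, tm, threshold = 0.3)$labels, seg$labels)
})

test_that("smoothing is the identity at factor 0 and a fixed point on uniform labels", {
  tm <- make_canonical_templates()
  rec <- random_recording(19, 500, seed = 24)
  seg <- assign_labels(rec, tm, threshold = 0.3)
  s0 <- smooth_labels(seg, rec, tm, factor = 0)
  expect_identical(s0$labels, seg$labels)
  # uniform sequence: data = one map everywhere -> smoothing cannot change it
  udata <- tm$maps["D", ] %o% runif(300, 0.5, 2)
  urec <- eeg_recording(udata, 250, tm$channel_labels)
  useg <- assign_labels(urec, tm)
  expect_identical(unique(useg$labels), 4L)
  expect_identical(smooth_labels(useg, urec, tm)$labels, useg$labels)
})

test_that("smoothing absorbs a one-sample flicker with near-tied correlations", {
  # three exactly orthonormal zero-mean maps give full control of the scores
  set.seed(25)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(19 * 3), 19))))[, 2:4]
  maps <- ms_mapset(t(q), channel_labels = montage_1020_19())
  # ...AAABAAA... where the flicker sample barely prefers map 2 over map 1
  blend <- microspect:::normalize_topography(0.52 * q[, 2] + 0.48 * q[, 1])
  data <- cbind(q[, 1] %o% rep(1, 3), blend, q[, 1] %o% rep(1, 3))
  rec <- eeg_recording(data, 250, montage_1020_19())
  seg <- assign_labels(rec, maps)
  expect_identical(seg$labels, c(1L, 1L, 1L, 2L, 1L, 1L, 1L))
  sm <- smooth_labels(seg, rec, maps, window = 3L, factor = 2)
  expect_identical(sm$labels, rep(1L, 7))
})

test_that("minimum-duration rule splits short runs per the neighbor rule", {
  # interior short run: A A A B B C C C -> split 1 + 1
  seg <- segmentation_from_labels(c(1, 1, 1, 2, 2, 3, 3, 3), k = 3)
  out <- enforce_min_duration(seg, min_samples = 3L)
  expect_identical(out$labels, as.integer(c(1, 1, 1, 1, 3, 3, 3, 3)))
  # run of exactly min_samples is untouched
  seg2 <- segmentation_from_labels(c(1, 1, 1, 2, 2, 2, 3, 3, 3), k = 3)
  expect_identical(enforce_min_duration(seg2, 3L)$labels, seg2$labels)
  # short run at the start is absorbed entirely into its right neighbor
  seg3 <- segmentation_from_labels(c(2, 1, 1, 1, 1), k = 2)
  expect_identical(enforce_min_duration(seg3, 3L)$labels,
                   rep(1L, 5))
  # and at the end into its left neighbor
  seg4 <- segmentation_from_labels(c(1, 1, 1, 1, 2), k = 2)
  expect_identical(enforce_min_duration(seg4, 3L)$labels, rep(1L, 5))
  # iterative: the midpoint split can create a new short run that is re-fixed
  seg5 <- segmentation_from_labels(c(1, 1, 1, 1, 2, 2, 3, 3, 4, 4, 4, 4), k = 4)
  out5 <- enforce_min_duration(seg5, 3L)
  r5 <- rle(out5$labels)
  expect_true(all(r5$lengths >= 3))
  # recording shorter than the rule: warned, unchanged
  seg6 <- segmentation_from_labels(c(1, 2), k = 2)
  expect_warning(out6 <- enforce_min_duration(seg6, 3L), "shorter")
  expect_identical(out6$labels, seg6$labels)
})

test_that("temporal measures follow the run-length definitions with boundary censoring", {
  # single run covering everything: counted once, duration censored
  seg <- segmentation_from_labels(rep(1, 250), sfreq = 250, k = 2)
  m <- compute_measures(seg)
  expect_equal(m$occurrence, c(1, 0))
  expect_equal(m$coverage, c(1, 0))
  expect_equal(m$mean_duration, c(0, 0))   # boundary-truncated
  expect_identical(m$present, c(TRUE, FALSE))
  # strict alternation in 100-sample runs
  seg2 <- segmentation_from_labels(rep(rep(1:2, 10), each = 100)[1:2000],
                                   sfreq = 250, k = 2)
  m2 <- compute_measures(seg2)
  expect_equal(m2$coverage, c(0.5, 0.5))
  expect_equal(m2$mean_duration, c(400, 400))
  expect_equal(m2$occurrence, c(1.25, 1.25))
  # all unassigned
  seg3 <- segmentation_from_labels(rep(NA_integer_, 100), k = 2)
  m3 <- compute_measures(seg3)
  expect_equal(m3$coverage, c(0, 0))
  expect_equal(attr(m3, "unassigned_fraction"), 1)
  # coverages + unassigned always sum to one
  set.seed(26)
  lab <- sample(c(NA, 1:3), 5000, replace = TRUE)
  m4 <- compute_measures(segmentation_from_labels(lab, k = 3))
  expect_equal(sum(m4$coverage) + attr(m4, "unassigned_fraction"), 1,
               tolerance = 1e-9)
})

test_that("runs crossing an epoch seam are censored from mean duration only", {
  labels <- c(rep(1, 50), rep(2, 100), rep(1, 50))
  seg <- segmentation_from_labels(labels, sfreq = 250, k = 2, seams = 100L)
  m <- compute_measures(seg)
  # map 2's only run spans the seam: occurrence and coverage keep it
  expect_equal(m$occurrence[2], 1 / (200 / 250))
  expect_equal(m$coverage[2], 0.5)
  expect_equal(m$mean_duration[2], 0)
})

test_that("coverage is approximately occurrence x duration for interior-rich maps", {
  cfg <- quick_config(duration = 40, snr = 8)
  tm <- make_canonical_templates()
  s <- simulate_subject(cfg, 1, 77)
  meas <- band_pipeline(s$recording, tm,
                        bands = default_bands()["broadband"])
  ok <- meas$occurrence > 0.25          # >= 10 runs in 40 s
  expect_true(any(ok))
  expect_equal(meas$coverage[ok],
               (meas$occurrence * meas$mean_duration / 1000)[ok],
               tolerance = 0.10)
})

test_that("band_pipeline equals running the stages individually for broadband", {
  cfg <- quick_config(duration = 10)
  tm <- make_canonical_templates()
  s <- simulate_subject(cfg, 2, 31)
  bb <- default_bands()$broadband
  via_pipeline <- band_pipeline(s$recording, tm, bands = list(bb))
  filtered <- average_reference(bandpass(s$recording, bb))
  seg <- enforce_min_duration(
    smooth_labels(assign_labels(filtered, tm), filtered, tm), 3L)
  manual <- compute_measures(seg)
  expect_equal(via_pipeline$occurrence, manual$occurrence)
  expect_equal(via_pipeline$mean_duration, manual$mean_duration)
  expect_equal(via_pipeline$coverage, manual$coverage)
  expect_equal(via_pipeline$group, rep(2L, 5))
})

test_that("delta-band backfit of pure alpha content degenerates visibly", {
  tm <- make_canonical_templates()
  sfreq <- 250; t <- (0:(10 * sfreq - 1)) / sfreq
  data <- tm$maps["C", ] %o% sin(2 * pi * 10 * t)    # pure 10 Hz map C
  rec <- eeg_recording(data, sfreq, tm$channel_labels)
  meas <- band_pipeline(rec, tm, bands = default_bands()["delta"])
  # out-of-band content: either mostly unassigned or a near-uniform labeling
  degenerate <- meas$unassigned_fraction[1] > 0.5 || max(meas$coverage) > 0.9
  expect_true(degenerate)
})
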