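# Phase segmentation, time normalization, feature-matrix assembly,
# z-normalization and noise substitution.

test_that("segmentation recovers the generator's phase bounds within 5 frames", {
  rec <- small_recordings()
  curves <- fit_all_calibrations(rec)
  for (tr in rec$trials[c(1, 8, 15)]) {
    pr <- process_trial(tr, curves[[tr$subject_id]])
    seg <- segment_phases(pr)
    b <- tr$true_phase_bounds
    expect_lte(abs(seg$movement_onset - b[["movement_onset"]]), 5)
    expect_lte(abs(seg$contact_onset - b[["contact_onset"]]), 5)
    expect_lte(abs(seg$release_onset - b[["release_onset"]]), 5)
    expect_lte(abs(seg$movement_end - b[["movement_end"]]), 5)
  }
})

test_that("segmentation fails loudly without contact or movement", {
  quiet <- list(wrist_speed = c(rep(0, 50), rep(60, 100), rep(0, 50)),
                forces = matrix(0, 200, 5))
  expect_error(segment_phases(quiet), class = "graspid_segmentation_error")
  still <- list(wrist_speed = rep(0, 200),
                forces = matrix(1, 200, 5))
  expect_error(segment_phases(still), class = "graspid_segmentation_error")
})

test_that("clean step signals give exact boundary recovery", {
  speed <- rep(0, 400); speed[51:350] <- 60
  force <- matrix(0, 400, 5); force[151:250, ] <- 1
  seg <- segment_phases(list(wrist_speed = speed, forces = force))
  expect_equal(seg$movement_onset, 51)
  expect_equal(seg$contact_onset, 151)
  expect_equal(seg$release_onset, 251)
  expect_equal(seg$movement_end, 350)
})

test_that("time normalization is exact on ramps and idempotent at length 500", {
  ramp <- seq(0, 1, length.out = 800)
  y <- time_normalize(ramp, 500)
  expect_length(y, 500)
  expect_equal(y[1], 0)
  expect_equal(y[500], 1)
  expect_lt(max(abs(y - seq(0, 1, length.out = 500))), 1e-9)

  x <- rnorm(500)
  expect_equal(time_normalize(x, 500), x)
  expect_equal(time_normalize(rep(4, 37), 500), rep(4, 500))
  expect_error(time_normalize(1), class = "graspid_short_input_error")
})

test_that("feature matrices are 15 x 500 in every mode, with phase-equalized halves", {
  rec <- small_recordings()
  curves <- fit_all_calibrations(rec)
  tr <- rec$trials[[2]]
  pr <- process_trial(tr, curves[[tr$subject_id]])
  seg <- segment_phases(pr)

  for (mode in c("full", "no_release", "phase_equalized")) {
    fm <- assemble_feature_matrix(pr, seg, mode)
    expect_equal(dim(fm$values), c(15, 500))
    expect_false(anyNA(fm$values))
  }
  expect_error(assemble_feature_matrix(pr, seg, "bogus"),
               class = "graspid_config_error")

  # phase-equalized: columns 1-250 resample the reach span, 251-500 the grasp
  fm <- assemble_feature_matrix(pr, seg, "phase_equalized")
  reach_ref <- time_normalize(
    pr$angles[seg$movement_onset:seg$contact_onset, 1], 250)
  grasp_ref <- time_normalize(
    pr$angles[seg$contact_onset:seg$release_onset, 1], 250)
  expect_equal(unname(fm$values[1, 1:250]), reach_ref)
  expect_equal(unname(fm$values[1, 251:500]), grasp_ref)
})

test_that("full-mode angle rows reproduce the templates on a noise-free trial", {
  cfg <- noise_free_config(seed = 21)
  p <- generate_subject_profile(cfg, 1)
  tr <- generate_trial(p, "O1", 1)
  curves <- lapply(generate_calibration(p), fit_calibration)
  pr <- process_trial(tr, curves)
  seg <- segment_phases(pr)
  fm <- assemble_feature_matrix(pr, seg, "full")
  truth <- time_normalize(
    tr$true_angles[seg$movement_onset:seg$movement_end, 1], 500)
  expect_lt(max(abs(fm$values[1, ] - truth)), 1)
})

test_that("uniform time stretching changes the feature matrix only by resampling error", {
  t1 <- seq(0, 1, length.out = 301)
  t2 <- seq(0, 1, length.out = 601)   # same movement, twice the duration
  mk <- function(tg) {
    ang <- vapply(1:10, function(j) 40 + 20 * sin(2 * pi * tg + j),
                  numeric(length(tg)))
    frc <- vapply(1:5, function(j) pmax(0, sin(pi * tg))* j,
                  numeric(length(tg)))
    n <- length(tg)
    list(subject_id = "S", object_id = "O", trial_index = 1,
         angles = ang, forces = frc, wrist_speed = rep(0, n))
  }
  seg1 <- list(movement_onset = 1, contact_onset = 101, release_onset = 201,
               movement_end = 301)
  seg2 <- list(movement_onset = 1, contact_onset = 201, release_onset = 401,
               movement_end = 601)
  f1 <- assemble_feature_matrix(mk(t1), seg1, "full")
  f2 <- assemble_feature_matrix(mk(t2), seg2, "full")
  expect_lt(max(abs(f1$values - f2$values)), 0.01 * max(abs(f1$values)))
})

test_that("z-normalization pools angle and force statistics separately", {
  rec <- small_recordings()
  ext <- extract_features(rec)
  ds <- normalize_dataset(ext$matrices)
  expect_equal(ncol(ds$X), 7500)

  force_rows <- seq(3, 15, by = 3)
  frc_cols <- unlist(lapply(force_rows, function(r) (r - 1) * 500 + 1:500))
  ang_cols <- setdiff(seq_len(7500), frc_cols)
  expect_lt(abs(mean(ds$X[, ang_cols])), 1e-9)
  expect_lt(abs(sd(as.vector(ds$X[, ang_cols])) - 1), 1e-3)
  expect_lt(abs(mean(ds$X[, frc_cols])), 1e-9)
  expect_lt(abs(sd(as.vector(ds$X[, frc_cols])) - 1), 1e-3)

  expect_error(normalize_dataset(ext$matrices[1]),
               class = "graspid_config_error")
})

test_that("angles-only view is the exact angle-row subset, length 5000", {
  rec <- small_recordings()
  ext <- extract_features(rec)
  full <- normalize_dataset(ext$matrices, "all")
  ang <- normalize_dataset(ext$matrices, "angles")
  expect_equal(ncol(ang$X), 5000)
  force_rows <- seq(3, 15, by = 3)
  ang_cols <- unlist(lapply(setdiff(1:15, force_rows),
                            function(r) (r - 1) * 500 + 1:500))
  expect_equal(ang$X, full$X[, ang_cols])
})

test_that("noise substitution keeps chosen rows and re-draws the rest", {
  d <- simulate_feature_dataset(n_subjects = 4, n_trials = 10,
                                n_samples = 100, seed = 3)
  expect_identical(substitute_features(d, 1:15), d)
  expect_error(substitute_features(d, integer(0)),
               class = "graspid_config_error")

  keep <- c(1, 4, 6, 9, 11, 13)
  sub <- substitute_features(d, keep, seed = 77)
  keep_cols <- unlist(lapply(keep, function(r) (r - 1) * 100 + 1:100))
  expect_identical(sub$X[, keep_cols], d$X[, keep_cols])

  noise <- sub$X[, setdiff(seq_len(ncol(d$X)), keep_cols)]
  expect_gt(length(noise), 1e4)
  expect_lt(abs(mean(noise)), 0.05)
  expect_lt(abs(sd(as.vector(noise)) - 1), 0.05)

  # deterministic given the seed
  expect_identical(sub$X, substitute_features(d, keep, seed = 77)$X)
})

test_that("non-contact force noise carries no subject information", {
  # phase-equalized matrices: reach-half force samples are N(0,1); a
  # classifier on those samples alone must sit at chance
  rec <- small_recordings()
  ext <- extract_features(rec, mode = "phase_equalized")
  ds <- normalize_dataset(ext$matrices)
  force_rows <- seq(3, 15, by = 3)
  cols <- unlist(lapply(force_rows, function(r) (r - 1) * 500 + 1:250))
  emb <- embed_tsne(ds$X[, cols], dims = 2, perplexity = 5, seed = 1)
  cv <- graspid:::.cv_on_coords(emb$coords, ds$subject, 10, 5, 1)
  n_classes <- length(unique(ds$subject))
  expect_lt(mean(cv$per_fold_accuracy), 1 / n_classes + 0.3)
})
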