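# Synthetic grasp-recording generator: design counts, determinism,
# degeneracies, and the statistical contract of the template perturbations.

test_that("dataset size follows the study design", {
  cfg <- grasp_config(n_subjects = 2, n_objects = 3, n_trials_per_object = 4,
                      seed = 3)
  rec <- generate_dataset(cfg, calibrations = FALSE)
  expect_length(rec$trials, 24)
  per_subject <- table(vapply(rec$trials, `[[`, "", "subject_id"))
  expect_true(all(per_subject == 12))

  cfg1 <- grasp_config(n_subjects = 1, n_objects = 1, n_trials_per_object = 1)
  expect_length(generate_dataset(cfg1, calibrations = FALSE)$trials, 1)
})

test_that("generation is deterministic given the seed, with disjoint streams", {
  cfg <- grasp_config(n_subjects = 2, n_objects = 1, n_trials_per_object = 2,
                      seed = 11)
  p1 <- generate_subject_profile(cfg, 1)
  p2 <- generate_subject_profile(cfg, 1)
  expect_identical(p1, p2)

  t1 <- generate_trial(p1, "O1", 1)
  t2 <- generate_trial(p1, "O1", 1)
  expect_identical(t1, t2)

  # different trial index -> different realization
  t3 <- generate_trial(p1, "O1", 2)
  expect_false(identical(t1$marker_block, t3$marker_block))
})

test_that("zero subject effect degenerates to identical templates", {
  cfg <- grasp_config(n_subjects = 3, n_objects = 1, n_trials_per_object = 1,
                      subject_effect_scale = 0, seed = 5)
  tg <- seq(0, 1, length.out = 50)
  a1 <- angle_templates(generate_subject_profile(cfg, 1), tg)
  a2 <- angle_templates(generate_subject_profile(cfg, 2), tg)
  expect_equal(a1, a2)
  f1 <- force_templates(generate_subject_profile(cfg, 1), tg)
  f2 <- force_templates(generate_subject_profile(cfg, 3), tg)
  expect_equal(f1, f2)
})

test_that("trials are reproducible and noise-free trials repeat exactly", {
  cfg <- noise_free_config(seed = 9)
  p <- generate_subject_profile(cfg, 1)
  t1 <- generate_trial(p, "O1", 1)
  # same stream: identical; different trial of the same subject/object
  # differs only through phase-duration jitter and rigid pose
  t2 <- generate_trial(p, "O1", 1)
  expect_identical(t1$marker_block, t2$marker_block)
  expect_identical(t1$force_block, t2$force_block)
})

test_that("subject-template perturbation has the configured pointwise spread", {
  cfg <- grasp_config(n_subjects = 31, n_objects = 1, n_trials_per_object = 1,
                      subject_effect_scale = 1, seed = 17)
  tg <- seq(0.05, 0.95, length.out = 21)
  pop <- graspid:::.angle_population(tg)
  n_reps <- 120
  dev <- array(NA_real_, c(n_reps, length(tg)))
  for (r in seq_len(n_reps)) {
    cfg_r <- grasp_config(n_subjects = 31, n_objects = 1,
                          n_trials_per_object = 1, subject_effect_scale = 1,
                          seed = 1000 + r)
    a <- angle_templates(generate_subject_profile(cfg_r, 1), tg)
    dev[r, ] <- a[, 3] - pop[, 3]   # one representative angle series
  }
  ptwise_sd <- apply(dev, 2, sd)
  expect_true(all(abs(ptwise_sd - 1) < 0.2))
})

test_that("template invariants hold: angle bounds and force endpoints", {
  cfg <- grasp_config(n_subjects = 5, n_objects = 2, n_trials_per_object = 1,
                      subject_effect_scale = 12, seed = 23)
  tg <- seq(0, 1, length.out = 101)
  for (i in 1:5) {
    p <- generate_subject_profile(cfg, i)
    a <- angle_templates(p, tg, "O1")
    expect_true(all(a >= 0 & a <= 180))
    f <- force_templates(p, tg, "O1")
    expect_true(all(f >= 0))
    expect_equal(unname(f[1, ]), rep(0, 5))
    expect_equal(unname(f[101, ]), rep(0, 5))
    expect_gt(p$hand_size, 0)
  }
})

test_that("trial blocks satisfy the structural invariants", {
  rec <- small_recordings()
  tr <- rec$trials[[1]]
  expect_equal(dim(tr$marker_block)[3], 20)
  expect_equal(nrow(tr$force_block),
               8 * dim(tr$marker_block)[1])
  expect_true(all(is.finite(tr$marker_block)))
  expect_equal(sum(tr$marker_roles == "phalange"), 15)
  expect_equal(sum(tr$marker_roles == "palm"), 3)
  expect_equal(sum(tr$marker_roles == "wrist"), 2)
  b <- tr$true_phase_bounds
  expect_true(all(diff(b) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(grasp_config(n_subjects = 0), class = "graspid_config_error")
  expect_error(grasp_config(subject_effect_scale = -1),
               class = "graspid_config_error")
  expect_error(grasp_config(force_rate = 1000),
               class = "graspid_config_error")
  expect_error(grasp_config(spring_constant = 0),
               class = "graspid_config_error")
  cfg <- grasp_config(n_subjects = 2)
  expect_error(generate_subject_profile(cfg, 3),
               class = "graspid_config_error")
})

test_that("between-subject feature variance grows with the effect scale", {
  # extracted-feature spread across subjects at three effect settings
  spread_at <- function(scale) {
    cfg <- grasp_config(n_subjects = 6, n_objects = 1,
                        n_trials_per_object = 1,
                        subject_effect_scale = scale, trial_noise_scale = 0,
                        marker_noise_sd = 0, mains_noise_amplitude = 0,
                        sensor_noise_sd = 0,
                        phase_duration_ranges = fixed_phase_ranges, seed = 31)
    angs <- vapply(seq_len(6), function(i) {
      tr <- generate_trial(generate_subject_profile(cfg, i), "O1", 1, cfg)
      a <- extract_joint_angles(tr, filter_cutoff_hz = NULL)$angles
      colMeans(a)
    }, numeric(10))
    mean(apply(angs, 1, sd))
  }
  s <- vapply(c(0, 3, 9), spread_at, numeric(1))
  expect_true(all(diff(s) > 0))
})
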