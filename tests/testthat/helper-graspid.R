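# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

# brute-force weighted-kNN oracle: plain loops, independent of the package's
# vote implementation (used for exact-equivalence checks)
brute_wknn <- function(train, labels, query, k, eps = 1e-12) {
  labels <- as.character(labels)
  out <- character(nrow(query))
  for (q in seq_len(nrow(query))) {
    d2 <- numeric(nrow(train))
    for (i in seq_len(nrow(train)))
      d2[i] <- sum((query[q, ] - train[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- list()
    for (i in nn) {
      lb <- labels[i]
      votes[[lb]] <- (votes[[lb]] %||% 0) + 1 / max(d2[i], eps^2)
    }
    cls <- sort(names(votes))
    best <- cls[1]
    for (lb in cls) if (votes[[lb]] > votes[[best]]) best <- lb
    out[q] <- best
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- graspid:::with_seed

# mean silhouette width from coordinates and labels (plain implementation)
silhouette_mean <- function(coords, labels) {
  labels <- as.character(labels)
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(lv) mean(D[i, labels == lv]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# noise-free generator configuration: deterministic templates in, exact
# geometry out (used by the round-trip tests)
noise_free_config <- function(...) {
  grasp_config(n_subjects = 2, n_objects = 1, n_trials_per_object = 1,
               trial_noise_scale = 0, marker_noise_sd = 0,
               mains_noise_amplitude = 0, sensor_noise_sd = 0, ...)
}

# fixed phase durations: removes between-subject timing differences so that
# subject_effect_scale is the only subject-specific signal
fixed_phase_ranges <- list(reach = c(1, 1), grasp = c(1.5, 1.5),
                           release = c(1, 1))

# small processed+extracted dataset cache (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

small_recordings <- function() {
  if (is.null(.fixture_env$rec)) {
    .fixture_env$rec <- generate_dataset(
      grasp_config(n_subjects = 4, n_objects = 2, n_trials_per_object = 3,
                   subject_effect_scale = 8, trial_noise_scale = 0.8,
                   seed = 42))
  }
  .fixture_env$rec
}

small_datasets <- function() {
  if (is.null(.fixture_env$ds)) {
    rec <- small_recordings()
    ext <- extract_features(rec)
    .fixture_env$ext <- ext
    .fixture_env$ds <- build_object_datasets(ext$matrices,
                                             hand_sizes = hand_sizes(rec))
  }
  .fixture_env$ds
}
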