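# Phase segmentation, time normalization, 15 x 500 feature-matrix assembly,
# population z-normalization, and noise substitution.

#' Process one trial into synchronized angle and force series
#'
#' Runs the kinematic chain (filtering + angle extraction) and the kinetic
#' chain (mains bandstop, decimation to the kinematic rate, voltage-to-force
#' conversion) and aligns the two at the kinematic rate.
#'
#' @param trial a `grasp_trial`.
#' @param curves named list of `grasp_calibration` curves, one per finger.
#' @param filter_cutoff_hz trajectory low-pass cutoff (Hz); `NULL` disables.
#' @return list with `angles` (frames x 10, deg), `forces` (frames x 5, N),
#'   `wrist_speed` (mm/s), `rate_hz`, and the trial identifiers.
#' @export
process_trial <- function(trial, curves, filter_cutoff_hz = 15) {
  ang <- extract_joint_angles(trial, filter_cutoff_hz)
  factor <- trial$force_rate / trial$kinematic_rate
  volts <- bandstop_mains(trial$force_block, rate_hz = trial$force_rate)
  volts <- downsample_to_kinematic_rate(volts, factor)
  forces <- voltage_to_force(curves, volts)
  T_k <- min(nrow(ang$angles), nrow(forces))
  list(subject_id = trial$subject_id, object_id = trial$object_id,
       trial_index = trial$trial_index,
       angles = ang$angles[seq_len(T_k), , drop = FALSE],
       forces = forces[seq_len(T_k), , drop = FALSE],
       wrist_speed = ang$wrist_speed[seq_len(T_k)],
       rate_hz = ang$rate_hz)
}

#' Segment a trial into reach, grasp and release phases
#'
#' Movement onset/end come from the wrist-speed trace crossing a threshold
#' (sustained for `min_frames` consecutive frames, a debouncing hysteresis);
#' contact and release come from the total fingertip force crossing a force
#' threshold with the same debouncing.
#'
#' @param processed a processed trial from [process_trial()] (or any list
#'   with `forces`, `wrist_speed`).
#' @param speed_threshold wrist-speed threshold (mm/s).
#' @param force_threshold total-force threshold (N).
#' @param min_frames minimum run length (frames) for a crossing to count.
#' @return list of frame indices `movement_onset`, `contact_onset`,
#'   `release_onset`, `movement_end` (strictly increasing).
#' @export
segment_phases <- function(processed, speed_threshold = 8,
                           force_threshold = 0.25, min_frames = 3) {
  runs_of <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_frames
    cbind(start = starts[keep], end = ends[keep])
  }
  mv <- runs_of(processed$wrist_speed > speed_threshold)
  if (nrow(mv) == 0)
    stop_graspid("graspid_segmentation_error", "no movement detected (wrist speed)")
  total_force <- rowSums(processed$forces)
  ct <- runs_of(total_force > force_threshold)
  if (nrow(ct) == 0)
    stop_graspid("graspid_segmentation_error",
                 "no object contact detected (total fingertip force)")
  seg <- list(movement_onset = unname(mv[1, "start"]),
              contact_onset = unname(ct[1, "start"]),
              release_onset = unname(ct[nrow(ct), "end"] + 1L),
              movement_end = unname(mv[nrow(mv), "end"]))
  if (!(seg$movement_onset < seg$contact_onset &&
        seg$contact_onset < seg$release_onset &&
        seg$release_onset < seg$movement_end))
    stop_graspid("graspid_segmentation_error",
                 "inconsistent phase boundaries (onset %d, contact %d, release %d, end %d)",
                 seg$movement_onset, seg$contact_onset, seg$release_onset,
                 seg$movement_end)
  seg
}

#' Resample a series to a fixed length
#'
#' Linear-interpolation resampling on a normalized `[0, 1]` time axis to
#' exactly `target_length` samples, preserving both endpoints.
#'
#' @param series_block numeric vector or `frames x k` matrix.
#' @param target_length output length.
#' @return resampled vector or `target_length x k` matrix.
#' @export
#' @examples
#' time_normalize(seq(0, 1, length.out = 800))[c(1, 500)]
time_normalize <- function(series_block, target_length = 500) {
  one <- function(x) {
    if (length(x) < 2)
      stop_graspid("graspid_short_input_error",
                   "cannot time-normalize a series of length %d", length(x))
    approx(seq(0, 1, length.out = length(x)), x,
           xout = seq(0, 1, length.out = target_length))$y
  }
  if (is.matrix(series_block)) {
    out <- apply(series_block, 2, one)
    colnames(out) <- colnames(series_block)
    out
  } else one(series_block)
}

#' Assemble the 15 x 500 feature matrix of one trial
#'
#' Crops the processed series to the analysed time span, time-normalizes to
#' 500 samples and interleaves the ten angle rows with the five force rows
#' in the fixed feature order. Three croppings are supported:
#' `"full"` (movement onset to movement end), `"no_release"` (onset to
#' object release), and `"phase_equalized"` (reach resampled to 250 samples,
#' grasp to 250, concatenated). In the latter two modes force samples from
#' non-contact spans are replaced by standard-normal noise (drawn from the
#' caller's RNG stream), matching the convention that non-contact forces
#' are pure noise on the normalized scale.
#'
#' @param processed a processed trial from [process_trial()].
#' @param segmentation phase boundaries from [segment_phases()].
#' @param mode one of `"full"`, `"no_release"`, `"phase_equalized"`.
#' @param target_length number of output samples per feature.
#' @return an object of class `grasp_features`: list with `values`
#'   (15 x 500 matrix, rows in [feature_names()] order), identifiers and
#'   `mode`.
#' @export
assemble_feature_matrix <- function(processed, segmentation,
                                    mode = c("full", "no_release",
                                             "phase_equalized"),
                                    target_length = 500) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop_graspid("graspid_config_error",
                                                    "unknown feature-matrix mode"))
  seg <- segmentation
  crop <- function(from, to, len) {
    idx <- from:to
    cbind(time_normalize(processed$angles[idx, , drop = FALSE], len),
          time_normalize(processed$forces[idx, , drop = FALSE], len))
  }
  half <- target_length / 2
  if (mode == "full") {
    blk <- crop(seg$movement_onset, seg$movement_end, target_length)
    noise_cols <- integer(0)
  } else if (mode == "no_release") {
    blk <- crop(seg$movement_onset, seg$release_onset, target_length)
    n_reach <- seg$contact_onset - seg$movement_onset
    n_total <- seg$release_onset - seg$movement_onset
    noise_cols <- seq_len(max(0, round(target_length * n_reach / n_total)))
  } else {
    blk <- rbind(crop(seg$movement_onset, seg$contact_onset, half),
                 crop(seg$contact_onset, seg$release_onset, half))
    noise_cols <- seq_len(half)
  }
  # blk: target_length x 15 (10 angles then 5 forces); reorder to the
  # interleaved per-finger feature order and transpose to 15 x 500
  ang <- t(blk[, 1:10, drop = FALSE])
  frc <- t(blk[, 11:15, drop = FALSE])
  if (length(noise_cols))
    frc[, noise_cols] <- rnorm(length(noise_cols) * 5)
  values <- matrix(NA_real_, 15, target_length,
                   dimnames = list(feature_names(), NULL))
  for (f in 1:5) {
    values[3 * f - 2, ] <- ang[2 * f - 1, ]
    values[3 * f - 1, ] <- ang[2 * f, ]
    values[3 * f, ] <- frc[f, ]
  }
  structure(list(values = values, subject_id = processed$subject_id,
                 object_id = processed$object_id,
                 trial_index = processed$trial_index, mode = mode),
            class = "grasp_features")
}

#' @export
print.grasp_features <- function(x, ...) {
  cat(sprintf("Feature matrix (%s): %d x %d, subject %s, object %s, trial %s\n",
              x$mode, nrow(x$values), ncol(x$values),
              x$subject_id %||% "?", x$object_id %||% "?",
              x$trial_index %||% "?"))
  invisible(x)
}

#' Pool trials into a z-normalized dataset matrix
#'
#' Flattens each trial's feature matrix row-major (feature by feature) into
#' one vector and z-normalizes with two pooled (mean, sd) pairs computed
#' over all trials together: one over all angle entries, one over all force
#' entries, so the final vectors are dimensionless.
#'
#' @param matrices list of `grasp_features` objects (same mode and shape).
#' @param features `"all"` (15 rows, length 7500 at 500 samples) or
#'   `"angles"` (10 angle rows only, length 5000).
#' @param hand_sizes optional named vector (mm) keyed by subject id.
#' @return an object of class `grasp_dataset`: list with `X` (trials x
#'   flattened features), `subject`, `object`, `trial`, `hand_size`,
#'   `feature_names`, `n_samples`, `mode` and `normalization`.
#' @export
normalize_dataset <- function(matrices, features = c("all", "angles"),
                              hand_sizes = NULL) {
  features <- match.arg(features)
  if (length(matrices) < 2)
    stop_graspid("graspid_config_error",
                 "need at least 2 trials to build a dataset")
  n_samples <- ncol(matrices[[1]]$values)
  force_rows <- seq(3, 15, by = 3)
  angle_rows <- setdiff(1:15, force_rows)

  all_ang <- unlist(lapply(matrices, function(m) m$values[angle_rows, ]))
  ang_mu <- mean(all_ang); ang_sd <- sd(all_ang)
  all_frc <- unlist(lapply(matrices, function(m) m$values[force_rows, ]))
  frc_mu <- mean(all_frc); frc_sd <- sd(all_frc)
  if (ang_sd < 1e-12 || (features == "all" && frc_sd < 1e-12))
    stop_graspid("graspid_degenerate_error",
                 "zero pooled standard deviation; cannot z-normalize")

  keep_rows <- if (features == "all") 1:15 else angle_rows
  X <- t(vapply(matrices, function(m) {
    v <- m$values
    v[angle_rows, ] <- (v[angle_rows, ] - ang_mu) / ang_sd
    v[force_rows, ] <- (v[force_rows, ] - frc_mu) / frc_sd
    as.vector(t(v[keep_rows, , drop = FALSE]))
  }, numeric(length(keep_rows) * n_samples)))

  subject <- vapply(matrices, function(m) as.character(m$subject_id), "")
  object <- vapply(matrices, function(m) as.character(m$object_id), "")
  trial <- vapply(matrices, function(m) as.integer(m$trial_index), 0L)
  hs <- if (!is.null(hand_sizes)) unname(hand_sizes[subject]) else rep(NA_real_, length(subject))

  structure(list(X = X, subject = subject, object = object, trial = trial,
                 hand_size = hs,
                 feature_names = feature_names()[keep_rows],
                 n_samples = n_samples,
                 mode = matrices[[1]]$mode,
                 normalization = list(angle = c(mean = ang_mu, sd = ang_sd),
                                      force = c(mean = frc_mu, sd = frc_sd))),
            class = "grasp_dataset")
}

#' @export
print.grasp_dataset <- function(x, ...) {
  cat(sprintf("Grasp dataset: %d trials x %d values (%d features x %d samples, mode '%s')\n",
              nrow(x$X), ncol(x$X), length(x$feature_names), x$n_samples,
              x$mode %||% "?"))
  cat(sprintf("  %d subjects, %d objects\n",
              length(unique(x$subject)), length(unique(x$object))))
  invisible(x)
}

# internal: build a grasp_dataset directly from components
.make_dataset <- function(X, subject, object = rep("O1", length(subject)),
                          trial = seq_along(subject), feature_names., n_samples,
                          mode = "full", hand_size = rep(NA_real_, length(subject))) {
  structure(list(X = X, subject = subject, object = object, trial = trial,
                 hand_size = hand_size, feature_names = feature_names.,
                 n_samples = n_samples, mode = mode,
                 normalization = NULL),
            class = "grasp_dataset")
}

#' Restrict a dataset to a subset of trials
#'
#' @param dataset a `grasp_dataset`.
#' @param idx logical or integer trial index.
#' @return the restricted `grasp_dataset`.
#' @export
subset_trials <- function(dataset, idx) {
  dataset$X <- dataset$X[idx, , drop = FALSE]
  for (f in c("subject", "object", "trial", "hand_size"))
    dataset[[f]] <- dataset[[f]][idx]
  dataset
}

# column indices of given feature rows in the flattened layout
.feature_cols <- function(dataset, rows) {
  s <- as.integer(dataset$n_samples)
  as.vector(vapply(as.integer(rows), function(r) (r - 1L) * s + seq_len(s),
                   integer(s)))
}

#' Replace non-kept feature rows by standard-normal noise
#'
#' Sensitivity-analysis primitive: feature rows not in `keep` are replaced,
#' independently per trial, by N(0, 1) samples, matching the distribution of
#' the z-normalized data, so the input dimensionality and scale of the
#' pipeline are unchanged.
#'
#' @param dataset a `grasp_dataset`.
#' @param keep integer indices (into `dataset$feature_names`) of the rows to
#'   keep; must be non-empty.
#' @param seed optional seed for the noise stream; `NULL` uses the current
#'   RNG state.
#' @return a new `grasp_dataset` with the substituted values.
#' @export
substitute_features <- function(dataset, keep, seed = NULL) {
  n_feat <- length(dataset$feature_names)
  if (length(keep) == 0)
    stop_graspid("graspid_config_error", "keep must name at least one feature")
  if (any(keep < 1 | keep > n_feat))
    stop_graspid("graspid_config_error", "keep indices outside 1:%d", n_feat)
  drop_rows <- setdiff(seq_len(n_feat), keep)
  if (length(drop_rows) == 0) return(dataset)
  cols <- .feature_cols(dataset, drop_rows)
  draw <- function() {
    dataset$X[, cols] <- rnorm(nrow(dataset$X) * length(cols))
    dataset
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# replace all columns outside [start, start + width - 1] (within each
# feature row's sample axis) by N(0,1); used by the time-window scan
substitute_time_window <- function(dataset, start, width, seed = NULL) {
  s <- as.integer(dataset$n_samples)
  start <- as.integer(start); width <- as.integer(width)
  if (width < 1 || width > s || start < 1 || start + width - 1 > s)
    stop_graspid("graspid_config_error", "invalid time window")
  keep_samples <- start:(start + width - 1L)
  drop_samples <- setdiff(seq_len(s), keep_samples)
  if (length(drop_samples) == 0) return(dataset)
  n_feat <- length(dataset$feature_names)
  cols <- as.vector(vapply(seq_len(n_feat),
                           function(r) (r - 1L) * s + drop_samples,
                           integer(length(drop_samples))))
  draw <- function() {
    dataset$X[, cols] <- rnorm(nrow(dataset$X) * length(cols))
    dataset
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
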