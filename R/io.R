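# Plain-text interchange formats: per-trial marker/force CSV pairs with a
# JSON metadata sidecar, per-finger calibration CSVs, a dataset manifest,
# and flattened dataset CSV export.

.trial_stem <- function(trial) {
  sprintf("%s_%s_T%02d", trial$subject_id, trial$object_id, trial$trial_index)
}

#' Write one trial to CSV + JSON files
#'
#' Writes `<stem>_markers.csv` (columns `frame`, `marker`, `x`, `y`, `z` in
#' mm), `<stem>_forces.csv` (columns `sample`, `f1`..`f5` in volts) and
#' `<stem>_meta.json` (identifiers, rates, marker roles, true phase bounds).
#'
#' @param trial a `grasp_trial`.
#' @param dir output directory (created if needed).
#' @return the metadata file path, invisibly.
#' @export
write_trial_files <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, .trial_stem(trial))
  mb <- trial$marker_block
  T_k <- dim(mb)[1]
  nm <- dimnames(mb)[[3]]
  mk <- data.frame(frame = rep(seq_len(T_k), times = 20),
                   marker = rep(nm, each = T_k),
                   x = as.vector(mb[, 1, ]), y = as.vector(mb[, 2, ]),
                   z = as.vector(mb[, 3, ]))
  utils::write.csv(mk, paste0(stem, "_markers.csv"), row.names = FALSE)
  fb <- as.data.frame(trial$force_block)
  names(fb) <- paste0("f", 1:5)
  utils::write.csv(cbind(sample = seq_len(nrow(fb)), fb),
                   paste0(stem, "_forces.csv"), row.names = FALSE)
  meta <- list(subject_id = trial$subject_id, object_id = trial$object_id,
               trial_index = trial$trial_index,
               kinematic_rate = trial$kinematic_rate,
               force_rate = trial$force_rate,
               marker_names = nm, marker_roles = trial$marker_roles,
               true_phase_bounds = as.list(trial$true_phase_bounds),
               files = list(markers = basename(paste0(stem, "_markers.csv")),
                            forces = basename(paste0(stem, "_forces.csv"))))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, "_meta.json"))
}

#' Read one trial back from its metadata sidecar
#'
#' @param meta_path path to a `*_meta.json` written by [write_trial_files()].
#' @return a `grasp_trial` (without generator-only ground truth).
#' @export
read_trial_files <- function(meta_path) {
  if (!file.exists(meta_path))
    stop_graspid("graspid_io_error", "cannot read '%s'", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dir <- dirname(meta_path)
  mk <- utils::read.csv(file.path(dir, meta$files$markers))
  fb <- utils::read.csv(file.path(dir, meta$files$forces))
  nm <- meta$marker_names
  T_k <- max(mk$frame)
  mb <- array(NA_real_, c(T_k, 3, length(nm)),
              dimnames = list(NULL, c("x", "y", "z"), nm))
  for (m in seq_along(nm)) {
    rows <- mk[mk$marker == nm[m], ]
    rows <- rows[order(rows$frame), ]
    mb[rows$frame, , m] <- as.matrix(rows[, c("x", "y", "z")])
  }
  force_block <- as.matrix(fb[, -1, drop = FALSE])
  colnames(force_block) <- FINGERS[seq_len(ncol(force_block))]
  structure(list(subject_id = meta$subject_id, object_id = meta$object_id,
                 trial_index = meta$trial_index, marker_block = mb,
                 marker_roles = meta$marker_roles, force_block = force_block,
                 kinematic_rate = meta$kinematic_rate,
                 force_rate = meta$force_rate,
                 true_phase_bounds = unlist(meta$true_phase_bounds)),
            class = "grasp_trial")
}

#' Write a subject's calibration recordings to CSV
#'
#' One file per finger, columns `repetition`, `sample`, `voltage`,
#' `displacement_mm`.
#'
#' @param calib named list of `grasp_calibration_recording` (per finger).
#' @param dir output directory.
#' @param subject_id used in file names.
#' @return written paths, invisibly.
#' @export
write_calibration_csv <- function(calib, dir, subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(calib, function(cr) {
    d <- do.call(rbind, lapply(seq_along(cr$repetitions), function(r)
      cbind(repetition = r, cr$repetitions[[r]])))
    p <- file.path(dir, sprintf("%s_calibration_%s.csv", subject_id, cr$finger))
    utils::write.csv(d, p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Read a calibration recording from CSV
#'
#' @param path CSV written by [write_calibration_csv()].
#' @param finger finger label.
#' @param spring_constant spring constant (N/mm).
#' @return a `grasp_calibration_recording`.
#' @export
read_calibration_csv <- function(path, finger, spring_constant = 0.45) {
  if (!file.exists(path))
    stop_graspid("graspid_io_error", "cannot read '%s'", path)
  d <- utils::read.csv(path)
  reps <- lapply(split(d, d$repetition), function(x)
    x[, c("sample", "voltage", "displacement_mm")])
  structure(list(finger = finger, repetitions = unname(reps),
                 spring_constant = spring_constant),
            class = "grasp_calibration_recording")
}

#' Write a full recording set to a directory with a manifest
#'
#' @param recordings a `grasp_recordings`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metas <- vapply(recordings$trials, write_trial_files, "", dir = dir)
  for (sid in names(recordings$calibrations %||% list()))
    write_calibration_csv(recordings$calibrations[[sid]], dir, sid)
  manifest <- list(n_trials = length(recordings$trials),
                   trials = basename(metas),
                   subjects = names(recordings$profiles),
                   hand_sizes = as.list(hand_sizes(recordings)),
                   objects = recordings$objects,
                   spring_constant = recordings$config$spring_constant,
                   seed = recordings$config$seed)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Serialize fitted calibration curves to JSON
#'
#' @param curves a single `grasp_calibration` or a named list of them.
#' @param path output JSON path.
#' @export
write_calibration_json <- function(curves, path) {
  if (inherits(curves, "grasp_calibration")) curves <- list(curves)
  payload <- lapply(curves, function(cc)
    list(finger = cc$finger, voltage = cc$voltage, force = cc$force,
         range = cc$range))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted calibration curves from JSON
#'
#' @param path JSON written by [write_calibration_json()].
#' @return named list of `grasp_calibration` objects.
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path))
    stop_graspid("graspid_io_error", "cannot read '%s'", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(payload) %||% length(payload)), function(i) {
    cc <- if (is.data.frame(payload)) lapply(payload, `[[`, i)
          else payload[[i]]
    structure(list(finger = cc$finger, voltage = unlist(cc$voltage),
                   force = unlist(cc$force), range = unlist(cc$range)),
              class = "grasp_calibration")
  })
  names(out) <- vapply(out, `[[`, "", "finger")
  out
}

#' Export a flattened dataset to CSV
#'
#' One row per trial: `subject`, `object`, `trial`, then the flattened
#' feature values.
#'
#' @param dataset a `grasp_dataset`.
#' @param path output CSV path.
#' @export
write_dataset_csv <- function(dataset, path) {
  d <- cbind(data.frame(subject = dataset$subject, object = dataset$object,
                        trial = dataset$trial), as.data.frame(dataset$X))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a flattened dataset back from CSV
#'
#' Validates the expected shape: identifier columns followed by
#' `n_features * n_samples` value columns in the fixed feature order.
#'
#' @param path CSV written by [write_dataset_csv()].
#' @param n_samples samples per feature row (500 in the reference design).
#' @return a `grasp_dataset`.
#' @export
read_dataset_csv <- function(path, n_samples = 500) {
  if (!file.exists(path))
    stop_graspid("graspid_io_error", "cannot read '%s'", path)
  d <- utils::read.csv(path)
  id_cols <- c("subject", "object", "trial")
  if (!all(id_cols %in% names(d)))
    stop_graspid("graspid_io_error",
                 "dataset CSV must carry subject/object/trial columns")
  X <- as.matrix(d[, setdiff(names(d), id_cols), drop = FALSE])
  if (ncol(X) %% n_samples != 0)
    stop_graspid("graspid_io_error",
                 "%d value columns are not a multiple of %d samples",
                 ncol(X), n_samples)
  n_feat <- ncol(X) / n_samples
  fn <- if (n_feat == 15) feature_names()
        else if (n_feat == 10) angle_names()
        else paste0("feature_", seq_len(n_feat))
  .make_dataset(unname(X), as.character(d$subject),
                as.character(d$object), d$trial,
                feature_names. = fn, n_samples = n_samples)
}

#' Validate trial files on disk
#'
#' Per-trial structural checks mirroring the rejection of trials with
#' missing data: marker count must be 20, marker coordinates finite for all
#' frames, the force block must have 5 channels and exactly
#' `force_rate / kinematic_rate` times as many samples as the marker block
#' has frames.
#'
#' @param paths character vector of `*_meta.json` paths, or a directory
#'   containing them, or a `manifest.json` path.
#' @return data frame with columns `trial`, `pass`, `reason`; every excluded
#'   trial appears with its reason (no silent drops).
#' @export
validate_trial_files <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, "_meta\\.json$", full.names = TRUE)
  if (length(paths) == 1 && grepl("manifest\\.json$", paths)) {
    mf <- jsonlite::read_json(paths, simplifyVector = TRUE)
    paths <- file.path(dirname(paths), mf$trials)
  }
  res <- lapply(paths, function(p) {
    trial <- basename(p)
    chk <- tryCatch({
      tr <- read_trial_files(p)
      ratio <- tr$force_rate / tr$kinematic_rate
      if (dim(tr$marker_block)[3] != 20)
        sprintf("marker count: %d != 20", dim(tr$marker_block)[3])
      else if (!all(is.finite(tr$marker_block)))
        "missing marker frames"
      else if (ncol(tr$force_block) != 5)
        sprintf("force channels: %d != 5", ncol(tr$force_block))
      else if (nrow(tr$force_block) != ratio * dim(tr$marker_block)[1])
        sprintf("rate ratio: %d force samples != %g x %d frames",
                nrow(tr$force_block), ratio, dim(tr$marker_block)[1])
      else NA_character_
    }, error = function(e) conditionMessage(e))
    data.frame(trial = trial, pass = is.na(chk),
               reason = ifelse(is.na(chk), "", chk))
  })
  do.call(rbind, res)
}
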