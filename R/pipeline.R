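# End-to-end pipeline: simulate (or load) -> calibrate -> extract ->
# segment -> assemble -> normalize -> per-object classification ->
# optional sensitivity scan, with a provenance record.

#' Fit all calibration curves of a recording set
#'
#' @param recordings a `grasp_recordings`.
#' @return nested named list: per subject, per finger, a `grasp_calibration`.
#' @export
fit_all_calibrations <- function(recordings) {
  lapply(recordings$calibrations, function(cal) lapply(cal, fit_calibration))
}

#' Extract per-trial feature matrices from a recording set
#'
#' Runs the full extraction chain on every trial: trajectory filtering and
#' angle extraction, force filtering / decimation / conversion, phase
#' segmentation, and feature-matrix assembly. Trials whose segmentation
#' fails are excluded and reported, never dropped silently.
#'
#' @param recordings a `grasp_recordings`.
#' @param mode time cropping/normalization mode (see
#'   [assemble_feature_matrix()]).
#' @param target_length samples per feature row.
#' @param filter_cutoff_hz trajectory low-pass cutoff.
#' @param noise_seed seed for the non-contact force-noise stream.
#' @return list with `matrices` (list of `grasp_features`) and `excluded`
#'   (data frame of excluded trials and reasons).
#' @export
extract_features <- function(recordings, mode = "full", target_length = 500,
                             filter_cutoff_hz = 15,
                             noise_seed = derive_seed(recordings$config$seed,
                                                      "assembly-noise")) {
  curves <- fit_all_calibrations(recordings)
  matrices <- list()
  excluded <- list()
  with_seed(noise_seed, {
    for (trial in recordings$trials) {
      res <- tryCatch({
        pr <- process_trial(trial, curves[[trial$subject_id]],
                            filter_cutoff_hz)
        seg <- segment_phases(pr)
        assemble_feature_matrix(pr, seg, mode, target_length)
      }, graspid_error = function(e) e)
      if (inherits(res, "grasp_features")) {
        matrices[[length(matrices) + 1L]] <- res
      } else {
        excluded[[length(excluded) + 1L]] <-
          data.frame(subject = trial$subject_id, object = trial$object_id,
                     trial = trial$trial_index,
                     reason = conditionMessage(res))
      }
    }
  })
  list(matrices = matrices,
       excluded = if (length(excluded)) do.call(rbind, excluded)
       else data.frame(subject = character(), object = character(),
                       trial = integer(), reason = character()))
}

#' Build per-object z-normalized datasets
#'
#' Groups feature matrices by object and z-normalizes each group over all
#' its subjects combined, the form consumed by the per-object
#' classification and sensitivity analyses.
#'
#' @param matrices list of `grasp_features` (from [extract_features()]).
#' @param features `"all"` or `"angles"`.
#' @param hand_sizes optional named vector (mm) by subject.
#' @param objects optional subset of object labels; `NULL` keeps all.
#' @param combine also return the pooled all-object dataset under
#'   `"combined"`?
#' @return named list of `grasp_dataset`, one per object (plus optionally
#'   `combined`).
#' @export
build_object_datasets <- function(matrices, features = "all",
                                  hand_sizes = NULL, objects = NULL,
                                  combine = FALSE) {
  objs <- vapply(matrices, function(m) as.character(m$object_id), "")
  keep_objs <- objects %||% sort(unique(objs))
  out <- lapply(keep_objs, function(ob)
    normalize_dataset(matrices[objs == ob], features, hand_sizes))
  names(out) <- keep_objs
  if (combine)
    out$combined <- normalize_dataset(matrices[objs %in% keep_objs],
                                      features, hand_sizes)
  out
}

# ---- configuration ----------------------------------------------------------

#' Assemble (and validate) a pipeline configuration
#'
#' @param config a named list or a YAML file path. Recognized top-level
#'   sections: `synthetic` (arguments of [grasp_config()]), `mode`,
#'   `features` (`"all"`/`"angles"`), `embedding` (`dims`, `perplexity`,
#'   `n_iter`), `knn` (`k`), `folds`, `sensitivity` (`enabled`, `min_size`,
#'   `max_size`, `n_repeats`), `seed`.
#' @return validated config list of class `grasp_pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("synthetic", "mode", "features", "embedding", "knn", "folds",
             "sensitivity", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_graspid("graspid_config_error", "unknown config fields: %s",
                 paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  cfg <- list(
    synthetic = do.call(grasp_config,
                        c(config$synthetic %||% list(),
                          if (is.null(config$synthetic$seed))
                            list(seed = derive_seed(seed, "synthetic")))),
    mode = config$mode %||% "full",
    features = config$features %||% "all",
    embedding = list(dims = config$embedding$dims %||% 3,
                     perplexity = config$embedding$perplexity %||% 12,
                     n_iter = config$embedding$n_iter %||% 500),
    knn = list(k = config$knn$k %||% 10),
    folds = config$folds %||% 5,
    sensitivity = list(enabled = isTRUE(config$sensitivity$enabled),
                       min_size = config$sensitivity$min_size %||% 2,
                       max_size = config$sensitivity$max_size %||% 14,
                       n_repeats = config$sensitivity$n_repeats %||% 3),
    seed = as.integer(seed))
  if (!cfg$mode %in% c("full", "no_release", "phase_equalized"))
    stop_graspid("graspid_config_error", "mode '%s' unknown", cfg$mode)
  if (!cfg$features %in% c("all", "angles"))
    stop_graspid("graspid_config_error", "features '%s' unknown", cfg$features)
  if (!cfg$embedding$dims %in% 2:3)
    stop_graspid("graspid_config_error", "embedding dims must be 2 or 3")
  class(cfg) <- "grasp_pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulates a recording set, extracts and normalizes features, classifies
#' subjects per object with the embed + weighted kNN + cross-validation
#' pipeline, optionally runs the feature-subset sensitivity scan, and
#' writes all artifacts (dataset CSV, per-object report JSON, confusion
#' CSVs, figures, provenance record) into `out_dir`.
#'
#' @param config a [pipeline_config()] input (list or YAML path).
#' @param out_dir output directory.
#' @param figures write PNG figures (skipped with a message if no graphics
#'   device is available)?
#' @return list with the per-object `grasp_cv` reports, the datasets, the
#'   exclusion table and (if enabled) the sensitivity result; invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("graspid_run_"),
                         figures = TRUE) {
  cfg <- if (inherits(config, "grasp_pipeline_config")) config
         else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  recordings <- generate_dataset(cfg$synthetic)
  ext <- extract_features(recordings, mode = cfg$mode)
  datasets <- build_object_datasets(ext$matrices, features = cfg$features,
                                    hand_sizes = hand_sizes(recordings))

  reports <- lapply(names(datasets), function(ob) {
    d <- datasets[[ob]]
    cross_validate(d, k_neighbors = cfg$knn$k, n_folds = cfg$folds,
                   seed = derive_seed(cfg$seed, "cv", ob),
                   dims = cfg$embedding$dims,
                   perplexity = cfg$embedding$perplexity,
                   n_iter = cfg$embedding$n_iter)
  })
  names(reports) <- names(datasets)

  sens <- NULL
  if (cfg$sensitivity$enabled) {
    subsets <- enumerate_subsets(length(datasets[[1]]$feature_names),
                                 cfg$sensitivity$min_size,
                                 cfg$sensitivity$max_size)
    sens <- sensitivity_scan(datasets, subsets,
                             n_repeats = cfg$sensitivity$n_repeats,
                             seed = derive_seed(cfg$seed, "sensitivity"),
                             dims = cfg$embedding$dims,
                             perplexity = cfg$embedding$perplexity,
                             n_iter = cfg$embedding$n_iter,
                             k_neighbors = cfg$knn$k, n_folds = cfg$folds)
    utils::write.csv(sens$table, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
  }

  for (ob in names(datasets))
    write_dataset_csv(datasets[[ob]],
                      file.path(out_dir, sprintf("dataset_%s.csv", ob)))
  utils::write.csv(ext$excluded, file.path(out_dir, "excluded_trials.csv"),
                   row.names = FALSE)
  report_json <- lapply(reports, function(r)
    list(mean_accuracy = r$mean_accuracy,
         per_fold_accuracy = r$per_fold_accuracy,
         k_neighbors = r$k_neighbors, n_folds = r$n_folds))
  jsonlite::write_json(report_json, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ob in names(reports))
    utils::write.csv(reports[[ob]]$confusion,
                     file.path(out_dir, sprintf("confusion_%s.csv", ob)))

  if (figures) {
    ok <- tryCatch({
      png(file.path(out_dir, "embedding_%d.png"), width = 900, height = 700)
      for (ob in names(datasets)) {
        emb <- embed_tsne(datasets[[ob]], dims = cfg$embedding$dims,
                          perplexity = cfg$embedding$perplexity,
                          seed = derive_seed(cfg$seed, "cv", ob, "tsne"))
        plot(emb, main = sprintf("object %s", ob))
      }
      dev.off()
      TRUE
    }, error = function(e) {
      message("figures skipped: ", conditionMessage(e))
      FALSE
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("graspid")),
    seed = cfg$seed,
    config = list(mode = cfg$mode, features = cfg$features,
                  embedding = cfg$embedding, knn = cfg$knn,
                  folds = cfg$folds,
                  synthetic = unclass(cfg$synthetic)[
                    setdiff(names(cfg$synthetic), "phase_duration_ranges")],
                  sensitivity = cfg$sensitivity),
    n_trials = length(recordings$trials),
    n_excluded = nrow(ext$excluded),
    flattened_width = ncol(datasets[[1]]$X),
    mean_accuracy = vapply(reports, `[[`, 0, "mean_accuracy"))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(reports = reports, datasets = datasets,
                 excluded = ext$excluded, sensitivity = sens,
                 out_dir = out_dir))
}
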