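# Exhaustive feature-subset sensitivity analysis with noise substitution:
# which of the 15 features (10 angles, 5 forces) carry the subject-specific
# information? Every subset of sizes 2-14 is scored by the same
# t-SNE + weighted kNN + cross-validation pipeline after replacing the
# non-chosen features by N(0,1) noise, repeated with fresh noise and
# embedding initializations and averaged.

#' Enumerate feature subsets
#'
#' All subsets of `n_features` features with sizes in
#' `[min_size, max_size]`, in deterministic order (size ascending,
#' lexicographic within size). For the canonical 15 features and sizes 2-14
#' this yields 32,751 subsets.
#'
#' @param n_features number of features.
#' @param min_size,max_size inclusive size bounds.
#' @return list of integer vectors.
#' @export
#' @examples
#' length(enumerate_subsets(15, 2, 14))  # 32751
enumerate_subsets <- function(n_features = 15, min_size = 2, max_size = 14) {
  if (min_size < 1 || min_size > max_size || max_size > n_features)
    stop_graspid("graspid_config_error",
                 "need 1 <= min_size <= max_size <= n_features")
  out <- vector("list", sum(choose(n_features, min_size:max_size)))
  k <- 0L
  for (s in min_size:max_size) {
    cc <- combn(n_features, s)
    for (j in seq_len(ncol(cc))) {
      k <- k + 1L
      out[[k]] <- cc[, j]
    }
  }
  out
}

.subset_key <- function(subset) paste(subset, collapse = "-")

#' Pipeline quality of one feature subset
#'
#' Replaces all features outside `subset` by standard-normal noise and runs
#' the unchanged t-SNE + weighted kNN + cross-validation pipeline; repeats
#' `n_repeats` times with fresh noise and embedding initializations (each
#' repeat's seed is a stable hash of `(seed, subset, repeat)`) and averages.
#'
#' @param dataset a z-normalized `grasp_dataset`.
#' @param subset integer indices of the features to keep.
#' @param n_repeats number of repeats to average.
#' @param labels class labels; defaults to subjects.
#' @param seed master seed.
#' @param dims,perplexity,n_iter,k_neighbors,n_folds pipeline parameters.
#' @return mean cross-validated accuracy (fraction in `[0, 1]`).
#' @export
subset_quality <- function(dataset, subset, n_repeats = 3, labels = NULL,
                           seed = 1, dims = 3, perplexity = 12, n_iter = 500,
                           k_neighbors = 10, n_folds = 5) {
  labels <- labels %||% dataset$subject
  accs <- vapply(seq_len(n_repeats), function(r) {
    rseed <- derive_seed(seed, "subset", .subset_key(subset), r)
    sub <- substitute_features(dataset, keep = subset,
                               seed = derive_seed(rseed, "noise"))
    cv <- cross_validate(sub, labels = labels, k_neighbors = k_neighbors,
                         n_folds = n_folds, seed = rseed, dims = dims,
                         perplexity = perplexity, n_iter = n_iter)
    cv$mean_accuracy
  }, numeric(1))
  mean(accs)
}

# fast scan engine over one dataset: per-feature squared-distance blocks are
# precomputed (squared Euclidean distance decomposes exactly over feature
# blocks), noise blocks are drawn once per (feature, repeat), and each
# subset's distance matrix is assembled by one matrix product per chunk.
.scan_one_dataset <- function(dataset, subsets, labels, n_repeats, seed,
                              dims, perplexity, n_iter, k_neighbors, n_folds,
                              chunk = 512L, tag = "scan") {
  X <- dataset$X
  n <- nrow(X)
  n_feat <- length(dataset$feature_names)
  labels <- as.character(labels)
  d2_real <- vapply(seq_len(n_feat), function(r)
    as.vector(.sq_dist(X[, .feature_cols(dataset, r), drop = FALSE])),
    numeric(n * n))
  quality <- matrix(0, length(subsets), n_repeats)
  keep_mat <- matrix(0, n_feat, length(subsets))
  for (j in seq_along(subsets)) keep_mat[subsets[[j]], j] <- 1

  for (r in seq_len(n_repeats)) {
    d2_noise <- with_seed(derive_seed(seed, tag, "noise", r), {
      vapply(seq_len(n_feat), function(f)
        as.vector(.sq_dist(matrix(rnorm(n * dataset$n_samples), n))),
        numeric(n * n))
    })
    for (lo in seq(1L, length(subsets), by = chunk)) {
      hi <- min(lo + chunk - 1L, length(subsets))
      K <- keep_mat[, lo:hi, drop = FALSE]
      D2_blk <- d2_real %*% K + d2_noise %*% (1 - K)
      for (j in lo:hi) {
        D2 <- matrix(D2_blk[, j - lo + 1L], n, n)
        key <- .subset_key(subsets[[j]])
        Y <- .tsne_from_d2(D2, dims, perplexity,
                           derive_seed(seed, tag, "tsne", key, r), n_iter)
        cvr <- .cv_on_coords(Y, labels, k_neighbors, n_folds,
                             derive_seed(seed, tag, "folds", key, r))
        quality[j, r] <- mean(cvr$per_fold_accuracy, na.rm = TRUE)
      }
    }
  }
  rowMeans(quality)
}

#' Exhaustive feature-subset sensitivity scan
#'
#' Scores every requested feature subset on each per-object dataset with
#' the unchanged pipeline after noise substitution, averages over
#' `n_repeats`, then averages the per-object quality vectors (unweighted)
#' into a cross-object score. Results are deterministic given `seed` and
#' independent of evaluation order, since every (object, subset, repeat)
#' triple derives its own seed.
#'
#' @param datasets a `grasp_dataset`, or a named list of them (one per
#'   object, consistent feature ordering).
#' @param subsets list of integer subsets; default
#'   [enumerate_subsets()] over the dataset's features with sizes
#'   `2..(n_features - 1)`.
#' @inheritParams subset_quality
#' @return an object of class `grasp_sensitivity`: data frame `table` with
#'   columns `subset` (key string), `size`, one quality column per object
#'   and `mean_quality`, plus the scan parameters.
#' @export
sensitivity_scan <- function(datasets, subsets = NULL, n_repeats = 3,
                             labels = NULL, seed = 1, dims = 3,
                             perplexity = 12, n_iter = 500,
                             k_neighbors = 10, n_folds = 5) {
  if (inherits(datasets, "grasp_dataset")) datasets <- list(all = datasets)
  n_feat <- unique(vapply(datasets, function(d) length(d$feature_names), 0L))
  if (length(n_feat) != 1)
    stop_graspid("graspid_config_error",
                 "object datasets have mismatched feature counts")
  if (is.null(subsets))
    subsets <- enumerate_subsets(n_feat, 2, n_feat - 1)
  obj_names <- names(datasets) %||% sprintf("O%d", seq_along(datasets))

  per_obj <- vapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    .scan_one_dataset(d, subsets, labels %||% d$subject, n_repeats,
                      seed, dims, perplexity, n_iter, k_neighbors, n_folds,
                      tag = paste0("scan:", obj_names[i]))
  }, numeric(length(subsets)))
  per_obj <- matrix(per_obj, nrow = length(subsets),
                    dimnames = list(NULL, obj_names))

  tab <- data.frame(subset = vapply(subsets, .subset_key, ""),
                    size = lengths(subsets), stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(per_obj))
  tab$mean_quality <- rowMeans(per_obj)
  structure(list(table = tab, subsets = subsets, objects = obj_names,
                 n_repeats = n_repeats, seed = seed,
                 params = list(dims = dims, perplexity = perplexity,
                               n_iter = n_iter, k_neighbors = k_neighbors,
                               n_folds = n_folds)),
            class = "grasp_sensitivity")
}

#' @export
print.grasp_sensitivity <- function(x, ...) {
  cat(sprintf("Feature-subset sensitivity scan: %d subsets, %d object(s), %d repeat(s)\n",
              nrow(x$table), length(x$objects), x$n_repeats))
  best <- x$table[which.max(x$table$mean_quality), ]
  cat(sprintf("  best subset {%s} (size %d): %.2f%%\n",
              best$subset, best$size, 100 * best$mean_quality))
  invisible(x)
}

#' Per-size max/mean/min quality profile
#'
#' @param result a `grasp_sensitivity`.
#' @return an object of class `grasp_size_profile`: data frame with columns
#'   `size`, `min`, `mean`, `max`.
#' @export
size_profile <- function(result) {
  tab <- result$table
  if (nrow(tab) == 0)
    stop_graspid("graspid_config_error", "empty sensitivity result")
  sizes <- sort(unique(tab$size))
  prof <- data.frame(size = sizes,
                     min = vapply(sizes, function(s) min(tab$mean_quality[tab$size == s]), 0),
                     mean = vapply(sizes, function(s) mean(tab$mean_quality[tab$size == s]), 0),
                     max = vapply(sizes, function(s) max(tab$mean_quality[tab$size == s]), 0))
  class(prof) <- c("grasp_size_profile", "data.frame")
  prof
}

#' @export
plot.grasp_size_profile <- function(x, ...) {
  plot(x$size, x$max, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "number of features", ylab = "quality of clustering", ...)
  lines(x$size, x$mean, type = "b", pch = 1)
  lines(x$size, x$min, type = "b", pch = 4)
  legend("bottomright", legend = c("max", "mean", "min"), pch = c(19, 1, 4),
         lty = 1, bty = "n")
  invisible(x)
}

#' Best subset of a given size
#'
#' @param result a `grasp_sensitivity`.
#' @param size subset size to extract (default 6, the knee of the quality
#'   profile).
#' @return list with `subset` (integer indices), `quality`, and the per-size
#'   rank table.
#' @export
best_subset <- function(result, size = 6) {
  tab <- result$table
  rows <- which(tab$size == size)
  if (length(rows) == 0)
    stop_graspid("graspid_config_error", "size %d was not scanned", size)
  best <- rows[which.max(tab$mean_quality[rows])]
  list(subset = result$subsets[[best]],
       quality = tab$mean_quality[best],
       key = tab$subset[best])
}

#' Refined best subset of a given size
#'
#' The exhaustive scan scores every subset with few repeats, so the argmax
#' among thousands of near-tied candidates inherits the repeat-to-repeat
#' spread of the stochastic embedding — and any single re-scoring pass over
#' a large candidate pool re-introduces the same selection bias. This
#' successive-halving refinement therefore narrows the pool in stages: the
#' `top[1]` screening candidates are re-scored with `n_repeats[1]` fresh
#' repeats, the best `top[2]` of those with `n_repeats[2]` repeats, and so
#' on (per-(subset, repeat) seeds, pipeline parameters unchanged); the
#' final argmax is taken over a handful of well-estimated scores.
#'
#' @param dataset the `grasp_dataset` the scan was run on.
#' @param result a `grasp_sensitivity` over that dataset.
#' @param size subset size to extract.
#' @param top candidate-pool sizes per refinement stage (decreasing).
#' @param n_repeats repeats per refinement stage (increasing).
#' @inheritParams subset_quality
#' @return list with `subset`, `quality` (final-stage score) and `key`.
#' @export
best_subset_refined <- function(dataset, result, size = 6, top = c(30, 5),
                                n_repeats = c(12, 30), labels = NULL,
                                seed = 1, dims = 3, perplexity = 12,
                                n_iter = 500, k_neighbors = 10, n_folds = 5) {
  if (length(top) != length(n_repeats))
    stop_graspid("graspid_config_error",
                 "top and n_repeats must have the same length")
  tab <- result$table
  rows <- which(tab$size == size)
  if (length(rows) == 0)
    stop_graspid("graspid_config_error", "size %d was not scanned", size)
  cand <- rows[order(-tab$mean_quality[rows])]
  q <- tab$mean_quality[cand]
  for (stage in seq_along(top)) {
    cand <- cand[order(-q)][seq_len(min(top[stage], length(cand)))]
    q <- vapply(cand, function(i)
      subset_quality(dataset, result$subsets[[i]],
                     n_repeats = n_repeats[stage], labels = labels,
                     seed = derive_seed(seed, "refine", stage),
                     dims = dims, perplexity = perplexity, n_iter = n_iter,
                     k_neighbors = k_neighbors, n_folds = n_folds),
      numeric(1))
  }
  best <- cand[which.max(q)]
  list(subset = result$subsets[[best]], quality = max(q),
       key = tab$subset[best])
}

#' Best-subset grid across objects
#'
#' Renders, for each per-object quality column of a scan (and the
#' cross-object mean), which features enter the best subset of the given
#' size — a feature x object membership grid with the achieved quality.
#'
#' @param result a `grasp_sensitivity`.
#' @param size subset size (default 6).
#' @return data frame: one row per object plus `combined`, one logical
#'   column per feature, and `quality_pct`.
#' @export
best_subset_grid <- function(result, size = 6) {
  tab <- result$table
  rows <- which(tab$size == size)
  if (length(rows) == 0)
    stop_graspid("graspid_config_error", "size %d was not scanned", size)
  n_feat <- max(unlist(result$subsets))
  feat_names <- if (n_feat == 15) feature_names()
                else paste0("feature_", seq_len(n_feat))
  cols <- c(result$objects, if (length(result$objects) > 1) "mean_quality")
  grid <- do.call(rbind, lapply(cols, function(cl) {
    best <- rows[which.max(tab[[cl]][rows])]
    membership <- as.list(seq_len(n_feat) %in% result$subsets[[best]])
    names(membership) <- feat_names
    cbind(data.frame(dataset = if (cl == "mean_quality") "combined" else cl),
          as.data.frame(membership),
          data.frame(quality_pct = 100 * tab[[cl]][best]))
  }))
  grid
}

#' Time-window sensitivity scan
#'
#' Which part of the movement carries the subject-specific information?
#' For each contiguous window of `window_width` samples (non-overlapping by
#' default), all samples outside the window - in every feature row - are
#' replaced by N(0,1) noise and the unchanged pipeline quality is computed.
#'
#' @param dataset a z-normalized `grasp_dataset`.
#' @param window_width window width in samples (50 gives 10 windows on
#'   500-sample features).
#' @param stride window step; defaults to `window_width` (non-overlapping).
#' @inheritParams subset_quality
#' @return data frame with `start`, `end` (sample indices) and `quality`.
#' @export
time_window_scan <- function(dataset, window_width = 50, stride = window_width,
                             n_repeats = 3, labels = NULL, seed = 1, dims = 3,
                             perplexity = 12, n_iter = 500, k_neighbors = 10,
                             n_folds = 5) {
  s <- dataset$n_samples
  if (window_width < 1 || window_width > s)
    stop_graspid("graspid_config_error", "window width must be in 1..%d", s)
  labels <- labels %||% dataset$subject
  starts <- seq(1L, s - window_width + 1L, by = stride)
  quality <- vapply(starts, function(st) {
    accs <- vapply(seq_len(n_repeats), function(r) {
      rseed <- derive_seed(seed, "window", st, r)
      sub <- substitute_time_window(dataset, st, window_width,
                                    seed = derive_seed(rseed, "noise"))
      cross_validate(sub, labels = labels, k_neighbors = k_neighbors,
                     n_folds = n_folds, seed = rseed, dims = dims,
                     perplexity = perplexity, n_iter = n_iter)$mean_accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  data.frame(start = starts, end = starts + window_width - 1L,
             quality = quality)
}

#' Reduced subset design for size profiles
#'
#' Builds a deterministic reduced subset list for profiling quality against
#' subset size when the exhaustive scan is unnecessary: for every size it
#' samples `n_random` subsets at random and, when a `focus` feature set is
#' given, adds subsets drawn from inside `focus` (for sizes up to
#' `length(focus)`) and supersets of `focus` (for larger sizes), so the
#' per-size maximum is probed where it is expected to live.
#'
#' @param n_features total number of features.
#' @param sizes integer vector of subset sizes.
#' @param n_random random subsets per size.
#' @param focus optional integer feature set to probe around.
#' @param n_focus focused subsets per size.
#' @param seed seed for the sampling.
#' @return list of integer subsets (unique, deterministic order).
#' @export
sample_subset_design <- function(n_features = 15, sizes = 2:14,
                                 n_random = 20, focus = NULL, n_focus = 10,
                                 seed = 1) {
  with_seed(derive_seed(seed, "subset-design"), {
    out <- list()
    for (s in sizes) {
      for (i in seq_len(n_random))
        out[[length(out) + 1L]] <- sort(sample(n_features, s))
      if (!is.null(focus)) {
        for (i in seq_len(n_focus)) {
          sub <- if (s <= length(focus)) sort(sample(focus, s))
                 else sort(c(focus, sample(setdiff(seq_len(n_features), focus),
                                           s - length(focus))))
          out[[length(out) + 1L]] <- sub
        }
      }
    }
    unique(out)
  })
}

#' Simulate a feature-level dataset with planted informative features
#'
#' Generates a z-scale dataset directly at the feature-matrix level (no
#' kinematic synthesis): each informative feature row carries a smooth
#' subject-specific signature curve (pointwise SD `signal_sd`) plus white
#' within-subject noise (`noise_sd`); non-informative rows are pure N(0,1).
#' With `signal_sd^2 + noise_sd^2 = 1` the marginal scale matches
#' z-normalized data. Used to validate the sensitivity analysis: the scan
#' should recover the planted informative set.
#'
#' @param n_subjects,n_trials design counts.
#' @param n_features,n_samples feature-matrix shape.
#' @param informative integer indices of the informative features.
#' @param signal_sd pointwise SD of the between-subject signature curves.
#' @param noise_sd SD of within-subject white noise on informative rows.
#' @param n_harmonics harmonics per signature curve; more harmonics make the
#'   realized between-subject separation per feature more uniform.
#' @param seed master seed.
#' @return a `grasp_dataset`.
#' @export
simulate_feature_dataset <- function(n_subjects = 8, n_trials = 5,
                                     n_features = 15, n_samples = 40,
                                     informative = 1:6, signal_sd = 0.5,
                                     noise_sd = sqrt(0.75), n_harmonics = 8,
                                     seed = 1) {
  n <- n_subjects * n_trials
  subject <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_trials)
  tgrid <- seq(0, 1, length.out = n_samples)
  X <- with_seed(derive_seed(seed, "planted"), {
    sig <- lapply(seq_len(n_subjects), function(s) {
      vapply(informative, function(f)
        as.vector(.eval_smooth(.draw_phases(1, n_harmonics), signal_sd, tgrid)),
        numeric(n_samples))
    })
    M <- matrix(rnorm(n * n_features * n_samples), n)
    for (i in seq_len(n)) {
      s <- (i - 1) %/% n_trials + 1
      for (jf in seq_along(informative)) {
        cols <- (informative[jf] - 1L) * n_samples + seq_len(n_samples)
        M[i, cols] <- sig[[s]][, jf] + noise_sd * rnorm(n_samples)
      }
    }
    M
  })
  .make_dataset(X, subject,
                feature_names. = feature_names()[seq_len(n_features)],
                n_samples = n_samples)
}
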