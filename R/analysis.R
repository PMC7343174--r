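# Classification pipeline: inverse-square-distance weighted kNN on the
# embedded coordinates, k-fold cross-validation, and hand-size-ordered
# confusion matrices.

#' Weighted k-nearest-neighbour prediction
#'
#' Each query point is labelled by the class with the largest summed vote
#' among its `k` nearest training points, where neighbour `i` at distance
#' `d_i` votes with weight `w_i = d_i^-2`. Distances are floored at
#' `eps = 1e-12` so that a query coinciding with a training point takes that
#' point's label (the limit the weight dictates). Vote ties break to the
#' lexicographically smallest class label, for determinism.
#'
#' @param train_coords `n_train x dims` matrix.
#' @param train_labels labels of the training points.
#' @param query_coords `n_query x dims` matrix.
#' @param k number of neighbours (`k <= n_train`).
#' @param eps distance floor.
#' @return character vector of predicted labels.
#' @export
weighted_knn_predict <- function(train_coords, train_labels, query_coords,
                                 k = 10, eps = 1e-12) {
  train_coords <- as.matrix(train_coords)
  query_coords <- as.matrix(query_coords)
  n_train <- nrow(train_coords)
  if (n_train == 0)
    stop_graspid("graspid_config_error", "empty training set")
  if (k > n_train)
    stop_graspid("graspid_config_error", "k = %d exceeds training size %d",
                 k, n_train)
  labels <- factor(as.character(train_labels))  # levels sort lexicographically
  # cross squared distances
  D2 <- outer(rowSums(query_coords^2), rowSums(train_coords^2), "+") -
    2 * tcrossprod(query_coords, train_coords)
  D2 <- pmax(D2, 0)
  pred <- cpp_wknn_vote(D2, as.integer(labels), k, nlevels(labels), eps)
  levels(labels)[pred]
}

# internal fast path: fold CV on a precomputed embedding distance matrix
.cv_on_coords <- function(Y, labels, k_neighbors, n_folds, fold_seed) {
  lab <- factor(as.character(labels))
  li <- as.integer(lab)
  n <- length(li)
  fold <- .stratified_folds(as.character(lab), n_folds, fold_seed)
  nl <- nlevels(lab)
  conf <- matrix(0L, nl, nl, dimnames = list(true = levels(lab),
                                             predicted = levels(lab)))
  D2 <- .sq_dist(Y)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(test) == 0) { acc[f] <- NA_real_; next }
    pred <- cpp_wknn_vote(D2[test, train, drop = FALSE], li[train],
                          min(k_neighbors, length(train)), nl)
    for (i in seq_along(test))
      conf[li[test[i]], pred[i]] <- conf[li[test[i]], pred[i]] + 1L
    acc[f] <- mean(pred == li[test])
  }
  list(per_fold_accuracy = acc, confusion = conf, fold = fold)
}

# seeded stratified fold assignment; singleton classes go to fold 0
# (training-only) with a warning
.stratified_folds <- function(labels, n_folds, seed) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < 2) {
        warning(sprintf("class '%s' has a single trial; used for training only", lv))
        fold[idx] <- 0L
        next
      }
      idx <- sample(idx)
      fold[idx] <- rep_len(sample(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated weighted-kNN classification of an embedding
#'
#' Splits the trials into `n_folds` seeded stratified folds; each fold in
#' turn is the test set, classified by weighted kNN against the remaining
#' trials. The mean of the fold accuracies is the "quality of clustering"
#' score reported throughout the package.
#'
#' By default the folds are split *after* embedding, i.e. the test trials
#' participated in the (unsupervised) t-SNE embedding. This mirrors the
#' standard t-SNE + kNN + cross-validation pipeline but lets the test points
#' shape the embedding; pass a `grasp_dataset` with
#' `split = "before_embedding"` for an honest generalization estimate, where
#' each fold's test trials are placed into the training-only embedding at the
#' inverse-square-distance weighted average (in input space) of their `k`
#' nearest training trials.
#'
#' @param x a `grasp_embedding` (split after embedding) or a `grasp_dataset`.
#' @param labels class labels per trial; defaults to the stored subjects.
#' @param k_neighbors kNN neighbourhood size.
#' @param n_folds number of cross-validation folds.
#' @param seed seed for fold assignment (and for the embedding when `x` is a
#'   dataset).
#' @param split `"after_embedding"` (default) or `"before_embedding"`.
#' @param dims,perplexity,n_iter embedding parameters, used when `x` is a
#'   `grasp_dataset`.
#' @return an object of class `grasp_cv`: `per_fold_accuracy`,
#'   `mean_accuracy`, `confusion` (rows = true class), `subject_order`,
#'   `k_neighbors`, `n_folds`.
#' @export
cross_validate <- function(x, labels = NULL, k_neighbors = 10, n_folds = 5,
                           seed = 1, split = c("after_embedding",
                                               "before_embedding"),
                           dims = 3, perplexity = 12, n_iter = 500) {
  split <- match.arg(split)
  if (inherits(x, "grasp_embedding")) {
    labels <- labels %||% x$subject
    res <- .cv_on_coords(x$coords, labels, k_neighbors, n_folds,
                         derive_seed(seed, "folds"))
    hs <- x$hand_size
  } else if (inherits(x, "grasp_dataset")) {
    labels <- labels %||% x$subject
    hs <- x$hand_size
    if (split == "after_embedding") {
      emb <- embed_tsne(x, dims = dims, perplexity = perplexity,
                        seed = derive_seed(seed, "tsne"), n_iter = n_iter)
      res <- .cv_on_coords(emb$coords, labels, k_neighbors, n_folds,
                           derive_seed(seed, "folds"))
    } else {
      res <- .cv_before_embedding(x, labels, k_neighbors, n_folds, seed,
                                  dims, perplexity, n_iter)
    }
  } else {
    stop_graspid("graspid_config_error",
                 "x must be a grasp_embedding or grasp_dataset")
  }
  labels <- as.character(labels)
  if (any(table(labels) < 2) && all(table(labels) < 2))
    stop_graspid("graspid_config_error", "every class needs at least 2 trials")
  structure(list(per_fold_accuracy = res$per_fold_accuracy,
                 mean_accuracy = mean(res$per_fold_accuracy, na.rm = TRUE),
                 confusion = res$confusion,
                 subject_order = rownames(res$confusion),
                 hand_size = if (!is.null(hs))
                   hs[match(rownames(res$confusion), labels)],
                 k_neighbors = k_neighbors, n_folds = n_folds,
                 seed = seed, split = split),
            class = "grasp_cv")
}

# honest mode: per fold, embed the training trials only and place each test
# trial at the weighted (input-space d^-2) barycentre of its k nearest
# training trials' embedded coordinates
.cv_before_embedding <- function(dataset, labels, k_neighbors, n_folds, seed,
                                 dims, perplexity, n_iter) {
  labels <- as.character(labels)
  X <- dataset$X
  fold <- .stratified_folds(labels, n_folds, derive_seed(seed, "folds"))
  lev <- sort(unique(labels))
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(true = lev,
                                                               predicted = lev))
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f); train <- which(fold != f)
    if (length(test) == 0) { acc[f] <- NA_real_; next }
    Ytr <- .tsne_from_d2(.sq_dist(X[train, , drop = FALSE]), dims, perplexity,
                         derive_seed(seed, "tsne", f), n_iter)
    D2 <- outer(rowSums(X[test, , drop = FALSE]^2), rowSums(X[train, , drop = FALSE]^2), "+") -
      2 * tcrossprod(X[test, , drop = FALSE], X[train, , drop = FALSE])
    D2 <- pmax(D2, 0)
    kk <- min(k_neighbors, length(train))
    Yte <- t(apply(D2, 1, function(d2) {
      nn <- order(d2)[seq_len(kk)]
      w <- 1 / pmax(d2[nn], 1e-24)
      colSums(Ytr[nn, , drop = FALSE] * w) / sum(w)
    }))
    pred <- weighted_knn_predict(Ytr, labels[train], Yte,
                                 k = min(k_neighbors, length(train)))
    for (i in seq_along(test))
      conf[labels[test[i]], pred[i]] <- conf[labels[test[i]], pred[i]] + 1L
    acc[f] <- mean(pred == labels[test])
  }
  list(per_fold_accuracy = acc, confusion = conf)
}

#' @export
print.grasp_cv <- function(x, ...) {
  cat(sprintf("Cross-validated weighted kNN (k = %d, %d folds, split %s)\n",
              x$k_neighbors, x$n_folds, x$split %||% "after_embedding"))
  cat(sprintf("  mean accuracy: %.2f%%\n", 100 * x$mean_accuracy))
  cat(sprintf("  per-fold: %s\n",
              paste(sprintf("%.1f%%", 100 * x$per_fold_accuracy), collapse = ", ")))
  invisible(x)
}

#' @export
summary.grasp_cv <- function(object, ...) {
  conf <- object$confusion
  n_per <- rowSums(conf)
  recall <- ifelse(n_per > 0, diag(conf) / n_per, NA)
  out <- list(mean_accuracy = object$mean_accuracy,
              overall_accuracy = sum(diag(conf)) / max(1, sum(conf)),
              per_class = data.frame(class = rownames(conf), n = n_per,
                                     recall = recall, row.names = NULL))
  class(out) <- "summary.grasp_cv"
  out
}

#' @export
print.summary.grasp_cv <- function(x, ...) {
  cat(sprintf("Mean fold accuracy: %.2f%% (pooled: %.2f%%)\n",
              100 * x$mean_accuracy, 100 * x$overall_accuracy))
  print(head(x$per_class, 10))
  if (nrow(x$per_class) > 10) cat(sprintf("  ... %d classes\n", nrow(x$per_class)))
  invisible(x)
}

#' Confusion-matrix heat map
#'
#' @param x a `grasp_cv`.
#' @param ... passed to [image()].
#' @export
plot.grasp_cv <- function(x, ...) {
  conf <- x$confusion
  n <- nrow(conf)
  image(seq_len(n), seq_len(n), t(conf[n:1, , drop = FALSE]),
        col = hcl.colors(32, "Blues 3", rev = TRUE),
        xlab = "predicted", ylab = "true", axes = FALSE, ...)
  axis(1, at = seq_len(n), labels = colnames(conf), las = 2, cex.axis = 0.6)
  axis(2, at = seq_len(n), labels = rev(rownames(conf)), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Reorder a confusion matrix by ascending hand size
#'
#' Rows and columns of the confusion matrix are permuted so subjects appear
#' in ascending hand-size order; counts are preserved. Useful to see whether
#' misclassifications concentrate between subjects of similar hand size.
#'
#' @param report a `grasp_cv`.
#' @param hand_sizes named numeric vector (mm) keyed by subject label;
#'   defaults to hand sizes stored in the report.
#' @return the report with permuted `confusion`, `subject_order` and
#'   `hand_size`.
#' @export
confusion_by_hand_size <- function(report, hand_sizes = NULL) {
  hs <- hand_sizes %||% stats::setNames(report$hand_size, report$subject_order)
  if (is.null(hs) || any(is.na(hs[report$subject_order])))
    stop_graspid("graspid_metadata_error",
                 "hand size missing for some subjects")
  ord <- order(hs[report$subject_order])
  report$confusion <- report$confusion[ord, ord, drop = FALSE]
  report$subject_order <- report$subject_order[ord]
  report$hand_size <- unname(hs[report$subject_order])
  report
}

#' Grip-type (object-level) classification
#'
#' Runs the same embed + weighted kNN + cross-validation pipeline with the
#' object identity as the class label, at the larger perplexity appropriate
#' for few big clusters.
#'
#' @param dataset a `grasp_dataset` spanning several objects.
#' @param perplexity t-SNE perplexity (default 50).
#' @param ... passed to [cross_validate()].
#' @return a `grasp_cv` over object labels.
#' @export
classify_objects <- function(dataset, perplexity = 50, ...) {
  cross_validate(dataset, labels = dataset$object, perplexity = perplexity, ...)
}
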