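# t-SNE embedding (exact, dense). The conditional-probability bandwidths
# are matched to the requested perplexity by bisection, and the embedding
# is optimized by gradient descent with early exaggeration, momentum
# switching and adaptive gains. All randomness (the initial configuration)
# is drawn on the R side from a single seed, so embeddings are reproducible.

# squared Euclidean distance matrix, clipped at 0 for numerical safety
.sq_dist <- function(X) {
  s <- rowSums(X^2)
  D2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  diag(D2) <- 0
  pmax(D2, 0)
}

# core: embed from a squared-distance matrix (used by the sensitivity scan,
# where subset distances are assembled without materializing the data)
.tsne_from_d2 <- function(D2, dims, perplexity, seed, n_iter, eta = 200,
                          exaggeration = 12, exag_iter = 100) {
  n <- nrow(D2)
  if (n - 1 < 3 * perplexity)
    stop_graspid("graspid_config_error",
                 "perplexity %g too large for %d points (need n - 1 >= 3 * perplexity)",
                 perplexity, n)
  P <- cpp_perplexity_probs(D2, perplexity)
  Y0 <- with_seed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  cpp_tsne_iterate(P, Y0, n_iter = n_iter, eta = eta,
                   exaggeration = exaggeration, exag_iter = exag_iter)
}

#' Embed a dataset with t-SNE
#'
#' Reduces the flattened trial vectors to 2 or 3 dimensions with exact
#' t-distributed Stochastic Neighbor Embedding, the standard tool for
#' visualizing and locally clustering high-dimensional trial data.
#'
#' @param x a `grasp_dataset` or a numeric `trials x features` matrix.
#' @param dims embedding dimensionality (2 or 3).
#' @param perplexity effective neighbourhood size; requires
#'   `n - 1 >= 3 * perplexity`.
#' @param seed seed for the random initial configuration.
#' @param n_iter gradient-descent iterations.
#' @param eta learning rate.
#' @return an object of class `grasp_embedding`: list with `coords`
#'   (trials x dims), `perplexity`, `seed`, `n_input_dims`, and the trial
#'   labels when `x` is a `grasp_dataset`.
#' @export
embed_tsne <- function(x, dims = 3, perplexity = 12, seed = 1,
                       n_iter = 500, eta = 200) {
  if (!dims %in% c(2L, 3L))
    stop_graspid("graspid_config_error", "dims must be 2 or 3")
  X <- if (inherits(x, "grasp_dataset")) x$X else as.matrix(x)
  Y <- .tsne_from_d2(.sq_dist(X), dims, perplexity, seed, n_iter, eta)
  structure(list(coords = Y, dims = dims, perplexity = perplexity,
                 seed = seed, n_input_dims = ncol(X),
                 subject = if (inherits(x, "grasp_dataset")) x$subject,
                 object = if (inherits(x, "grasp_dataset")) x$object,
                 hand_size = if (inherits(x, "grasp_dataset")) x$hand_size),
            class = "grasp_embedding")
}

#' @export
print.grasp_embedding <- function(x, ...) {
  cat(sprintf("t-SNE embedding: %d trials, %d -> %d dims, perplexity %g, seed %s\n",
              nrow(x$coords), x$n_input_dims, x$dims, x$perplexity, x$seed))
  invisible(x)
}

#' Scatter plot of an embedding, coloured by label
#'
#' Plots the first two embedding dimensions with one colour per label
#' (subjects by default).
#'
#' @param x a `grasp_embedding`.
#' @param labels labels per trial; defaults to the stored subject labels.
#' @param ... passed to [plot()].
#' @export
plot.grasp_embedding <- function(x, labels = x$subject, ...) {
  lab <- factor(labels %||% rep("trial", nrow(x$coords)))
  cols <- hcl.colors(max(3, nlevels(lab)), "Dark 3")[as.integer(lab)]
  plot(x$coords[, 1], x$coords[, 2], col = cols, pch = 19,
       xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}
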