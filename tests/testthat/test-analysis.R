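# Embedding, weighted kNN, cross-validation and confusion handling.

test_that("weighted kNN matches the brute-force vote oracle exactly", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    dims <- sample(1:3, 1)
    k <- sample(seq_len(min(10, n)), 1)
    n_classes <- sample(2:5, 1)
    train <- matrix(rnorm(n * dims), n)
    labels <- sample(LETTERS[seq_len(n_classes)], n, replace = TRUE)
    query <- matrix(rnorm(7 * dims), 7)
    expect_identical(unname(weighted_knn_predict(train, labels, query, k)),
                     brute_wknn(train, labels, query, k))
  }
})

test_that("inverse-square weights beat raw majority in the constructed case", {
  # neighbour distances (1, 2, 2) with labels (A, B, B): A wins 1 vs 0.5
  train <- matrix(c(1, 2, -2), 3, 1)
  pred <- weighted_knn_predict(train, c("A", "B", "B"),
                               matrix(0, 1, 1), k = 3)
  expect_equal(unname(pred), "A")

  # all neighbours share one label
  pred2 <- weighted_knn_predict(matrix(1:4, 4, 1), rep("Z", 4),
                                matrix(0, 1, 1), k = 4)
  expect_equal(unname(pred2), "Z")
})

test_that("a query on top of a training point takes that point's label", {
  set.seed(5)
  train <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2), c(4, 4))
  labels <- c(rep("near", 10), "far")
  pred <- weighted_knn_predict(train, labels, matrix(c(4, 4), 1, 2), k = 10)
  expect_equal(unname(pred), "far")
})

test_that("kNN input contracts are enforced", {
  expect_error(weighted_knn_predict(matrix(0, 0, 2), character(0),
                                    matrix(0, 1, 2), 1),
               class = "graspid_config_error")
  expect_error(weighted_knn_predict(matrix(0, 3, 2), c("a", "b", "c"),
                                    matrix(0, 1, 2), 5),
               class = "graspid_config_error")
})

test_that("t-SNE embedding: shape, determinism, perplexity validity", {
  set.seed(7)
  X <- matrix(rnorm(40 * 25), 40)
  e1 <- embed_tsne(X, dims = 3, perplexity = 8, seed = 4)
  expect_equal(dim(e1$coords), c(40, 3))
  expect_true(all(is.finite(e1$coords)))
  e2 <- embed_tsne(X, dims = 3, perplexity = 8, seed = 4)
  expect_identical(e1$coords, e2$coords)
  e3 <- embed_tsne(X, dims = 3, perplexity = 8, seed = 5)
  expect_false(identical(e1$coords, e3$coords))

  expect_error(embed_tsne(X, perplexity = 20), class = "graspid_config_error")
  expect_error(embed_tsne(X, dims = 4, perplexity = 5),
               class = "graspid_config_error")
})

test_that("well-separated clusters stay separated in the embedding", {
  set.seed(11)
  n_per <- 15
  centers <- matrix(rnorm(4 * 60, sd = 10), 4)   # 10-sigma separation scale
  X <- do.call(rbind, lapply(1:4, function(c)
    matrix(rnorm(n_per * 60), n_per, 60) + centers[rep(c, n_per), ]))
  labels <- rep(letters[1:4], each = n_per)
  emb <- embed_tsne(X, dims = 2, perplexity = 5, seed = 2, n_iter = 1000)
  expect_gt(silhouette_mean(emb$coords, labels), 0.8)
})

test_that("cross-validation: fold partition, confusion bookkeeping, accuracy", {
  d <- simulate_feature_dataset(n_subjects = 5, n_trials = 8,
                                n_samples = 50, informative = 1:15,
                                signal_sd = 0.9, noise_sd = 0.3, seed = 13)
  emb <- embed_tsne(d, dims = 2, perplexity = 8, seed = 3)
  cv <- cross_validate(emb, k_neighbors = 5, n_folds = 5, seed = 9)

  expect_length(cv$per_fold_accuracy, 5)
  expect_true(all(cv$per_fold_accuracy >= 0 & cv$per_fold_accuracy <= 1))
  expect_equal(cv$mean_accuracy, mean(cv$per_fold_accuracy))
  # confusion row sums = per-class trial counts (all trials tested once)
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.vector(table(d$subject))))
  expect_equal(sum(cv$confusion), 40)
  expect_gt(cv$mean_accuracy, 0.9)   # strong signal separates cleanly

  # folds are deterministic given the seed
  cv2 <- cross_validate(emb, k_neighbors = 5, n_folds = 5, seed = 9)
  expect_identical(cv$confusion, cv2$confusion)
})

test_that("label scrambling drives accuracy to chance", {
  d <- simulate_feature_dataset(n_subjects = 5, n_trials = 8,
                                n_samples = 50, informative = 1:15,
                                signal_sd = 0.9, noise_sd = 0.3, seed = 13)
  emb <- embed_tsne(d, dims = 2, perplexity = 8, seed = 3)
  set.seed(21)
  accs <- vapply(1:8, function(i)
    cross_validate(emb, labels = sample(d$subject), seed = i)$mean_accuracy,
    numeric(1))
  # chance is 1/5; allow 3 Monte-Carlo standard errors
  expect_lt(abs(mean(accs) - 0.2), 3 * sd(accs) / sqrt(length(accs)) + 0.02)
})

test_that("the honest split mode also classifies structured data", {
  d <- simulate_feature_dataset(n_subjects = 5, n_trials = 8,
                                n_samples = 50, informative = 1:15,
                                signal_sd = 0.9, noise_sd = 0.3, seed = 13)
  cv <- cross_validate(d, split = "before_embedding", perplexity = 8,
                       seed = 4, n_iter = 300)
  expect_gt(cv$mean_accuracy, 0.8)
})

test_that("hand-size ordering permutes the confusion matrix correctly", {
  conf <- matrix(c(5L, 1L, 0L,
                   0L, 6L, 2L,
                   1L, 0L, 7L), 3, 3, byrow = TRUE,
                 dimnames = list(true = c("a", "b", "c"),
                                 predicted = c("a", "b", "c")))
  rep0 <- structure(list(confusion = conf, subject_order = c("a", "b", "c"),
                         hand_size = NULL), class = "grasp_cv")

  sorted <- confusion_by_hand_size(rep0, c(a = 150, b = 170, c = 190))
  expect_identical(sorted$confusion, conf)   # already ascending -> identity

  rev_ <- confusion_by_hand_size(rep0, c(a = 190, b = 170, c = 150))
  expect_equal(rev_$subject_order, c("c", "b", "a"))
  expect_identical(rev_$confusion, conf[3:1, 3:1])
  expect_equal(sum(rev_$confusion), sum(conf))
  expect_equal(sum(diag(rev_$confusion)), sum(diag(conf)))

  expect_error(confusion_by_hand_size(rep0, c(a = 1, b = 2)),
               class = "graspid_metadata_error")
})

test_that("object-level classification separates objects and hits chance when scrambled", {
  # three object clusters at the feature level, several subjects each
  set.seed(31)
  n_per <- 60
  X <- do.call(rbind, lapply(1:3, function(o)
    matrix(rnorm(n_per * 100), n_per) + 3 * o))
  d <- graspid:::.make_dataset(X, subject = rep("s", 3 * n_per),
                               object = rep(c("O1", "O2", "O3"), each = n_per),
                               feature_names. = paste0("f", 1:10),
                               n_samples = 10)
  cv <- classify_objects(d, perplexity = 50, seed = 2)
  expect_gt(cv$mean_accuracy, 0.95)

  set.seed(32)
  d_null <- d
  d_null$object <- sample(d$object)
  cv0 <- classify_objects(d_null, perplexity = 50, seed = 2)
  expect_lt(abs(cv0$mean_accuracy - 1 / 3), 0.15)
})
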