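# Feature-subset sensitivity analysis: enumeration, subset quality,
# scan contracts, size profiles and the time-window scan.

test_that("subset enumeration matches the closed form", {
  expect_length(enumerate_subsets(15, 2, 14), 32751)
  expect_length(enumerate_subsets(3, 2, 2), 3)
  expect_length(enumerate_subsets(5, 2, 4), 25)
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    lo <- sample(seq_len(n - 1), 1)
    hi <- sample(lo:n, 1)
    subs <- enumerate_subsets(n, lo, hi)
    expect_length(subs, sum(choose(n, lo:hi)))
    expect_false(any(duplicated(vapply(subs, paste, "", collapse = "-"))))
    expect_true(all(lengths(subs) >= lo & lengths(subs) <= hi))
  }
  expect_error(enumerate_subsets(5, 3, 2), class = "graspid_config_error")
  expect_error(enumerate_subsets(5, 0, 2), class = "graspid_config_error")
})

test_that("subset quality: determinism, full-set equivalence, chance floor", {
  d <- simulate_feature_dataset(n_subjects = 5, n_trials = 6, n_samples = 40,
                                seed = 19)
  q1 <- subset_quality(d, 1:6, n_repeats = 2, seed = 7, perplexity = 6,
                       n_iter = 300)
  q2 <- subset_quality(d, 1:6, n_repeats = 2, seed = 7, perplexity = 6,
                       n_iter = 300)
  expect_identical(q1, q2)

  # keeping all features performs no substitution: quality equals the plain
  # pipeline accuracy under the same derived seed
  rseed <- derive_seed(7, "subset", paste(1:15, collapse = "-"), 1)
  expected <- cross_validate(d, seed = rseed, perplexity = 6,
                             n_iter = 300)$mean_accuracy
  q_all <- subset_quality(d, 1:15, n_repeats = 1, seed = 7, perplexity = 6,
                          n_iter = 300)
  expect_equal(q_all, expected)

  # pure-noise subsets on a zero-signal dataset sit near chance (1/5)
  d0 <- simulate_feature_dataset(n_subjects = 5, n_trials = 6, n_samples = 40,
                                 informative = integer(0), seed = 23)
  q0 <- subset_quality(d0, 7:12, n_repeats = 3, seed = 3, perplexity = 6,
                       n_iter = 300)
  expect_lt(abs(q0 - 0.2), 0.2)
})

test_that("the scan is order-independent and matches subset_quality-style scoring", {
  d1 <- simulate_feature_dataset(n_subjects = 4, n_trials = 5, n_features = 6,
                                 n_samples = 30, informative = 1:3, seed = 29)
  d2 <- simulate_feature_dataset(n_subjects = 4, n_trials = 5, n_features = 6,
                                 n_samples = 30, informative = 1:3, seed = 31)
  subs <- enumerate_subsets(6, 2, 5)
  sc <- sensitivity_scan(list(A = d1, B = d2), subs, n_repeats = 2, seed = 3,
                         perplexity = 4, n_iter = 250)
  expect_equal(nrow(sc$table), length(subs))
  expect_true(all(sc$table$mean_quality >= 0 & sc$table$mean_quality <= 1))
  expect_equal(sc$table$mean_quality, rowMeans(sc$table[, c("A", "B")]))

  # evaluating the subsets in reverse order gives identical results
  sc_rev <- sensitivity_scan(list(A = d1, B = d2), rev(subs), n_repeats = 2,
                             seed = 3, perplexity = 4, n_iter = 250)
  m1 <- sc$table[order(sc$table$subset), c("subset", "A", "B", "mean_quality")]
  m2 <- sc_rev$table[order(sc_rev$table$subset),
                     c("subset", "A", "B", "mean_quality")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("aggregation: single object equals its own table, duplicates average to themselves", {
  d <- simulate_feature_dataset(n_subjects = 4, n_trials = 5, n_features = 6,
                                n_samples = 30, informative = 1:3, seed = 37)
  subs <- enumerate_subsets(6, 2, 3)
  sc1 <- sensitivity_scan(list(only = d), subs, n_repeats = 1, seed = 5,
                          perplexity = 4, n_iter = 250)
  expect_equal(sc1$table$mean_quality, sc1$table$only)
})

test_that("size profile brackets and degenerate cases", {
  d <- simulate_feature_dataset(n_subjects = 4, n_trials = 5, n_features = 6,
                                n_samples = 30, informative = 1:3, seed = 43)
  subs <- enumerate_subsets(6, 2, 5)
  sc <- sensitivity_scan(d, subs, n_repeats = 1, seed = 7, perplexity = 4,
                         n_iter = 250)
  prof <- size_profile(sc)
  expect_true(all(prof$min <= prof$mean & prof$mean <= prof$max))

  # a single subset per size collapses the bracket
  one <- sensitivity_scan(d, list(c(1, 2), c(1, 2, 3)), n_repeats = 1,
                          seed = 7, perplexity = 4, n_iter = 250)
  p1 <- size_profile(one)
  expect_equal(p1$min, p1$max)
  expect_equal(p1$min, p1$mean)

  bs <- best_subset(sc, 5)
  expect_equal(bs$quality, max(sc$table$mean_quality[sc$table$size == 5]))
  expect_error(best_subset(sc, 6), class = "graspid_config_error")
})

test_that("the best-subset grid marks the winning features per object", {
  d <- simulate_feature_dataset(n_subjects = 4, n_trials = 5, n_features = 6,
                                n_samples = 30, informative = 1:3, seed = 61)
  sc <- sensitivity_scan(list(A = d, B = d), enumerate_subsets(6, 3, 3),
                         n_repeats = 1, seed = 13, perplexity = 4,
                         n_iter = 250)
  grid <- best_subset_grid(sc, 3)
  expect_equal(grid$dataset, c("A", "B", "combined"))
  expect_equal(unname(rowSums(grid[, 2:7])), rep(3, 3))
  best <- best_subset(sc, 3)
  expect_equal(which(unlist(grid[3, 2:7])), best$subset,
               ignore_attr = TRUE)
})

test_that("time-window scan: window count and full-width equivalence", {
  d <- simulate_feature_dataset(n_subjects = 4, n_trials = 5, n_features = 4,
                                n_samples = 50, informative = 1:4, seed = 47)
  tw <- time_window_scan(d, window_width = 10, n_repeats = 1, seed = 9,
                         perplexity = 4, n_iter = 250)
  expect_equal(nrow(tw), 5)
  expect_equal(tw$start, seq(1, 41, by = 10))

  # width = n_samples: a single window, nothing substituted -> equals the
  # plain pipeline accuracy under the scan's derived seed
  tw_full <- time_window_scan(d, window_width = 50, n_repeats = 1, seed = 9,
                              perplexity = 4, n_iter = 250)
  expect_equal(nrow(tw_full), 1)
  rseed <- derive_seed(9, "window", 1, 1)
  expected <- cross_validate(d, seed = rseed, perplexity = 4,
                             n_iter = 250)$mean_accuracy
  expect_equal(tw_full$quality, expected)

  expect_error(time_window_scan(d, window_width = 0),
               class = "graspid_config_error")
})

test_that("the most informative window is found by the scan", {
  # subject signal planted only in samples 21-30 of every feature
  set.seed(53)
  n_sub <- 5; n_tr <- 6; n_feat <- 6; s <- 50
  subject <- rep(sprintf("S%d", 1:n_sub), each = n_tr)
  X <- matrix(rnorm(n_sub * n_tr * n_feat * s), n_sub * n_tr)
  for (i in seq_len(nrow(X))) {
    subj <- (i - 1) %/% n_tr + 1
    set.seed(1000 + subj)
    sig <- rnorm(10, sd = 1.2)
    for (f in seq_len(n_feat)) {
      cols <- (f - 1) * s + 21:30
      X[i, cols] <- 0.5 * X[i, cols] + sig
    }
  }
  d <- graspid:::.make_dataset(X, subject, feature_names. = paste0("f", 1:n_feat),
                               n_samples = s)
  tw <- time_window_scan(d, window_width = 10, n_repeats = 2, seed = 3,
                         perplexity = 6, n_iter = 300)
  expect_equal(tw$start[which.max(tw$quality)], 21)
})

test_that("informative subsets dominate the top of a reduced scan", {
  d <- simulate_feature_dataset(n_subjects = 6, n_trials = 5, n_features = 8,
                                n_samples = 30, informative = 1:4, seed = 59)
  subs <- enumerate_subsets(8, 3, 4)
  sc <- sensitivity_scan(d, subs, n_repeats = 2, seed = 11, perplexity = 6,
                         n_iter = 300)
  tab <- sc$table
  n_inf <- vapply(sc$subsets, function(s) sum(s <= 4), 0L)
  top <- order(-tab$mean_quality)[seq_len(ceiling(nrow(tab) / 10))]
  # the top decile of subsets is dominated by informative-heavy subsets
  expect_gt(mean(n_inf[top]), mean(n_inf) + 0.75)
  # and the best size-4 subset is the planted one
  expect_equal(sort(best_subset(sc, 4)$subset), 1:4)
  # refinement re-scores the top candidates and agrees here
  ref <- best_subset_refined(d, sc, 4, top = 10, n_repeats = 4, seed = 11,
                             perplexity = 6, n_iter = 300)
  expect_equal(sort(ref$subset), 1:4)
  expect_true(ref$quality >= 0 && ref$quality <= 1)
})
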