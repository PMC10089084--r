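# small fast roster for pipeline-level experiments on blob data
fast_roster <- c("lda", "dt", "ridge")

test_that("backward elimination traces the argmin-precision rule to one class", {
  tab <- make_blobs(30, k = 4, p = 4, sep = 8, seed = 61)
  trace <- backward_eliminate(tab, roster = fast_roster, folds = 3,
                              budget = 1, seed = 3,
                              features = blob_features())
  expect_s3_class(trace, "elimination_trace")
  expect_equal(nrow(trace), 4L)
  expect_equal(trace$n_classes, 4:1)
  expect_equal(trace$iteration, 1:4)
  # separable classes stay at ceiling accuracy throughout
  expect_true(all(trace$accuracy == 1))
  # each dropped class had minimal precision at its iteration, ties -> lowest id
  precs <- attr(trace, "class_precision")
  for (i in seq_len(nrow(trace))) {
    p <- precs[[i]]
    cand <- names(p)[p == min(p)]
    expect_equal(trace$dropped[i],
                 cand[which.min(as.numeric(cand))])
  }
  # remaining sets shrink by exactly the dropped class
  rem <- attr(trace, "remaining")
  for (i in 2:4) {
    expect_setequal(rem[[i]], setdiff(rem[[i - 1]], trace$dropped[i - 1]))
  }
  expect_error(backward_eliminate(tab[tab$label == 1, ]), "at least 2")
})

test_that("Y-scrambling collapses to chance while the true model stays high", {
  # signal vs chance on separable blobs: the unscrambled model is perfect,
  # every scrambled refit is not
  tab <- make_blobs(80, k = 4, p = 4, sep = 8, seed = 71)
  sp <- stratified_split(tab, 0.25, seed = 2)
  ys <- y_scramble(sp$train, sp$test, "lda", repeats = 15, seed = 9,
                   features = blob_features())
  expect_length(ys$scrambled, 15)
  expect_equal(ys$reference, 1)
  expect_gt(ys$reference, max(ys$scrambled))
  # single repeat allowed
  expect_length(y_scramble(sp$train, sp$test, "lda", repeats = 1, seed = 1,
                           features = blob_features())$scrambled, 1)

  # chance-level law on featureless data (no cluster structure, so repeat
  # accuracies are near-binomial): mean ~ 1/K, spread shrinks with test size
  noise_tab <- function(n, seed) {
    t <- make_blobs(n, k = 4, p = 4, sep = 0, sd = 1, seed = seed)
    t
  }
  spn <- stratified_split(noise_tab(80, 73), 0.25, seed = 2)
  ysn <- y_scramble(spn$train, spn$test, "lda", repeats = 20, seed = 9,
                    features = blob_features())
  expect_lt(abs(mean(ysn$scrambled) - 0.25), 0.03)
  spb <- stratified_split(noise_tab(400, 74), 0.25, seed = 2)
  ysb <- y_scramble(spb$train, spb$test, "lda", repeats = 20, seed = 9,
                    features = blob_features())
  expect_lt(abs(mean(ysb$scrambled) - 0.25), 0.02)
  expect_lt(sd(ysb$scrambled), sd(ysn$scrambled))
})

test_that("feature importance ranks an informative feature over pure noise", {
  set.seed(81)
  n <- 150
  tab <- data.frame(
    signal = rep(c(0, 4), each = n) + rnorm(2 * n),
    noise = rnorm(2 * n),
    label = rep(1:2, each = n)
  )
  imp <- feature_importance(tab, "lightgbm", seed = 1,
                            features = c("signal", "noise"))
  expect_equal(imp$feature[1], "signal")
  expect_true(all(imp$gain >= 0))
  expect_equal(nrow(imp), 2L)
  expect_error(feature_importance(tab, "lda", features = c("signal", "noise")),
               "tree-ensemble")
  # random-forest route agrees on the ranking
  imp_rf <- feature_importance(tab, "rf", seed = 1,
                               features = c("signal", "noise"))
  expect_equal(imp_rf$feature[1], "signal")
})

test_that("feature ablation reproduces the baseline at full width", {
  tab <- make_blobs(40, k = 3, p = 4, sep = 8, seed = 91)
  sp <- stratified_split(tab, 0.25, seed = 5)
  imp <- feature_importance(sp$train, "lightgbm", seed = 2,
                            features = blob_features())
  curve <- feature_ablation_curve(sp$train, sp$test, imp$feature,
                                  family = "lightgbm", seed = 7)
  expect_equal(nrow(curve), 4L)
  expect_equal(curve$n_features, 4:1)
  base <- train_reader(sp$train, "lightgbm",
                       seed = nanobarcoder:::derive_seed(7, "abl4"),
                       features = imp$feature)
  expect_equal(curve$accuracy[1], evaluate_reader(base, sp$test)$accuracy)
  expect_error(feature_ablation_curve(sp$train, sp$test, c("f1", "zz")),
               "unknown")
})

test_that("learning curve improves with observations per class", {
  tab <- make_blobs(300, k = 3, p = 4, sep = 3, sd = 2, seed = 95)
  lc <- learning_curve(tab, c(20, 250), family = "lda", seed = 3,
                       features = blob_features())
  expect_equal(lc$size, c(20, 250))
  expect_gte(lc$accuracy[2], lc$accuracy[1])
  expect_equal(nrow(learning_curve(tab, 50, family = "lda", seed = 3,
                                   features = blob_features())), 1L)
  expect_error(learning_curve(tab, c(10, 500), family = "lda", seed = 1,
                              features = blob_features()),
               "fewer than 500")
})

test_that("PCA matches an eigendecomposition oracle and centering invariance", {
  set.seed(105)
  tab <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  names(tab) <- paste0("f", 1:5)
  pc <- pca_fingerprint(tab, components = 3, features = names(tab))
  # explained variance sums to 100 and is non-increasing
  expect_equal(sum(pc$explained_variance), 100)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # oracle: eigendecomposition of the centered covariance
  X <- as.matrix(tab)
  eg <- eigen(cov(X), symmetric = TRUE)
  expect_equal(pc$explained_variance,
               100 * eg$values / sum(eg$values))
  sc_oracle <- scale(X, center = TRUE, scale = FALSE) %*% eg$vectors[, 1:3]
  for (j in 1:3) {
    expect_equal(abs(pc$scores[, j]), abs(sc_oracle[, j]), tolerance = 1e-8)
  }
  # scores' covariance is diagonal
  cv <- cov(pc$scores)
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-8))
  # mean-shift invariance
  tab2 <- tab
  tab2$f1 <- tab2$f1 + 100
  pc2 <- pca_fingerprint(tab2, components = 3, features = names(tab))
  expect_equal(pc2$scores, pc$scores)
  # 1-D data: PC1 explains everything
  t <- seq(0, 1, length.out = 30)
  line <- as.data.frame(outer(t, c(1, -2, 3, 0.5, 1)))
  names(line) <- paste0("f", 1:5)
  pcl <- pca_fingerprint(line, components = 1, features = names(line))
  expect_equal(pcl$explained_variance[1], 100)
  expect_error(pca_fingerprint(tab, components = 9, features = names(tab)),
               "exceeds")
})

test_that("virtual mixtures sample equally, stay unlabeled and score correctly", {
  tab <- make_blobs(150, k = 3, p = 4, sep = 8, seed = 111)
  sp <- stratified_split(tab, 0.3, seed = 2)
  model <- train_reader(sp$train, "lda", features = blob_features())
  mx <- make_mixture(sp$test, c(1, 2), 30, seed = 4)
  expect_equal(nrow(mx$table), 60L)
  expect_false("label" %in% names(mx$table))
  expect_equal(unname(table(mx$key)), c(30L, 30L), ignore_attr = TRUE)
  res <- evaluate_mixture(model, mx)
  expect_equal(res$confusion$accuracy, 1)
  expect_equal(sum(res$histogram), 60)
  expect_error(make_mixture(sp$test, c(1, 2), 1000, seed = 1), "only")
})

test_that("mixture scoring mirrors the standard test-set precisions", {
  # overlapping classes so precisions are informative, not all 1
  tab <- make_blobs(400, k = 3, p = 4, sep = 2.2, sd = 2, seed = 115)
  sp <- stratified_split(tab, 0.5, seed = 2)
  model <- train_reader(sp$train, "lda", features = blob_features())
  cm_std <- evaluate_reader(model, sp$test)
  mx <- make_mixture(sp$test, 1:3, 150, seed = 9)
  cm_mix <- evaluate_mixture(model, mx)$confusion
  expect_lt(max(abs(cm_mix$precision - cm_std$precision)), 0.12)
})
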