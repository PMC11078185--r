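test_that("binarization thresholds at the per-channel mean, strictly", {
  m <- rbind(c(1, 5), c(3, 5))
  f <- binarize(m)
  expect_equal(f, rbind(c(0, 0), c(1, 0)), ignore_attr = TRUE)
  expect_equal(attr(f, "thresholds"), c(2, 5))
  # identical events: nothing strictly exceeds its own mean
  same <- matrix(4, 5, 3)
  expect_true(all(binarize(same) == 0))
  expect_true(all(binarize(matrix(0, 4, 2)) == 0))
  expect_error(binarize(matrix(numeric(0), 0, 3)), "event")
})

test_that("the stratified split is exact, seeded and validated", {
  labels <- rep(c("MEP_L", "MEP_R", "SSEP_L", "SSEP_R"), each = 25)
  sp <- split_stratified(labels, 0.60, seed = 3)
  expect_length(sp$train, 60)
  expect_length(sp$test, 40)
  expect_true(all(table(labels[sp$train]) == 15))
  expect_true(all(table(labels[sp$test]) == 10))
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, split_stratified(labels, 0.60, seed = 3))
  expect_error(split_stratified(c("MEP_L", "MEP_L", "MEP_R")),
               "MEP_R")
})

test_that("k = 1 city-block KNN matches an exhaustive oracle", {
  set.seed(31)
  n <- 200
  x <- matrix(runif(n * 32), n)
  y <- sample(c("MEP_L", "MEP_R", "SSEP_L", "SSEP_R"), n, replace = TRUE)
  sp <- split_stratified(y, 0.60, seed = 5)
  res <- knn_classify(x[sp$train, ], y[sp$train], x[sp$test, ],
                      test_y = y[sp$test])
  # O(n^2) brute-force nearest neighbour under L1
  oracle <- vapply(sp$test, function(i) {
    d <- vapply(sp$train, function(j) sum(abs(x[i, ] - x[j, ])), numeric(1))
    y[sp$train[which.min(d)]]
  }, character(1))
  expect_identical(res$predicted, oracle)
  # confusion-matrix invariants
  expect_equal(sum(res$confusion), length(sp$test))
  expect_equal(res$accuracy, sum(diag(res$confusion)) / length(sp$test))
  expect_equal(as.numeric(rowSums(res$confusion)),
               as.numeric(table(factor(y[sp$test],
                                       levels = rownames(res$confusion)))))

  # self-classification with k = 1 is perfect
  self <- knn_classify(x[sp$train, ], y[sp$train], x[sp$train, ],
                       test_y = y[sp$train])
  expect_equal(self$accuracy, 1.0)

  # predictions are invariant under a consistent channel permutation
  perm <- sample(32)
  res_p <- knn_classify(x[sp$train, perm], y[sp$train], x[sp$test, perm])
  expect_identical(res_p$predicted, res$predicted)

  expect_error(knn_classify(x[sp$train, ], y[sp$train],
                            x[sp$test, 1:10]), "dimension")
})

test_that("PCA embeddings match an independent eigendecomposition", {
  set.seed(32)
  x <- matrix(rnorm(300), 50, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  sc <- reduce_pca(x, 3)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(attr(sc, "variance_ratio"), (ev / sum(ev))[1:3],
               tolerance = 1e-10)
  expect_true(all(diff(apply(sc, 2, var)) <= 1e-12))
  # one-dimensional data: first component carries all variance
  one <- outer(rnorm(30), c(1, 2, 3))
  expect_equal(attr(reduce_pca(one, 1), "variance_ratio")[1], 1)
  # full rank keeps all information: reconstruction is exact
  full <- reduce_pca(x, 6)
  rebuilt <- full %*% t(attr(full, "rotation"))
  rebuilt <- sweep(rebuilt, 2, colMeans(x), "+")
  expect_equal(rebuilt, x, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(reduce_pca(x, 0), "n_components")
})

test_that("UMAP is seeded when available and fails clearly when not", {
  x <- matrix(rnorm(200), 50, 4)
  if (requireNamespace("uwot", quietly = TRUE)) {
    a <- reduce_umap(x, 2, seed = 7)
    b <- reduce_umap(x, 2, seed = 7)
    expect_equal(a, b)
  } else {
    expect_error(reduce_umap(x, 2), "reduce_pca")
  }
})

test_that("clustering separates point masses and honours its contract", {
  x <- rbind(matrix(0, 10, 4), matrix(10, 12, 4))
  truth <- rep(c("TIBIAL", "PERONEAL"), c(10, 12))
  cl <- cluster_sources(x, 2, seed = 1, true_labels = truth)
  expect_equal(cl$agreement, 1.0)
  expect_length(unique(cl$cluster), 2)
  km <- cluster_sources(x, 2, seed = 1, method = "kmeans",
                        true_labels = truth)
  expect_equal(km$agreement, 1.0)
  expect_error(cluster_sources(x, 1), "n_clusters")
})
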