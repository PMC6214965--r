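test_that("k-means separates well-separated clouds and validates inputs", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40 * 2, -10, 0.1), ncol = 2),
             matrix(rnorm(40 * 2, 10, 0.1), ncol = 2))
  truth <- rep(1:2, each = 40)
  m <- kmeans_cluster(X, 2, restarts = 10, seed = 5)
  expect_equal(adjusted_rand_index(m$labels, truth), 1)
  # centers are the means of their members
  for (c in 1:2)
    expect_equal(m$centers[c, ], colMeans(X[m$labels == c, , drop = FALSE]))
  # SSE trace is non-increasing
  expect_true(all(diff(m$sse_trace) <= 1e-12))

  expect_error(kmeans_cluster(X, 1), "k must be")
  expect_error(kmeans_cluster(X[1:3, ], 4), "exceeds")
  expect_error(kmeans_cluster(matrix(1, 10, 3), 2), "degenerate")
  expect_error(kmeans_cluster(matrix(c(1, NA), 4, 2), 2), "finite")
})

test_that("best-of-restarts SSE matches the exhaustive-partition optimum", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(n * 2), ncol = 2)
    m <- kmeans_cluster(X, k, restarts = 50, seed = rep)
    expect_equal(m$sse, oracle_best_sse(X, k), tolerance = 1e-9)
  }
})

test_that("fixed seed and restarts make clustering bit-reproducible", {
  set.seed(9)
  X <- matrix(rnorm(60 * 4), ncol = 4)
  m1 <- kmeans_cluster(X, 3, restarts = 20, seed = 77)
  m2 <- kmeans_cluster(X, 3, restarts = 20, seed = 77)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$sse, m2$sse)
  expect_identical(m1$centers, m2$centers)
})

test_that("partitions agree with stats::kmeans on well-separated data", {
  set.seed(11)
  X <- rbind(matrix(rnorm(30 * 3, 0, 0.3), ncol = 3),
             matrix(rnorm(30 * 3, 5, 0.3), ncol = 3),
             matrix(rnorm(30 * 3, -5, 0.3), ncol = 3))
  ours <- kmeans_cluster(X, 3, restarts = 20, seed = 3)
  ref <- stats::kmeans(X, 3, nstart = 20)
  expect_equal(adjusted_rand_index(ours$labels, ref$cluster), 1)
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-8)
})

test_that("mean silhouette follows the (b - a)/max(a, b) definition", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # hand computation: s = (9.5/10.5, 8.5/9.5, 8.5/9.5, 9.5/10.5)
  expect_equal(mean_silhouette(X, lab),
               (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)
  expect_equal(round(mean_silhouette(X, lab), 4), 0.8997)

  # coincident clusters score <= 0
  Y <- rbind(matrix(1:6, ncol = 2), matrix(1:6, ncol = 2))
  expect_lte(mean_silhouette(Y, rep(1:2, each = 3)), 0)

  # separation -> 1 in the wide-separation limit
  Z <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
             matrix(rnorm(20, 1e4, 0.01), ncol = 2))
  expect_gt(mean_silhouette(Z, rep(1:2, each = 10)), 0.999)

  expect_error(mean_silhouette(X, rep(1, 4)), "two clusters")
})

test_that("mean silhouette matches a brute-force oracle to 1e-12", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * 3), ncol = 3)
    lab <- sample(rep_len(seq_len(k), n))  # every cluster nonempty
    expect_equal(mean_silhouette(X, lab), oracle_mean_silhouette(X, lab),
                 tolerance = 1e-12)
  }
  # singleton clusters contribute 0
  X <- matrix(c(0, 0.1, 5), ncol = 1)
  expect_equal(mean_silhouette(X, c(1, 1, 2)),
               oracle_mean_silhouette(X, c(1, 1, 2)), tolerance = 1e-12)
})

test_that("silhouette-based k selection finds planted cluster counts", {
  set.seed(4)
  X3 <- rbind(matrix(rnorm(30 * 2, 0, 0.2), ncol = 2),
              matrix(rnorm(30 * 2, 4, 0.2), ncol = 2),
              cbind(rnorm(30, 4, 0.2), rnorm(30, -4, 0.2)))
  expect_identical(select_k(X3, 2:6, restarts = 20, seed = 1)$k, 3L)
  X2 <- rbind(matrix(rnorm(40 * 2, -3, 0.2), ncol = 2),
              matrix(rnorm(40 * 2, 3, 0.2), ncol = 2))
  expect_identical(select_k(X2, 2:5, restarts = 20, seed = 1)$k, 2L)
  expect_error(select_k(X2, integer(0)), "empty")
  expect_error(select_k(X2[1:4, ], 2:6), "within")
})

test_that("canonical labelling orders clusters by size then center, idempotently", {
  set.seed(8)
  X <- rbind(matrix(rnorm(24 * 2, 0, 0.1), ncol = 2),
             matrix(rnorm(21 * 2, 6, 0.1), ncol = 2),
             matrix(rnorm(19 * 2, -6, 0.1), ncol = 2))
  m <- kmeans_cluster(X, 3, restarts = 20, seed = 2)
  expect_identical(m$sizes, c(24L, 21L, 19L))
  expect_identical(unname(m$labels[1]), 1L)    # largest cluster is label 1
  expect_identical(unname(m$labels[25]), 2L)
  expect_identical(unname(m$labels[46]), 3L)
  m2 <- canonicalize_labels(m)
  expect_identical(m2$labels, m$labels)
  expect_identical(m2$centers, m$centers)

  # equal sizes: deterministic order by lexicographic center comparison
  Y <- rbind(matrix(rnorm(10 * 2, 5, 0.05), ncol = 2),
             matrix(rnorm(10 * 2, -5, 0.05), ncol = 2))
  mm <- kmeans_cluster(Y, 2, restarts = 10, seed = 1)
  expect_true(mm$centers[1, 1] < mm$centers[2, 1])
})

test_that("adjusted Rand index agrees with mclust's implementation", {
  set.seed(21)
  for (rep in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
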