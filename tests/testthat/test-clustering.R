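test_that("kmeans recovers closed-form optima", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  fit <- kmeans_cluster(x, 2, seed = 3)
  expect_equal(fit$inertia, 0.01)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_true(fit$labels[1] != fit$labels[3])

  expect_equal(kmeans_cluster(x, 4, seed = 1)$inertia, 0)
  expect_equal(kmeans_cluster(x, 1, seed = 1)$inertia,
               sum(scale(x, scale = FALSE)^2))
  expect_error(kmeans_cluster(x, 5), "k must lie")
})

test_that("best-of-restarts equals the exhaustive optimum on small sets", {
  for (seed in 1:5) {
    x <- with_seed_test(seed, matrix(stats::rnorm(14), 7, 2))
    for (k in 2:3) {
      fit <- kmeans_cluster(x, k, seed = seed)
      expect_equal(fit$inertia, oracle_kmeans_optimum(x, k), tolerance = 1e-8)
    }
  }
})

test_that("kmeans and spectral are deterministic given a seed", {
  x <- make_blobs(3, n_per = 8)$x
  expect_identical(kmeans_cluster(x, 3, seed = 11)$labels,
                   kmeans_cluster(x, 3, seed = 11)$labels)
  expect_identical(spectral_cluster(x, 3, seed = 11)$labels,
                   spectral_cluster(x, 3, seed = 11)$labels)
})

test_that("inertia curves decrease and vanish at k = n", {
  x <- with_seed_test(2, matrix(stats::rnorm(40), 10, 4))
  curve <- inertia_curve(x, 10, seed = 4)
  expect_true(all(diff(curve$inertia) <= 1e-9))
  expect_equal(curve$inertia[10], 0)

  blobs <- make_blobs(4, n_per = 9)
  cb <- inertia_curve(blobs$x, 8, seed = 4)
  drops <- -diff(cb$inertia)
  expect_gt(min(drops[1:3]), 5 * max(drops[4:7]))
})

test_that("the elbow rule maximizes the second forward difference", {
  expect_equal(select_k_elbow(data.frame(k = 1:6,
    inertia = c(1000, 600, 300, 50, 45, 42))), 4L)
  expect_equal(select_k_elbow(data.frame(k = 1:5,
    inertia = c(100, 10, 9, 8.5, 8.4))), 2L)
  # flat curve: smallest-k tie-break
  expect_equal(select_k_elbow(data.frame(k = 1:4,
    inertia = c(10, 10, 10, 10))), 2L)
  expect_error(select_k_elbow(data.frame(k = 1:2, inertia = c(2, 1))),
               "at least")
})

test_that("spectral clustering recovers planted partitions", {
  blobs <- make_blobs(2, n_per = 10)
  fit <- spectral_cluster(blobs$x, 2, seed = 5)
  expect_equal(adjusted_rand_index(fit$labels, blobs$labels), 1)
  # k = n: every point its own cluster
  xs <- make_blobs(2, n_per = 3)$x
  expect_setequal(spectral_cluster(xs, nrow(xs), seed = 1)$labels,
                  0:(nrow(xs) - 1))
  expect_error(spectral_cluster(matrix(1, 5, 2), 2), "degenerate")
})

test_that("dbscan separates dense blobs from noise", {
  x <- rbind(matrix(c(0, 0, 0.1, 0, 0, 0.1), 3, 2, byrow = TRUE),
             matrix(c(10, 10, 10.1, 10, 10, 10.1), 3, 2, byrow = TRUE),
             c(100, 100))
  fit <- dbscan_cluster(x, eps = 1, min_samples = 3)
  sz <- cluster_sizes(fit)
  expect_equal(as.integer(sz$sizes), c(3L, 3L))
  expect_equal(sz$noise, 1L)
  # limits: infinite radius -> one cluster; vanishing radius -> all noise
  expect_equal(unique(dbscan_cluster(x, eps = 1e6, min_samples = 1)$labels), 0L)
  expect_true(all(dbscan_cluster(x, eps = 1e-9, min_samples = 2)$labels == -1L))
  expect_error(dbscan_cluster(x, eps = 0), "eps")
})

test_that("ward agglomeration merges by variance", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  fit <- agglomerative_cluster(x, 2)
  expect_equal(fit$labels, c(0L, 0L, 1L))
  expect_equal(agglomerative_cluster(x, 3)$labels, 0:2)
  blobs <- make_blobs(3, n_per = 8)
  expect_equal(adjusted_rand_index(
    agglomerative_cluster(blobs$x, 3)$labels, blobs$labels), 1)
})

test_that("ARI follows the pair-counting formula", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(5, 5, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  for (seed in 1:20) {
    ab <- with_seed_test(seed, list(sample(0:3, 30, TRUE), sample(0:2, 30, TRUE)))
    expect_equal(adjusted_rand_index(ab[[1]], ab[[2]]),
                 oracle_ari(ab[[1]], ab[[2]]))
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  for (seed in 1:10) {
    ab <- with_seed_test(seed, list(sample(0:3, 25, TRUE), sample(0:4, 25, TRUE)))
    expect_equal(adjusted_rand_index(ab[[1]], ab[[2]]),
                 mclust::adjustedRandIndex(ab[[1]], ab[[2]]))
  }
})

test_that("random partitions have null ARI near zero", {
  aris <- with_seed_test(99, vapply(1:1000, function(i)
    adjusted_rand_index(sample(0:3, 37, TRUE), sample(0:3, 37, TRUE)),
    double(1)))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("cluster sizes partition the samples", {
  expect_equal(as.integer(cluster_sizes(
    breathmap:::cluster_result("kmeans", c(0, 0, 1)))$sizes), c(2L, 1L))
  sz <- cluster_sizes(breathmap:::cluster_result("dbscan", c(0, -1, 0)))
  expect_equal(as.integer(sz$sizes), 2L)
  expect_equal(sz$noise, 1L)
})
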