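two_mass_dataset <- function() {
  # 20 cases at (0,0), 20 at (2,2), plus 10 controls that must be ignored
  g <- rbind(matrix(0L, 20, 2), matrix(2L, 20, 2),
             matrix(1L, 10, 2))
  genotype_dataset(g, c(rep(1L, 40), rep(0L, 10)))
}

test_that("separable point masses split perfectly with zero inertia", {
  ds <- two_mass_dataset()
  a <- cluster_cases(ds, c(1, 2), K = 2, seed = 1)
  expect_equal(a$inertia, 0)
  expect_length(a$case_indices, 40)                 # controls never clustered
  expect_equal(length(unique(a$cluster_of[1:20])), 1)
  expect_equal(length(unique(a$cluster_of[21:40])), 1)
  expect_false(a$cluster_of[1] == a$cluster_of[21])
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(3)
  g <- matrix(sample(0:2, 200 * 4, replace = TRUE), 200, 4)
  ds <- genotype_dataset(g, rep(c(0L, 1L), 100))
  a <- cluster_cases(ds, 1:4, K = 3, seed = 9)
  b <- cluster_cases(ds, 1:4, K = 3, seed = 9)
  expect_identical(a$cluster_of, b$cluster_of)
  expect_identical(a$centroids, b$centroids)
})

test_that("K-means attains the exhaustive-bipartition optimum on 12 points", {
  set.seed(17)
  x <- matrix(sample(0:2, 24, replace = TRUE), 12, 2)
  ds <- genotype_dataset(x, rep(1L, 12))
  a <- cluster_cases(ds, c(1, 2), K = 2, seed = 5)
  expect_equal(a$inertia, oracle_best_bipartition_inertia(x * 1.0), tolerance = 1e-9)
})

test_that("inertia agrees with the reference K-means implementation", {
  set.seed(21)
  g <- matrix(sample(0:2, 300 * 3, replace = TRUE), 300, 3)
  ds <- genotype_dataset(g, rep(1L, 300))
  a <- cluster_cases(ds, 1:3, K = 2, seed = 2)
  ref <- stats::kmeans(g * 1.0, centers = 2, nstart = 10, iter.max = 300,
                       algorithm = "Lloyd")
  # k-means++ restarts must do at least as well as random-start Lloyd
  expect_lte(a$inertia, ref$tot.withinss + 1e-6)
  # and the reported inertia is the true within-cluster sum of squares
  wss <- sum(vapply(1:2, function(k) {
    xs <- g[a$cluster_of == k, , drop = FALSE] * 1.0
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
  expect_equal(a$inertia, wss, tolerance = 1e-9)
})

test_that("inertia is non-increasing across Lloyd iterations", {
  set.seed(33)
  g <- matrix(sample(0:2, 400 * 5, replace = TRUE), 400, 5)
  ds <- genotype_dataset(g, rep(1L, 400))
  a <- cluster_cases(ds, 1:5, K = 4, seed = 6)
  expect_true(all(diff(a$inertia_trace) <= 1e-9))
})

test_that("cluster structure is invariant to case row order", {
  set.seed(41)
  g <- rbind(matrix(rbinom(60, 2, 0.15), 30, 2), matrix(rbinom(60, 2, 0.85), 30, 2))
  ds <- genotype_dataset(g, rep(1L, 60))
  perm <- sample.int(60)
  dsp <- genotype_dataset(g[perm, ], rep(1L, 60))
  a <- cluster_cases(ds, c(1, 2), K = 2, seed = 3)
  b <- cluster_cases(dsp, c(1, 2), K = 2, seed = 4)
  la <- a$canonical[a$cluster_of]
  lb <- b$canonical[b$cluster_of]
  expect_identical(la, lb[order(perm)])  # same canonical label per original row
})

test_that("relabeling canonicalizes by cluster size and round-trips to binary", {
  set.seed(2)
  g <- rbind(matrix(0L, 300, 2), matrix(2L, 200, 2), matrix(1L, 100, 2))
  ds <- genotype_dataset(g, c(rep(1L, 500), rep(0L, 100)))
  a <- cluster_cases(ds, c(1, 2), K = 2, seed = 1)
  mc <- relabel_cases(ds, a)
  expect_equal(sum(mc$labels == 0), 100)                 # controls untouched
  expect_equal(sum(mc$labels == 1), 300)                 # larger cluster -> label 1
  expect_equal(sum(mc$labels == 2), 200)
  expect_identical(as.integer(mc$labels >= 1), ds$labels)  # binary round trip
  expect_identical(mc$binary_labels, ds$labels)
})

test_that("relabeling rejects a mismatched assignment", {
  ds <- two_mass_dataset()
  a <- cluster_cases(ds, c(1, 2), K = 2, seed = 1)
  ds2 <- genotype_dataset(ds$genotypes, rev(ds$labels))
  expect_error(relabel_cases(ds2, a), "case samples")
})

test_that("nearest-centroid prediction extends cluster labels to new samples", {
  ds <- two_mass_dataset()
  a <- cluster_cases(ds, c(1, 2), K = 2, seed = 1)
  pred <- predict(a, matrix(c(0L, 0L, 2L, 2L), 2, 2, byrow = TRUE))
  in_sample <- a$canonical[a$cluster_of]
  expect_equal(pred[1], in_sample[1])
  expect_equal(pred[2], in_sample[21])
})

test_that("adjusted Rand index matches its oracle and its fixed points", {
  expect_equal(clustering_agreement(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # relabeling
  expect_equal(clustering_agreement(rep(1, 20), rep(1:2, 10)), 0)      # one cluster
  set.seed(14)
  for (rep in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:2, 20, replace = TRUE)
    expect_equal(clustering_agreement(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("subtypes are recovered on heterogeneous data with marginal-bearing epistasis", {
  aris <- vapply(1:5, function(s) {
    m1 <- domdom_model(2, 0.2, 0.02, 0.95, c(5, 20))
    m2 <- domdom_model(2, 0.3, 0.02, 0.95, c(11, 28))
    ds <- simulate_heterogeneous(2000, 30, m1, m2, 0.5, seed = s)
    a <- cluster_cases(ds, c(5, 20, 11, 28), K = 2, seed = s)
    clustering_agreement(a, ds$truth$subtype[a$case_indices])
  }, numeric(1))
  expect_gte(median(aris), 0.3)
})
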