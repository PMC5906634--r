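test_that("genotype combination indexing is the expected base-3 bijection", {
  expect_equal(genotype_combination_index(c(0, 0)), 0)
  expect_equal(genotype_combination_index(c(2, 2, 2)), 26)
  grid <- as.matrix(expand.grid(g2 = 0:2, g1 = 0:2))[, c("g1", "g2")]
  idx <- genotype_combination_index(grid)
  expect_setequal(idx, 0:8)                      # bijective over 3^2 cells
  expect_equal(genotype_combination_index(c(1, 0)), 3)  # first SNP most significant
  expect_error(genotype_combination_index(c(0, 3)), "0, 1 or 2")
})

test_that("mutual information is zero under independence and H(Y) under determinism", {
  # counts exactly proportional across classes -> independence
  g <- cbind(rep(0:2, each = 20))
  y <- rep(rep(0:1, times = c(10, 10)), 3)
  expect_equal(mutual_information(g, y), 0, tolerance = 1e-12)
  # genotype determines the label, balanced labels -> exactly 1 bit
  g2 <- cbind(rep(c(0, 2), each = 25))
  y2 <- rep(c(0, 1), each = 25)
  expect_equal(mutual_information(g2, y2), 1)
})

test_that("mutual information matches the brute-force entropy oracle", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(1:3, 1)
    g <- matrix(sample(0:2, 40 * k, replace = TRUE), 40, k)
    y <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    expect_equal(mutual_information(g, y), oracle_mi(g, y), tolerance = 1e-12)
  }
})

test_that("all three scores are invariant to SNP order within the tuple", {
  set.seed(8)
  g <- matrix(sample(0:2, 300, replace = TRUE), 100, 3)
  y <- sample(0:1, 100, replace = TRUE)
  perm <- g[, c(3, 1, 2)]
  expect_equal(mutual_information(g, y), mutual_information(perm, y))
  expect_equal(k2_score(g, y), k2_score(perm, y))
  expect_equal(chi_square_test(g, y)$chi2, chi_square_test(perm, y)$chi2)
})

test_that("K2 matches the exact-integer factorial oracle and its edge cases", {
  # single occupied cell, all one class: term = log(r + 1)
  expect_equal(k2_score(cbind(rep(1, 7)), rep(1, 7)), log(8))
  # empty cells contribute nothing: extending the support changes no term
  g3 <- rbind(cbind(0, 0), cbind(0, 0))
  expect_equal(k2_score(g3, c(0, 1)), k2_score(matrix(c(0, 0), 2, 1), c(0, 1)))
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(1:2, 1)
    g <- matrix(sample(0:2, 30 * k, replace = TRUE), 30, k)
    y <- sample(0:1, 30, replace = TRUE)
    expect_equal(k2_score(g, y), oracle_k2(g, y), tolerance = 1e-10)
  }
})

test_that("K2 improves (decreases) as association strength grows", {
  k2s <- vapply(c(0.1, 0.2, 0.3, 0.45), function(d) {
    m <- parity_model(2, 0.3, 0.5 - d, 0.5 + d, c(1, 2))
    ds <- simulate_pure(600, 2, m, seed = 77)
    k2_score(ds$genotypes, ds$labels)
  }, numeric(1))
  expect_true(all(diff(k2s) < 0))
})

test_that("chi-square statistic, df and p-value match hand and reference computation", {
  # perfect fit: observed equals expected in every cell
  g <- cbind(rep(0:1, each = 30))
  y <- rep(rep(0:1, each = 15), 2)
  res <- chi_square_test(g, y)
  expect_equal(res$chi2, 0)
  expect_equal(res$pvalue, 1)
  # 2x2 cells 10/20 vs 20/10: margins 30/30 -> E = 15, chi2 = 4*25/15
  g2 <- cbind(rep(0:1, each = 30))
  y2 <- c(rep(0, 10), rep(1, 20), rep(0, 20), rep(1, 10))
  res2 <- chi_square_test(g2, y2)
  expect_equal(res2$chi2, 100 / 15, tolerance = 1e-12)
  expect_equal(res2$df, 1)
  # doubling the data doubles the statistic exactly
  res4 <- chi_square_test(rbind(g2, g2), c(y2, y2))
  expect_equal(res4$chi2, 2 * res2$chi2, tolerance = 1e-12)
  # reference routine agreement on random tables
  set.seed(19)
  for (rep in 1:10) {
    g <- matrix(sample(0:2, 160, replace = TRUE), 80, 2)
    y <- sample(0:1, 80, replace = TRUE)
    ours <- chi_square_test(g, y)
    ref <- suppressWarnings(
      stats::chisq.test(table(genotype_combination_index(g), y), correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$pvalue, ref$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate one-class input is rejected", {
  expect_error(chi_square_test(cbind(c(0, 1, 2)), c(1, 1, 1)), "both classes")
  expect_error(mutual_information(cbind(0:2), c(0, 1)), "mismatch")
})

test_that("null mutual information bias shrinks as sample size grows", {
  mean_null_mi <- function(n) {
    set.seed(55)
    g <- matrix(sample(0:2, 2 * n, replace = TRUE), n, 2)
    y <- rep(0:1, length.out = n)
    mean(vapply(1:200, function(i) mutual_information(g, sample(y)), numeric(1)))
  }
  m100 <- mean_null_mi(100)
  m1000 <- mean_null_mi(1000)
  expect_gt(m100, 0)
  expect_gt(m100, m1000)
})
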