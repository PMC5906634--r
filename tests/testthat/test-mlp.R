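test_that("rectifier and softmax behave by definition", {
  expect_equal(epiheter:::relu(c(-3, 0, 2)), c(0, 0, 2))
  z <- matrix(rnorm(15), 3, 5)
  p <- epiheter:::softmax(z)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # stability under large shifts
  p2 <- epiheter:::softmax(z + 1000)
  expect_equal(p, p2, tolerance = 1e-9)
})

test_that("architecture presets expose the reference deep net", {
  expect_equal(mlp_preset("desk"), c(64L, 32L))
  expect_equal(mlp_preset("paper"), c(2048L, 1024L, 512L, 256L, 128L, 64L))
  m <- build_model(100, mlp_preset("paper"), n_classes = 3, seed = 1)
  dims <- vapply(m$weights, dim, integer(2))
  expect_equal(dims[1, ], c(100L, mlp_preset("paper")))
  expect_equal(dims[2, ], c(mlp_preset("paper"), 3L))
  expect_error(build_model(10, c(64, 0), 2), "hidden_widths")
})

test_that("training reaches perfect accuracy on separable toy data", {
  ds <- toy_dataset(n = 200, n_snps = 3, seed = 5)  # label = SNP1 carries minor allele
  sp <- split_dataset(ds, seed = 1)
  m <- build_model(3, c(64, 32), 2, dropout_rate = 0, seed = 2)
  m <- train_model(m, ds, sp, training_config(seed = 3))
  x <- epiheter:::model_features(ds, training_config())
  pred <- predict_labels(m, x)
  expect_equal(mean(pred[sp$train] == ds$labels[sp$train]), 1.0)
})

test_that("training history is bounded by the epoch budget and records both losses", {
  ds <- toy_dataset(n = 150, n_snps = 4, seed = 9)
  sp <- split_dataset(ds, seed = 2)
  m <- build_model(4, c(16, 8), 2, seed = 1)
  m <- train_model(m, ds, sp, training_config(epochs = 30, seed = 4))
  expect_lte(nrow(m$history), 30)
  expect_named(m$history, c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  expect_true(all(is.finite(unlist(m$history))))
  expect_gte(m$best_epoch, 1)
})

test_that("training and prediction are deterministic under fixed seeds", {
  ds <- toy_dataset(n = 150, n_snps = 4, seed = 9)
  sp <- split_dataset(ds, seed = 2)
  fit <- function() {
    m <- build_model(4, c(16, 8), 2, seed = 1)
    train_model(m, ds, sp, training_config(epochs = 20, seed = 4))
  }
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$weights, m2$weights)
  x <- epiheter:::model_features(ds, training_config())
  p1 <- predict_labels(m1, x); p2 <- predict_labels(m2, x)
  expect_identical(as.integer(p1), as.integer(p2))
  # duplicate rows get identical predictions; probabilities sum to one
  xd <- rbind(x[1, ], x[1, ])
  pd <- predict_labels(m1, xd)
  expect_equal(pd[1], pd[2])
  expect_equal(rowSums(attr(pd, "prob")), c(1, 1), tolerance = 1e-6)
})

test_that("argmax prediction breaks ties toward the smaller class index", {
  # a zero-weight network outputs uniform probabilities for any input
  m <- build_model(2, c(4), 3, seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  p <- predict_labels(m, matrix(runif(10), 5, 2))
  expect_true(all(p == 0L))
})

test_that("evaluation arithmetic, confusion and binary collapse are correct", {
  ev <- evaluate(c(rep(0, 31), rep(1, 69)), c(rep(0, 100)))
  expect_equal(ev$accuracy, 0.31)
  ev2 <- evaluate(0:3, 0:3)
  expect_equal(ev2$accuracy, 1)
  expect_equal(sum(ev2$confusion) - sum(diag(ev2$confusion)), 0)
  expect_error(evaluate(0:1, 0:2), "mismatch")
  # collapsing subtype labels >= 1 to 1 can only help accuracy
  set.seed(6)
  for (rep in 1:20) {
    truth <- sample(0:3, 50, replace = TRUE)
    pred <- sample(0:3, 50, replace = TRUE)
    expect_gte(evaluate(pred, truth, collapse_binary = TRUE)$accuracy,
               evaluate(pred, truth)$accuracy)
  }
})

test_that("model checkpoints round-trip through the JSON container", {
  ds <- toy_dataset(n = 120, n_snps = 4, seed = 3)
  sp <- split_dataset(ds, seed = 1)
  m <- build_model(2, c(8, 4), 2, seed = 2)
  m <- train_model(m, ds, sp,
                   training_config(epochs = 10, seed = 5,
                                   feature_mode = "epistatic_snps",
                                   feature_snps = c(1, 3)))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$feature_snps, c(1L, 3L))
  x <- ds$genotypes[, c(1, 3)] / 2
  expect_identical(as.integer(predict_labels(m, x)),
                   as.integer(predict_labels(m2, x)))
  unlink(path)
})

test_that("dropout regularization narrows the train-validation gap on tiny data", {
  gaps <- function(rate) {
    vapply(1:5, function(s) {
      set.seed(s)
      g <- matrix(rbinom(120 * 20, 2, 0.3), 120, 20)
      y <- as.integer(runif(120) < plogis((g[, 1] - 0.6) * 1.2))
      ds <- genotype_dataset(g, y)
      sp <- split_dataset(ds, test_fraction = 0.2, validation_fraction = 0.3,
                          seed = s)
      m <- build_model(20, c(64, 32), 2, dropout_rate = rate, seed = s)
      m <- train_model(m, ds, sp, training_config(epochs = 60, seed = s + 100))
      h <- m$history[m$best_epoch, ]
      h$train_acc - h$val_acc
    }, numeric(1))
  }
  expect_gte(median(gaps(0)), median(gaps(0.5)))
})
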