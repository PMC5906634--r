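#' Build a feed-forward diagnosis network
#'
#' Fully connected multilayer perceptron for genotype-based diagnosis: input
#' layer of `input_dim` features, rectifier (`f(a) = max(0, a)`) hidden
#' layers of the given widths each followed by dropout (training mode only),
#' and a softmax output layer with one node per class. Weights are
#' He-initialized from a seeded normal scheme; biases start at zero.
#'
#' The default desk-scale architecture (64, 32) is adequate for datasets of
#' around a hundred SNPs; `hidden_widths = mlp_preset("paper")` gives the
#' reference deep architecture (2048, 1024, 512, 256, 128, 64).
#'
#' @param input_dim number of input features.
#' @param hidden_widths integer vector of hidden layer sizes (non-empty,
#'   all >= 1).
#' @param n_classes number of output classes (>= 2).
#' @param dropout_rate dropout probability in \[0, 1) applied after each
#'   hidden layer during training (default 0.5).
#' @param seed seed for weight initialization.
#' @return An object of class `prediction_model` with fields `input_dim`,
#'   `hidden_widths`, `n_classes`, `dropout_rate`, `weights`, `biases`.
#' @export
build_model <- function(input_dim, hidden_widths = c(64L, 32L), n_classes = 2L,
                        dropout_rate = 0.5, seed = 1L) {
  stopifnot(input_dim >= 1, length(hidden_widths) >= 1, all(hidden_widths >= 1),
            n_classes >= 2, dropout_rate >= 0, dropout_rate < 1)
  dims <- c(input_dim, hidden_widths, n_classes)
  with_seed(seed, {
    weights <- biases <- vector("list", length(dims) - 1)
    for (l in seq_len(length(dims) - 1)) {
      fan_in <- dims[l]
      weights[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                             fan_in, dims[l + 1])
      biases[[l]] <- numeric(dims[l + 1])
    }
    structure(list(input_dim = as.integer(input_dim),
                   hidden_widths = as.integer(hidden_widths),
                   n_classes = as.integer(n_classes),
                   dropout_rate = dropout_rate,
                   weights = weights, biases = biases,
                   feature_snps = NULL, label_map = NULL),
              class = "prediction_model")
  })
}

#' Reference architecture presets
#'
#' `"desk"` returns the default (64, 32) hidden widths; `"paper"` returns
#' the deep reference architecture whose hidden widths
#' (2048, 1024, 512, 256, 128, 64) multiply to 2^51 weights-scale capacity.
#'
#' @param name `"desk"` or `"paper"`.
#' @return Integer vector of hidden layer widths.
#' @export
mlp_preset <- function(name = c("desk", "paper")) {
  switch(match.arg(name),
         desk = c(64L, 32L),
         paper = c(2048L, 1024L, 512L, 256L, 128L, 64L))
}

relu <- function(a) pmax(a, 0)

# Numerically stable softmax over rows.
softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. With dropout = TRUE, inverted-dropout masks (scaled by
# 1/(1-p)) are applied after each hidden activation and cached for backprop.
mlp_forward <- function(model, x, dropout = FALSE) {
  n_layers <- length(model$weights)
  acts <- vector("list", n_layers + 1)  # acts[[1]] = input
  masks <- vector("list", n_layers)
  acts[[1]] <- x
  for (l in seq_len(n_layers - 1)) {
    z <- acts[[l]] %*% model$weights[[l]]
    z <- sweep(z, 2, model$biases[[l]], "+")
    a <- relu(z)
    if (dropout && model$dropout_rate > 0) {
      keep <- 1 - model$dropout_rate
      m <- matrix(stats::rbinom(length(a), 1, keep) / keep, nrow(a), ncol(a))
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l + 1]] <- a
  }
  z_out <- sweep(acts[[n_layers]] %*% model$weights[[n_layers]], 2,
                 model$biases[[n_layers]], "+")
  list(prob = softmax(z_out), acts = acts, masks = masks)
}

# Mean cross-entropy of one-hot targets y (class index vector, 1-based).
cross_entropy <- function(prob, y) {
  -mean(log(pmax(prob[cbind(seq_along(y), y)], 1e-12)))
}

#' Training configuration for the diagnosis network
#'
#' @param batch_size mini-batch size (default 32).
#' @param epochs maximum training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (default 10); the best-validation parameters are
#'   restored.
#' @param seed seed controlling batch shuffling and dropout masks.
#' @param feature_mode `"all_snps"` (input = every SNP column) or
#'   `"epistatic_snps"` (input = the detected SNP set in `feature_snps`).
#' @param feature_snps SNP column indices used when
#'   `feature_mode = "epistatic_snps"`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, epochs = 200L, learning_rate = 1e-3,
                            early_stop_patience = 10L, seed = 1L,
                            feature_mode = c("all_snps", "epistatic_snps"),
                            feature_snps = NULL) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0)
  if (feature_mode == "epistatic_snps" && is.null(feature_snps))
    stop("feature_mode 'epistatic_snps' requires feature_snps")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), feature_mode = feature_mode,
                 feature_snps = feature_snps),
            class = "training_config")
}

# Feature matrix for a dataset under a training config: genotype codes
# scaled to [0, 1] (divide by 2).
model_features <- function(ds, config) {
  cols <- if (config$feature_mode == "epistatic_snps")
    sort(unique(as.integer(config$feature_snps))) else seq_len(ncol(ds$genotypes))
  x <- ds$genotypes[, cols, drop = FALSE]
  storage.mode(x) <- "double"
  x / 2
}

#' Train the diagnosis network with mini-batch gradient descent
#'
#' Adam optimization of the softmax cross-entropy on the training split,
#' with dropout regularization, per-epoch monitoring of validation loss and
#' accuracy, early stopping after `early_stop_patience` epochs without
#' validation-loss improvement, and restoration of the best-validation
#' parameters. Deterministic under a fixed config seed.
#'
#' @param model a [build_model()] network whose `input_dim` matches the
#'   feature mode.
#' @param ds a `genotype_dataset` (binary or multi-class labels 0..K).
#' @param splits a [split_dataset()] result.
#' @param config a [training_config()].
#' @return The trained `prediction_model`, with a `history` data.frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc) and `best_epoch`
#'   attached.
#' @export
train_model <- function(model, ds, splits, config = training_config()) {
  stopifnot(inherits(model, "prediction_model"), inherits(ds, "genotype_dataset"))
  x_all <- model_features(ds, config)
  if (ncol(x_all) != model$input_dim)
    stop("feature width (", ncol(x_all), ") does not match model input_dim (",
         model$input_dim, ")")
  y_all <- as.integer(ds$labels) + 1L  # class index, 1-based
  if (max(y_all) > model$n_classes) stop("labels exceed the model's class count")
  if (length(unique(y_all[splits$train])) < model$n_classes)
    stop("a class is absent from the training split")

  x_tr <- x_all[splits$train, , drop = FALSE]; y_tr <- y_all[splits$train]
  x_va <- x_all[splits$validation, , drop = FALSE]; y_va <- y_all[splits$validation]
  n_tr <- nrow(x_tr)

  # Adam state
  mW <- lapply(model$weights, function(w) w * 0); vW <- mW
  mB <- lapply(model$biases, function(b) b * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  best <- list(loss = Inf, epoch = 0L, weights = model$weights, biases = model$biases)
  wait <- 0L
  n_layers <- length(model$weights)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_tr)
      starts <- seq(1, n_tr, by = config$batch_size)
      for (s in starts) {
        ix <- perm[s:min(s + config$batch_size - 1, n_tr)]
        xb <- x_tr[ix, , drop = FALSE]; yb <- y_tr[ix]
        fw <- mlp_forward(model, xb, dropout = TRUE)
        # backprop: softmax + cross-entropy gradient
        delta <- fw$prob
        delta[cbind(seq_along(yb), yb)] <- delta[cbind(seq_along(yb), yb)] - 1
        delta <- delta / length(yb)
        t_step <- t_step + 1
        for (l in n_layers:1) {
          gW <- crossprod(fw$acts[[l]], delta)
          gB <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(model$weights[[l]])
            if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
            delta <- delta * (fw$acts[[l]] > 0)
          }
          # Adam update
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
          vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
          mhW <- mW[[l]] / (1 - beta1^t_step); vhW <- vW[[l]] / (1 - beta2^t_step)
          mhB <- mB[[l]] / (1 - beta1^t_step); vhB <- vB[[l]] / (1 - beta2^t_step)
          model$weights[[l]] <- model$weights[[l]] -
            config$learning_rate * mhW / (sqrt(vhW) + eps)
          model$biases[[l]] <- model$biases[[l]] -
            config$learning_rate * mhB / (sqrt(vhB) + eps)
        }
      }
      p_tr <- mlp_forward(model, x_tr)$prob
      p_va <- mlp_forward(model, x_va)$prob
      row <- data.frame(epoch = epoch,
                        train_loss = cross_entropy(p_tr, y_tr),
                        train_acc = mean(max.col(p_tr, "first") == y_tr),
                        val_loss = cross_entropy(p_va, y_va),
                        val_acc = mean(max.col(p_va, "first") == y_va))
      history <- rbind(history, row)
      if (row$val_loss < best$loss - 1e-8) {
        best <- list(loss = row$val_loss, epoch = epoch,
                     weights = model$weights, biases = model$biases)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
  })

  model$weights <- best$weights
  model$biases <- best$biases
  model$feature_snps <- config$feature_snps
  model$feature_mode <- config$feature_mode
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Predict class labels for a feature matrix
#'
#' Argmax of the softmax class probabilities, dropout disabled; ties go to
#' the smaller class index. Features must already be on the model's input
#' scale (genotype codes / 2, as produced by training).
#'
#' @param model a trained `prediction_model`.
#' @param features numeric matrix, `input_dim` columns.
#' @return Integer label vector on the dataset's 0..K-1 label scale, with
#'   the class-probability matrix attached as attribute `"prob"`.
#' @export
predict_labels <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$input_dim)
    stop("feature width (", ncol(features), ") != model input_dim (",
         model$input_dim, ")")
  prob <- mlp_forward(model, features)$prob
  labels <- max.col(prob, ties.method = "first") - 1L
  attr(labels, "prob") <- prob
  labels
}

#' Evaluate predictions against true labels
#'
#' Accuracy `Acc = n/N` (correctly classified over total), per-class
#' accuracy and the confusion matrix. With `collapse_binary = TRUE` all
#' subtype labels >= 1 are mapped to 1 on both sides before scoring, so a
#' multi-class subtype model can be scored as a binary diagnostic.
#'
#' @param pred predicted labels (0..K).
#' @param truth true labels, same length.
#' @param collapse_binary score on the binary case/control scale.
#' @return An `evaluation_result`: list with `n_correct`, `n_total`,
#'   `accuracy`, `per_class_accuracy`, `confusion`.
#' @export
evaluate <- function(pred, truth, collapse_binary = FALSE) {
  if (length(pred) != length(truth)) stop("pred and truth length mismatch")
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (collapse_binary) { pred <- as.integer(pred >= 1L); truth <- as.integer(truth >= 1L) }
  classes <- 0:max(truth, pred)
  confusion <- table(factor(truth, classes), factor(pred, classes),
                     dnn = c("truth", "pred"))
  n_correct <- sum(diag(confusion))
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(n_correct = as.integer(n_correct), n_total = length(truth),
                 accuracy = n_correct / length(truth),
                 per_class_accuracy = as.numeric(per_class),
                 confusion = unclass(confusion)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Accuracy: %d/%d = %.4f\n", x$n_correct, x$n_total, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' Single-file self-describing JSON container: architecture, dropout rate,
#' feature mode and SNP set, and all weights/biases at full precision.
#'
#' @param model a `prediction_model`.
#' @param path file path.
#' @return `path` (save) or the restored `prediction_model` (load).
#' @export
save_model <- function(model, path) {
  payload <- list(
    input_dim = model$input_dim, hidden_widths = model$hidden_widths,
    n_classes = model$n_classes, dropout_rate = model$dropout_rate,
    feature_mode = model$feature_mode %||% "all_snps",
    feature_snps = model$feature_snps,
    weights = lapply(model$weights, function(w) list(dim = dim(w), x = as.numeric(w))),
    biases = model$biases)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_len(nrow_or_len(p$weights)), function(l) {
    w <- if (is.data.frame(p$weights)) p$weights[l, ] else p$weights[[l]]
    matrix(unlist(w$x), unlist(w$dim)[1], unlist(w$dim)[2])
  })
  biases <- if (is.list(p$biases)) lapply(p$biases, as.numeric) else list(as.numeric(p$biases))
  structure(list(input_dim = as.integer(p$input_dim),
                 hidden_widths = as.integer(p$hidden_widths),
                 n_classes = as.integer(p$n_classes),
                 dropout_rate = p$dropout_rate,
                 feature_mode = p$feature_mode,
                 feature_snps = if (length(p$feature_snps)) as.integer(p$feature_snps) else NULL,
                 weights = weights, biases = biases),
            class = "prediction_model")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("Feed-forward diagnosis network: %d -> %s -> %d (dropout %.2f)\n",
              x$input_dim, paste(x$hidden_widths, collapse = " -> "),
              x$n_classes, x$dropout_rate))
  if (!is.null(x$best_epoch))
    cat(sprintf("  trained; best validation epoch %d of %d recorded\n",
                x$best_epoch, nrow(x$history)))
  invisible(x)
}
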