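#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the three-stage analysis. Supply the input as
#' either a genotype file `input`, a built-in `preset` name, or an in-memory
#' `dataset`.
#'
#' @param input path to a tab-separated genotype file (see [read_gametes()]).
#' @param preset preset name (see [dataset_presets()]).
#' @param dataset an in-memory `genotype_dataset`.
#' @param preset_args list of extra arguments to [simulate_preset()]
#'   (e.g. `heritability`, `f_low`, `f_high`).
#' @param order epistasis interaction order for the detection scan.
#' @param alpha,correction chi-square filter controls
#'   (see [significance_filter()]).
#' @param run_clustering run the subtype-discovery stage (`FALSE` = binary
#'   diagnosis; `TRUE` = multi-class subtype diagnosis).
#' @param K cluster count when `run_clustering` (default 2).
#' @param feature_mode classifier input features: `"all_snps"` or
#'   `"epistatic_snps"` (the detected SNP set).
#' @param hidden_widths,dropout_rate network architecture
#'   (see [build_model()]).
#' @param batch_size,epochs,learning_rate,early_stop_patience training
#'   controls (see [training_config()]).
#' @param test_fraction,validation_fraction split protocol (defaults: 10%
#'   test, then 10% of the remainder as validation).
#' @param output_dir optional directory for stage artifacts (candidate
#'   report, assignment table, training history, JSON report).
#' @param seed single global seed; every stage derives its own sub-seed
#'   from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = NULL, dataset = NULL,
                            preset_args = list(),
                            order = 2L, alpha = 0.05,
                            correction = c("bonferroni", "none"),
                            run_clustering = FALSE, K = 2L,
                            feature_mode = c("all_snps", "epistatic_snps"),
                            hidden_widths = mlp_preset("desk"),
                            dropout_rate = 0.5,
                            batch_size = 32L, epochs = 200L,
                            learning_rate = 1e-3, early_stop_patience = 10L,
                            test_fraction = 0.1, validation_fraction = 0.1,
                            output_dir = NULL, seed = 1L) {
  if (is.null(input) + is.null(preset) + is.null(dataset) != 2)
    stop("supply exactly one of `input`, `preset`, `dataset`")
  stopifnot(order >= 2, !run_clustering || K >= 2)
  structure(list(input = input, preset = preset, dataset = dataset,
                 preset_args = preset_args, order = as.integer(order),
                 alpha = alpha, correction = match.arg(correction),
                 run_clustering = isTRUE(run_clustering), K = as.integer(K),
                 feature_mode = match.arg(feature_mode),
                 hidden_widths = as.integer(hidden_widths),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML whose keys are [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the three-stage pipeline end to end
#'
#' Executes: held-out split; exhaustive epistasis detection (Pareto front
#' over MI/K2 plus chi-square filter) on the training+validation samples;
#' optional K-means subtype discovery and case relabelling; network training
#' with early stopping; final evaluation on the untouched test split.
#'
#' Test samples are never visible to detection or clustering; when subtypes
#' are used, held-out cases receive their subtype label by nearest-centroid
#' assignment at evaluation time. If the chi-square filter removes every
#' front member, the pipeline warns and proceeds with the unfiltered front.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report`: list with `detection` (summary + candidate
#'   table), `clustering` (summary or `NULL`), `evaluation` (test-split
#'   [evaluate()] result; plus `evaluation_binary` when multi-class),
#'   `history`, `feature_snps`, `splits`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[stage] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  # ---- input ----
  ds <- if (!is.null(config$dataset)) config$dataset
  else if (!is.null(config$preset))
    do.call(simulate_preset, c(list(name = config$preset, seed = config$seed),
                               config$preset_args))
  else read_gametes(config$input)
  binary_labels <- if (!is.null(ds$binary_labels)) ds$binary_labels
  else as.integer(ds$labels >= 1L)
  ds_bin <- genotype_dataset(ds$genotypes, binary_labels, ds$snp_names,
                             truth = ds$truth)
  tick("input")

  # ---- split first: test samples stay unseen until final evaluation ----
  splits <- split_dataset(ds_bin, config$test_fraction,
                          config$validation_fraction,
                          seed = derive_seed(config$seed, "split"))
  dev_idx <- sort(c(splits$train, splits$validation))
  ds_dev <- genotype_dataset(ds_bin$genotypes[dev_idx, , drop = FALSE],
                             ds_bin$labels[dev_idx], ds_bin$snp_names)
  tick("split")

  # ---- stage 1: detection ----
  candidates <- enumerate_and_score(ds_dev, config$order)
  front <- pareto_front(candidates)
  det <- significance_filter(front, config$alpha, config$correction)
  detected <- det$significant
  empty_front_fallback <- NROW(detected) == 0
  if (empty_front_fallback) {
    warning("chi-square filter removed every front member; proceeding with the unfiltered Pareto front")
    detected <- front$candidates
  }
  feature_snps <- candidate_snp_union(detected)
  tick("detect")

  # ---- stage 2 (optional): subtype discovery on non-test cases ----
  clustering <- NULL
  labels_final <- ds_bin$labels
  if (config$run_clustering) {
    assignment <- cluster_cases(ds_dev, feature_snps, config$K,
                                seed = derive_seed(config$seed, "cluster"))
    ds_dev_mc <- relabel_cases(ds_dev, assignment)
    labels_final <- integer(length(ds_bin$labels))
    labels_final[dev_idx] <- ds_dev_mc$labels
    test_cases <- splits$test[ds_bin$labels[splits$test] >= 1L]
    if (length(test_cases))
      labels_final[test_cases] <-
        predict(assignment, ds_bin$genotypes[test_cases, , drop = FALSE])
    # report cluster membership in original sample coordinates
    assignment$case_indices <- dev_idx[assignment$case_indices]
    clustering <- assignment
  }
  ds_final <- genotype_dataset(ds_bin$genotypes, labels_final, ds_bin$snp_names,
                               truth = ds$truth, binary_labels = binary_labels)
  tick("cluster")

  # ---- stage 3: training + evaluation ----
  n_classes <- max(ds_final$labels) + 1L
  input_dim <- if (config$feature_mode == "epistatic_snps") length(feature_snps)
  else ncol(ds_final$genotypes)
  model <- build_model(input_dim, config$hidden_widths, n_classes,
                       config$dropout_rate,
                       seed = derive_seed(config$seed, "init"))
  tc <- training_config(config$batch_size, config$epochs, config$learning_rate,
                        config$early_stop_patience,
                        seed = derive_seed(config$seed, "train"),
                        feature_mode = config$feature_mode,
                        feature_snps = if (config$feature_mode == "epistatic_snps")
                          feature_snps else NULL)
  model <- train_model(model, ds_final, splits, tc)
  tick("train")

  x_test <- model_features(ds_final, tc)[splits$test, , drop = FALSE]
  pred <- predict_labels(model, x_test)
  truth <- ds_final$labels[splits$test]
  evaluation <- evaluate(pred, truth)
  evaluation_binary <- if (n_classes > 2L) evaluate(pred, truth, collapse_binary = TRUE)
  tick("evaluate")

  report <- structure(list(
    detection = list(n_evaluated = front$n_evaluated,
                     n_front = NROW(front$candidates),
                     n_significant = NROW(det$significant),
                     threshold = det$threshold,
                     empty_front_fallback = empty_front_fallback,
                     detected = detected),
    clustering = clustering,
    evaluation = evaluation,
    evaluation_binary = evaluation_binary,
    history = model$history,
    model = model,
    feature_snps = feature_snps,
    splits = splits,
    provenance = list(config = config, seed = config$seed,
                      detection_samples = dev_idx,
                      package_version = as.character(utils::packageVersion("epiheter")),
                      timestamp = format(Sys.time(), tz = "UTC"),
                      timings = timings)),
    class = "pipeline_report")

  if (!is.null(config$output_dir)) write_pipeline_artifacts(report, candidates, det, config)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Three-stage pipeline report\n")
  cat(sprintf("  detection: %d combinations -> %d on front -> %d significant%s\n",
              x$detection$n_evaluated, x$detection$n_front,
              x$detection$n_significant,
              if (x$detection$empty_front_fallback) " (fallback: unfiltered front)" else ""))
  cat("  epistatic SNPs:", paste(x$feature_snps, collapse = ", "), "\n")
  if (!is.null(x$clustering))
    cat(sprintf("  clustering: K = %d, inertia %.2f\n",
                x$clustering$K, x$clustering$inertia))
  cat(sprintf("  test accuracy: %.4f (%d/%d)\n", x$evaluation$accuracy,
              x$evaluation$n_correct, x$evaluation$n_total))
  if (!is.null(x$evaluation_binary))
    cat(sprintf("  test accuracy (collapsed to case/control): %.4f\n",
                x$evaluation_binary$accuracy))
  invisible(x)
}

# Stage artifacts under config$output_dir: candidate report, assignment
# table, training history, machine-readable JSON report.
write_pipeline_artifacts <- function(report, candidates, det, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  write_candidate_report(candidates, det, p("candidates.tsv"))
  if (!is.null(report$clustering)) {
    a <- report$clustering
    data.table::fwrite(data.table::data.table(
      sample_index = a$case_indices, cluster = a$cluster_of,
      canonical_label = a$canonical[a$cluster_of]),
      p("assignment.tsv"), sep = "\t")
  }
  data.table::fwrite(report$history, p("history.csv"))
  json <- list(
    seed = report$provenance$seed,
    detection = report$detection[c("n_evaluated", "n_front", "n_significant",
                                   "threshold", "empty_front_fallback")],
    detected_snps = report$feature_snps,
    clustering = if (!is.null(report$clustering))
      list(K = report$clustering$K, inertia = report$clustering$inertia,
           sizes = as.integer(tabulate(report$clustering$cluster_of,
                                       report$clustering$K))),
    evaluation = list(accuracy = report$evaluation$accuracy,
                      n_correct = report$evaluation$n_correct,
                      n_total = report$evaluation$n_total),
    evaluation_binary = if (!is.null(report$evaluation_binary))
      list(accuracy = report$evaluation_binary$accuracy),
    provenance = report$provenance[c("package_version", "timestamp", "timings")])
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(NULL)
}
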