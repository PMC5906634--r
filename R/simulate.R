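#' Construct a case-control genotype dataset
#'
#' Container for an n_samples x n_snps matrix of minor-allele-count genotype
#' codes (0/1/2) with class labels: 0 = control and 1 = case in binary mode,
#' or 0 = control and 1..K = disease subtype in multi-class mode. Simulated
#' datasets additionally carry a `truth` record with the generating disease
#' model(s) and, for heterogeneous data, each case's source model.
#'
#' @param genotypes integer matrix with entries in {0,1,2}.
#' @param labels integer vector, one label per row of `genotypes`.
#' @param snp_names optional column identifiers (default `SNP1..SNPm`).
#' @param truth optional list recording generating models / subtypes.
#' @param binary_labels optional original 0/1 labels kept alongside a
#'   multi-class relabelling.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, labels, snp_names = NULL, truth = NULL,
                             binary_labels = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) > 0 && !all(genotypes %in% c(0L, 1L, 2L)))
    stop("genotype codes must be 0, 1 or 2")
  labels <- as.integer(labels)
  if (length(labels) != nrow(genotypes))
    stop("labels length (", length(labels), ") != number of samples (",
         nrow(genotypes), ")")
  if (any(labels < 0)) stop("labels must be non-negative integers")
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  if (length(snp_names) != ncol(genotypes)) stop("snp_names length mismatch")
  colnames(genotypes) <- snp_names
  structure(list(genotypes = genotypes, labels = labels,
                 snp_names = as.character(snp_names), truth = truth,
                 binary_labels = binary_labels),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  k <- max(x$labels)
  mode <- if (k <= 1) "binary" else sprintf("multi-class (%d subtypes)", k)
  cat(sprintf("Genotype dataset: %d samples x %d SNPs, %s\n",
              nrow(x$genotypes), ncol(x$genotypes), mode))
  cat("  labels: ", paste(sprintf("%d x %d", sort(unique(x$labels)),
                                  tabulate(x$labels + 1L)[sort(unique(x$labels)) + 1L]),
                          collapse = ", "), "\n", sep = "")
  if (!is.null(x$truth))
    cat("  truth: simulated; pathogenic SNPs ",
        paste(vapply(x$truth$models, function(m)
          paste0("(", paste(m$snp_indices, collapse = ","), ")"), ""),
          collapse = " "), "\n", sep = "")
  invisible(x)
}

# Draw `n` genotype combinations (cell indices 0..3^k-1) under HWE at `mafs`.
draw_cells <- function(n, mafs) {
  idx <- integer(n)
  for (p in mafs) idx <- idx * 3L + stats::rbinom(n, 2L, p)
  idx
}

# Decode cell indices back to an n x k genotype matrix (first locus = most
# significant base-3 digit).
decode_cells <- function(idx, order) {
  g <- matrix(0L, length(idx), order)
  for (d in order:1) {
    g[, d] <- idx %% 3L
    idx <- idx %/% 3L
  }
  g
}

# Rejection-sample `n` pathogenic genotype combinations of the given class:
# draw g ~ HWE(mafs), accept as case with probability probs[g] (control with
# 1 - probs[g]). Returns cell indices.
sample_class_cells <- function(n, pt, is_case) {
  acc_prob <- if (is_case) pt$prevalence else 1 - pt$prevalence
  if (n > 0 && acc_prob <= 0)
    stop("penetrance model makes the requested ",
         if (is_case) "case" else "control", " quota unfillable")
  out <- integer(0)
  guard <- 0L
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / max(acc_prob, 0.01)) + 32L
    g <- draw_cells(m, pt$mafs)
    p_case <- pt$probs[g + 1L]
    keep <- stats::runif(m) < (if (is_case) p_case else 1 - p_case)
    out <- c(out, g[keep])
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to fill the quota")
  }
  out[seq_len(n)]
}

#' Simulate a pure epistatic case-control dataset
#'
#' Generates a dataset driven by a single k-SNP penetrance model. The
#' pathogenic SNP genotypes are drawn under HWE at the model MAFs; case or
#' control status is assigned by rejection sampling against the penetrance
#' table until each class quota (`case_fraction`, default balanced) is
#' filled, so realized class counts are exact. All other ("noise") SNPs get
#' MAFs drawn uniformly from \[0.05, 0.5\] and HWE genotypes.
#'
#' @param n_samples total sample count.
#' @param n_snps total SNP count (pathogenic + noise).
#' @param model a [disease_model()].
#' @param case_fraction proportion of cases in (0, 1\] (1 allowed: all cases).
#' @param seed integer seed; fixed seed gives identical datasets.
#' @param noise_mafs optional length-`n_snps` vector of column MAFs to use
#'   for non-pathogenic columns (entries at pathogenic positions ignored);
#'   drawn uniformly when `NULL`.
#' @return A `genotype_dataset` with `truth$models` and per-case
#'   `truth$subtype` (all 1 for a pure dataset; `NA` for controls).
#' @export
simulate_pure <- function(n_samples, n_snps, model, case_fraction = 0.5,
                          seed = 1L, noise_mafs = NULL) {
  stopifnot(inherits(model, "disease_model"),
            case_fraction > 0, case_fraction <= 1)
  pt <- model$penetrance
  if (n_snps < pt$order) stop("n_snps must be at least the model order")
  if (max(model$snp_indices) > n_snps) stop("pathogenic SNP index out of range")
  n_cases <- round(n_samples * case_fraction)
  n_controls <- n_samples - n_cases
  with_seed(seed, {
    if (is.null(noise_mafs)) noise_mafs <- stats::runif(n_snps, 0.05, 0.5)
    geno <- matrix(0L, n_samples, n_snps)
    noise_cols <- setdiff(seq_len(n_snps), model$snp_indices)
    for (j in noise_cols) geno[, j] <- stats::rbinom(n_samples, 2L, noise_mafs[j])
    cells <- c(sample_class_cells(n_cases, pt, TRUE),
               sample_class_cells(n_controls, pt, FALSE))
    geno[, model$snp_indices] <- decode_cells(cells, pt$order)
    labels <- rep(c(1L, 0L), c(n_cases, n_controls))
    perm <- sample.int(n_samples)
    genotype_dataset(geno[perm, , drop = FALSE], labels[perm],
                     truth = list(models = list(model),
                                  subtype = ifelse(labels[perm] == 1L, 1L, NA_integer_),
                                  noise_mafs = noise_mafs))
  })
}

#' Simulate a heterogeneous epistatic case-control dataset
#'
#' Emulates genetic heterogeneity: two disease models H1 and H2, each with
#' its own disjoint set of pathogenic SNPs, generate balanced sub-datasets
#' of `proportion_h1 * n_samples` and the remainder, sharing the same noise
#' SNP columns. The sub-datasets are concatenated and shuffled. Labels are
#' binary (case/control); each case's source model is recorded as
#' `truth$subtype` (1 or 2).
#'
#' Each model's pathogenic columns are, in the other model's sub-dataset,
#' plain HWE noise at that model's MAFs, so every pathogenic SNP keeps its
#' specified population MAF across the full dataset.
#'
#' @param n_samples,n_snps as in [simulate_pure()].
#' @param model_h1,model_h2 [disease_model()] objects with disjoint
#'   `snp_indices`.
#' @param proportion_h1 proportion of samples generated under H1, in (0, 1).
#' @param seed integer seed.
#' @return A `genotype_dataset`.
#' @export
simulate_heterogeneous <- function(n_samples, n_snps, model_h1, model_h2,
                                   proportion_h1 = 0.5, seed = 1L) {
  stopifnot(inherits(model_h1, "disease_model"), inherits(model_h2, "disease_model"))
  if (proportion_h1 <= 0 || proportion_h1 >= 1)
    stop("proportion_h1 must lie strictly in (0, 1); use simulate_pure() for a single model")
  if (length(intersect(model_h1$snp_indices, model_h2$snp_indices)) > 0)
    stop("pathogenic SNP sets of H1 and H2 must be disjoint")
  n1 <- round(n_samples * proportion_h1)
  n2 <- n_samples - n1
  if (n1 < 2 || n2 < 2) stop("n_samples too small to honor both proportions")
  with_seed(seed, {
    noise_mafs <- stats::runif(n_snps, 0.05, 0.5)
    noise_mafs[model_h1$snp_indices] <- model_h1$penetrance$mafs
    noise_mafs[model_h2$snp_indices] <- model_h2$penetrance$mafs
    s1 <- derive_seed(seed, "hete-sub1"); s2 <- derive_seed(seed, "hete-sub2")
    d1 <- simulate_pure(n1, n_snps, model_h1, 0.5, s1, noise_mafs)
    d2 <- simulate_pure(n2, n_snps, model_h2, 0.5, s2, noise_mafs)
    geno <- rbind(d1$genotypes, d2$genotypes)
    labels <- c(d1$labels, d2$labels)
    subtype <- c(ifelse(d1$labels == 1L, 1L, NA_integer_),
                 ifelse(d2$labels == 1L, 2L, NA_integer_))
    perm <- sample.int(n1 + n2)
    genotype_dataset(geno[perm, , drop = FALSE], labels[perm],
                     truth = list(models = list(model_h1, model_h2),
                                  subtype = subtype[perm],
                                  noise_mafs = noise_mafs))
  })
}

#' Split a dataset into train / validation / test index sets
#'
#' The held-out test set is drawn first (default 10% of all samples); the
#' validation set is then 10% of the remainder, the rest is training. Splits
#' are stratified by class label by default so class ratios are preserved in
#' every part.
#'
#' @param ds a `genotype_dataset`.
#' @param test_fraction,validation_fraction proportions in (0, 1).
#' @param seed integer seed; same seed, same split.
#' @param stratified stratify draws by label (default `TRUE`).
#' @return An object of class `split_indices`: list with integer index
#'   vectors `train`, `validation`, `test` (disjoint, covering all samples).
#' @export
split_dataset <- function(ds, test_fraction = 0.1, validation_fraction = 0.1,
                          seed = 1L, stratified = TRUE) {
  stopifnot(inherits(ds, "genotype_dataset"),
            test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  n <- length(ds$labels)
  draw <- function(pool, labels, frac) {
    if (stratified) {
      unlist(lapply(split(pool, labels[pool]), function(ix) {
        m <- round(length(ix) * frac)
        if (m == 0 || m == length(ix)) stop("a class stratum is too small to split")
        sample(ix, m)
      }), use.names = FALSE)
    } else {
      m <- round(length(pool) * frac)
      if (m == 0 || m == length(pool)) stop("dataset too small to split")
      sample(pool, m)
    }
  }
  with_seed(seed, {
    test <- sort(draw(seq_len(n), ds$labels, test_fraction))
    rest <- setdiff(seq_len(n), test)
    validation <- sort(draw(rest, ds$labels, validation_fraction))
    train <- setdiff(rest, validation)
    structure(list(train = train, validation = validation, test = test),
              class = "split_indices")
  })
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("Split: %d train / %d validation / %d test\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}
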