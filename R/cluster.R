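#' Cluster case samples on epistatic SNPs into disease subtypes
#'
#' Stage-2 subtype discovery: Lloyd's K-means on the case rows only,
#' restricted to the epistatic SNP columns, using raw 0/1/2 genotype codes
#' and Euclidean distance. k-means++ initialization with `n_restarts`
#' seeded restarts (best inertia kept), at most `max_iter` iterations,
#' convergence when the total squared centroid movement drops below `tol`.
#' An emptied cluster is re-seeded at the point farthest from its centroid.
#'
#' The number of clusters K is a modelling input: in practice it comes from
#' prior clinical knowledge of the disease's subtypes; for simulated data
#' it is naturally the number of generating disease models.
#'
#' @param ds a `genotype_dataset` (binary labels; only label-1..K rows,
#'   i.e. cases, are clustered).
#' @param epistatic_snps SNP column indices to use as features.
#' @param K number of clusters (>= 2).
#' @param seed integer seed.
#' @param n_restarts,max_iter,tol algorithm controls.
#' @return A `subtype_assignment`: list with `case_indices` (row indices of
#'   the clustered cases), `cluster_of` (raw cluster id 1..K per case),
#'   `centroids` (K x length(epistatic_snps)), `K`, `inertia`,
#'   `inertia_trace` (per-iteration inertia of the winning restart),
#'   `canonical` (map raw id -> canonical label 1..K, decreasing cluster
#'   size, ties to the cluster containing the smallest sample index), and
#'   `snps`.
#' @export
cluster_cases <- function(ds, epistatic_snps, K = 2L, seed = 1L,
                          n_restarts = 10L, max_iter = 300L, tol = 1e-4) {
  stopifnot(inherits(ds, "genotype_dataset"), K >= 2)
  epistatic_snps <- sort(unique(as.integer(epistatic_snps)))
  if (length(epistatic_snps) == 0) stop("epistatic_snps must be non-empty")
  if (max(epistatic_snps) > ncol(ds$genotypes)) stop("SNP index out of range")
  case_indices <- which(ds$labels >= 1L)
  if (length(case_indices) < K) stop("K exceeds the number of case samples")
  x <- ds$genotypes[case_indices, epistatic_snps, drop = FALSE]
  storage.mode(x) <- "double"

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_kmeans(x, K, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })

  sizes <- tabulate(best$cluster, K)
  # canonical label: decreasing size; ties broken by the cluster holding the
  # smallest original sample index
  first_member <- vapply(seq_len(K), function(k) {
    ix <- case_indices[best$cluster == k]
    if (length(ix)) min(ix) else Inf
  }, numeric(1))
  canon_order <- order(-sizes, first_member)
  canonical <- integer(K)
  canonical[canon_order] <- seq_len(K)

  structure(list(case_indices = case_indices, cluster_of = best$cluster,
                 centroids = best$centers, K = as.integer(K),
                 inertia = best$inertia, inertia_trace = best$trace,
                 canonical = canonical, snps = epistatic_snps),
            class = "subtype_assignment")
}

# Plain Lloyd iterations with k-means++ seeding; x is numeric n x d.
lloyd_kmeans <- function(x, K, max_iter, tol) {
  n <- nrow(x)
  centers <- x[kmeanspp_init(x, K), , drop = FALSE]
  trace <- numeric(0)
  cl <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- point_center_dist2(x, centers)
    cl <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(n), cl)])
    trace <- c(trace, inertia)
    new_centers <- centers
    for (k in seq_len(K)) {
      members <- cl == k
      if (any(members)) {
        new_centers[k, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # empty-cluster repair: re-seed at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), cl)])
        new_centers[k, ] <- x[far, ]
        cl[far] <- k
      }
    }
    move <- sum((new_centers - centers)^2)
    centers <- new_centers
    if (move < tol) break
  }
  d2 <- point_center_dist2(x, centers)
  cl <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), cl)])
  list(cluster = cl, centers = centers, inertia = inertia,
       trace = c(trace, inertia))
}

# Squared Euclidean distances, n x K.
point_center_dist2 <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (k in seq_len(K - 1)) {
    if (all(d2 <= 0)) centers[k + 1] <- sample.int(n, 1)
    else centers[k + 1] <- sample.int(n, 1, prob = d2)
    dk <- rowSums((x - matrix(x[centers[k + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dk)
  }
  centers
}

#' Predict subtype labels for new samples by nearest centroid
#'
#' Assigns each row of `newdata` (full genotype matrix or already-restricted
#' feature matrix) to the nearest cluster centroid, returning canonical
#' subtype labels 1..K.
#'
#' @param object a `subtype_assignment`.
#' @param newdata genotype matrix; if it has more columns than the
#'   assignment's feature set it is subset to `object$snps`.
#' @param ... unused.
#' @return Integer vector of canonical subtype labels.
#' @export
predict.subtype_assignment <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$snps)) x <- x[, object$snps, drop = FALSE]
  storage.mode(x) <- "double"
  d2 <- point_center_dist2(x, object$centroids)
  object$canonical[max.col(-d2, ties.method = "first")]
}

#' @export
print.subtype_assignment <- function(x, ...) {
  sizes <- tabulate(x$cluster_of, x$K)
  cat(sprintf("Subtype assignment: %d cases -> K = %d clusters (sizes %s), inertia %.2f\n",
              length(x$case_indices), x$K, paste(sizes, collapse = "/"), x$inertia))
  invisible(x)
}

#' Relabel case samples by their cluster
#'
#' Converts a binary dataset plus a subtype assignment into the multi-class
#' dataset used for subtype diagnosis: controls keep label 0, cases get
#' canonical labels 1..K (decreasing cluster size, ties to the cluster with
#' the smallest member sample index). The original binary labels are kept
#' in `binary_labels`.
#'
#' @param ds binary `genotype_dataset`.
#' @param assignment a [cluster_cases()] result covering exactly the case
#'   samples of `ds`.
#' @return A multi-class `genotype_dataset`.
#' @export
relabel_cases <- function(ds, assignment) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(assignment, "subtype_assignment"))
  cases <- which(ds$labels >= 1L)
  if (!identical(cases, assignment$case_indices))
    stop("assignment does not cover exactly the case samples of the dataset")
  labels <- integer(length(ds$labels))
  labels[assignment$case_indices] <- assignment$canonical[assignment$cluster_of]
  genotype_dataset(ds$genotypes, labels, ds$snp_names, truth = ds$truth,
                   binary_labels = as.integer(ds$labels >= 1L))
}

#' Adjusted Rand index between a subtype assignment and ground truth
#'
#' Chance-corrected agreement between the clustering partition and a
#' reference partition (e.g. the simulator's per-case source model). 1 means
#' identical partitions up to relabeling; 0 is the chance level.
#'
#' @param assignment a `subtype_assignment`, or an integer vector of cluster
#'   labels.
#' @param truth_subtypes reference labels, one per assigned case.
#' @return The adjusted Rand index in \[-1, 1\].
#' @export
clustering_agreement <- function(assignment, truth_subtypes) {
  a <- if (inherits(assignment, "subtype_assignment")) assignment$cluster_of else assignment
  if (length(a) != length(truth_subtypes))
    stop("assignment and truth must have the same length")
  tab <- table(a, truth_subtypes)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n_pairs <- comb2(sum(tab))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # degenerate partitions
  (sum_ij - expected) / (max_index - expected)
}
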