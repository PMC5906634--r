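#' Scoring configuration for epistasis statistics
#'
#' @param dirichlet_alpha Dirichlet pseudo-count of the K2 score's prior
#'   (default 1, the uninformative prior used when nothing is known about
#'   pathogenesis).
#' @param log_base_mi logarithm base for entropies (default 2: bits).
#' @param min_cell_for_chi2 expected-count floor below which a chi-square
#'   result should be treated with caution (default 0 = no floor; the
#'   statistic is used for ranking/filtering, not inference on sparse cells).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(dirichlet_alpha = 1, log_base_mi = 2,
                           min_cell_for_chi2 = 0) {
  stopifnot(dirichlet_alpha >= 0, log_base_mi > 1)
  structure(list(dirichlet_alpha = dirichlet_alpha, log_base_mi = log_base_mi,
                 min_cell_for_chi2 = min_cell_for_chi2),
            class = "scoring_config")
}

#' Map a genotype combination to its cell index
#'
#' Bijective base-3 encoding of a k-locus genotype combination (codes 0/1/2)
#' to an integer in `[0, 3^k)`. The first SNP is the most significant digit.
#' Accepts a vector (one combination) or an n x k matrix (one per row).
#'
#' @param genotype_codes vector or matrix of codes in {0,1,2}.
#' @return Integer index (or vector of indices) in `[0, 3^k)`.
#' @examples
#' genotype_combination_index(c(0, 0))    # 0
#' genotype_combination_index(c(2, 2, 2)) # 26
#' @export
genotype_combination_index <- function(genotype_codes) {
  g <- if (is.matrix(genotype_codes)) genotype_codes else matrix(genotype_codes, nrow = 1)
  if (!all(g %in% c(0L, 1L, 2L))) stop("genotype codes must be 0, 1 or 2")
  idx <- integer(nrow(g))
  for (j in seq_len(ncol(g))) idx <- idx * 3L + as.integer(g[, j])
  if (is.matrix(genotype_codes)) idx else idx[1]
}

# Shared count layout for all three scores: a (3^k) x 2 contingency of
# genotype-combination cells (rows) by class (columns: control, case).
cell_counts <- function(genotypes, labels) {
  g <- as.matrix(genotypes)
  if (nrow(g) != length(labels)) stop("genotypes and labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n_cells <- 3L^ncol(g)
  idx <- genotype_combination_index(g)
  cnt <- tabulate(idx + n_cells * as.integer(labels) + 1L, 2L * n_cells)
  matrix(cnt, n_cells, 2L)  # [, 1] controls, [, 2] cases
}

# Scores computed straight from a (cells x 2) count matrix; used by the
# exhaustive scan where counts are formed in-line for speed.
mi_from_counts <- function(counts, base = 2) {
  n <- sum(counts)
  ent <- function(v) { p <- v[v > 0] / n; -sum(p * log(p)) }
  (ent(colSums(counts)) + ent(rowSums(counts)) - ent(counts)) / log(base)
}

k2_from_counts <- function(counts, alpha = 1) {
  if (alpha <= 0) stop("the K2 Dirichlet pseudo-count must be positive")
  r1 <- counts[, 1]; r2 <- counts[, 2]; ri <- r1 + r2
  # alpha = 1 gives the classical K2 form sum_i [log((r_i+1)!) - log(r_i1!) - log(r_i2!)]
  sum(lgamma(ri + 2 * alpha) - lgamma(2 * alpha)
      - (lgamma(r1 + alpha) + lgamma(r2 + alpha) - 2 * lgamma(alpha)))
}

chi2_from_counts <- function(counts) {
  keep <- rowSums(counts) > 0
  o <- counts[keep, , drop = FALSE]
  n <- sum(o)
  col_m <- colSums(o); row_m <- rowSums(o)
  if (any(col_m == 0)) stop("chi-square test needs both classes present")
  if (nrow(o) < 2) stop("chi-square test needs at least two non-empty genotype cells")
  e <- outer(row_m, col_m) / n
  chi2 <- sum((o - e)^2 / e)
  df <- (nrow(o) - 1L) * (ncol(o) - 1L)
  list(chi2 = chi2, df = df,
       pvalue = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = o, expected = e)
}

#' Mutual information between a SNP combination and case-control status
#'
#' Plug-in (maximum-likelihood) mutual information
#' \eqn{I(Y; X_1..X_k) = H(Y) + H(X_1..X_k) - H(Y, X_1..X_k)} from the
#' empirical genotype-combination x class frequencies, with the convention
#' \eqn{0 \log 0 = 0}. Larger values mean the combination reduces more
#' uncertainty about the sample state.
#'
#' @param genotypes n x k matrix of genotype codes (or a vector for k = 1).
#' @param labels binary 0/1 class vector of length n.
#' @param config a [scoring_config()].
#' @return Mutual information in bits (or the configured base).
#' @export
mutual_information <- function(genotypes, labels, config = scoring_config()) {
  if (!is.matrix(genotypes)) genotypes <- cbind(genotypes)
  mi_from_counts(cell_counts(genotypes, labels), base = config$log_base_mi)
}

#' K2 Bayesian score of a SNP combination
#'
#' Negative log marginal likelihood of the class labels given the genotype
#' cells under a Dirichlet(1,1) prior per cell:
#' \deqn{K2 = \sum_i [\log((r_i + 1)!) - \log(r_{i1}!) - \log(r_{i2}!)]}
#' where \eqn{r_i} counts samples in genotype cell i and \eqn{r_{ij}} those
#' of class j. Evaluated with log-gamma for overflow safety; empty cells
#' contribute 0. Lower scores indicate stronger association.
#'
#' @inheritParams mutual_information
#' @return The K2 score (natural-log scale).
#' @export
k2_score <- function(genotypes, labels, config = scoring_config()) {
  if (!is.matrix(genotypes)) genotypes <- cbind(genotypes)
  k2_from_counts(cell_counts(genotypes, labels), alpha = config$dirichlet_alpha)
}

#' Chi-square test of a SNP combination against case-control status
#'
#' Test of independence on the 3^k x 2 genotype-combination by class table,
#' with expected counts from the row/column margins. Genotype cells with a
#' zero margin are dropped; degrees of freedom are
#' (retained cells - 1) x (2 - 1).
#'
#' @inheritParams mutual_information
#' @return A list of class `chi_square_result`: `chi2`, `df`, `pvalue`, and
#'   `table` (a list with `observed`, `expected`, `s` retained cells, `m`
#'   total observations).
#' @export
chi_square_test <- function(genotypes, labels, config = scoring_config()) {
  if (!is.matrix(genotypes)) genotypes <- cbind(genotypes)
  res <- chi2_from_counts(cell_counts(genotypes, labels))
  structure(list(chi2 = res$chi2, df = res$df, pvalue = res$pvalue,
                 table = list(observed = res$observed, expected = res$expected,
                              s = nrow(res$observed), m = sum(res$observed))),
            class = "chi_square_result")
}
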