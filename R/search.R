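#' Exhaustively score all k-order SNP combinations
#'
#' Stage-1 scan: every unordered combination of `order` SNP columns is
#' scored against the binary class labels with mutual information, the K2
#' score and the chi-square test. Enumeration is lexicographic and
#' deterministic. The combination count C(n_snps, order) is guarded by
#' `max_combinations`.
#'
#' @param ds a `genotype_dataset` with binary labels.
#' @param order interaction order (>= 2).
#' @param config a [scoring_config()].
#' @param max_combinations guard cap on C(n_snps, order) (default 1e6).
#' @return A data.frame of class `epistasis_candidates`, one row per
#'   combination: SNP index columns `snp1..snpk`, `snps` (comma-joined
#'   names), `mi`, `k2`, `chi2`, `df`, `pvalue`. Attribute `n_evaluated`
#'   records the number of combinations scored.
#' @export
enumerate_and_score <- function(ds, order = 2L, config = scoring_config(),
                                max_combinations = 1e6) {
  stopifnot(inherits(ds, "genotype_dataset"), order >= 2)
  order <- as.integer(order)
  m <- ncol(ds$genotypes)
  if (m < order) stop("dataset has fewer SNPs than the requested order")
  n_comb <- choose(m, order)
  if (n_comb > max_combinations)
    stop(sprintf(paste("C(%d, %d) = %.0f combinations exceeds the cap of %.0f;",
                       "reduce the order or pre-filter SNPs"),
                 m, order, n_comb, max_combinations))
  if (!all(ds$labels %in% c(0L, 1L)))
    stop("detection requires binary 0/1 labels")

  combs <- utils::combn(m, order)            # order x n_comb, lexicographic
  n_comb <- ncol(combs)
  labels <- as.integer(ds$labels)
  n_cells <- 3L^order
  off <- n_cells * labels + 1L
  base <- config$log_base_mi
  alpha <- config$dirichlet_alpha
  g <- ds$genotypes

  # class margins are constant across combinations
  n <- length(labels)
  n_case <- sum(labels); n_ctrl <- n - n_case
  if (n_case == 0L || n_ctrl == 0L) stop("both classes must be present")
  py <- c(n_ctrl, n_case) / n
  h_y <- -sum(py * log(py))

  mi <- k2 <- chi2 <- numeric(n_comb)
  df <- integer(n_comb)
  i_seq <- seq_len(n_cells); i_cases <- (n_cells + 1L):(2L * n_cells)
  log_base <- log(base); lg2a <- lgamma(2 * alpha); lga <- lgamma(alpha)
  i <- 0L
  score_cell_index <- function(idx) {
    i <<- i + 1L
    cnt <- tabulate(idx + off, 2L * n_cells)
    c0 <- cnt[i_seq]; c1 <- cnt[i_cases]
    ri <- c0 + c1
    nz <- ri > 0L
    p_row <- ri[nz] / n
    p_cell <- cnt[cnt > 0L] / n
    mi[i] <<- (h_y - sum(p_row * log(p_row)) + sum(p_cell * log(p_cell))) / log_base
    k2[i] <<- sum(lgamma(ri + 2 * alpha) - lg2a -
                    lgamma(c0 + alpha) - lgamma(c1 + alpha) + 2 * lga)
    e0 <- p_row * n_ctrl; e1 <- p_row * n_case
    chi2[i] <<- sum((c0[nz] - e0)^2 / e0) + sum((c1[nz] - e1)^2 / e1)
    df[i] <<- sum(nz) - 1L
  }
  # lexicographic recursion sharing the base-3 prefix index across siblings,
  # so the innermost level costs one add per combination
  recurse <- function(prefix, first, depth) {
    if (depth == 1L) {
      for (j in first:m) score_cell_index(prefix + g[, j])
    } else {
      for (j in first:(m - depth + 1L)) {
        recurse((prefix + g[, j]) * 3L, j + 1L, depth - 1L)
      }
    }
  }
  recurse(integer(n), 1L, order)
  pv <- stats::pchisq(chi2, df, lower.tail = FALSE)

  out <- as.data.frame(t(combs))
  names(out) <- paste0("snp", seq_len(order))
  out$snps <- apply(combs, 2, function(ix) paste(ds$snp_names[ix], collapse = ","))
  out$mi <- mi; out$k2 <- k2; out$chi2 <- chi2; out$df <- df; out$pvalue <- pv
  attr(out, "n_evaluated") <- n_comb
  attr(out, "order") <- order
  class(out) <- c("epistasis_candidates", "data.frame")
  out
}

#' Pareto non-dominated front under (maximize MI, minimize K2)
#'
#' Candidate a dominates b iff `a.mi >= b.mi` and `a.k2 <= b.k2` with at
#' least one strict inequality. The front (all non-dominated candidates) is
#' returned sorted by descending MI, ties by ascending K2, then by the SNP
#' tuple. Candidates with identical scores are mutually non-dominated and
#' all kept.
#'
#' @param candidates an [enumerate_and_score()] table (or any data.frame
#'   with `mi` and `k2` columns).
#' @return A `pareto_front` object: list with `candidates` (front rows, the
#'   input table gains a logical `on_front` marker), `n_evaluated`, `order`.
#' @export
pareto_front <- function(candidates) {
  if (NROW(candidates) == 0) stop("empty candidate list")
  snp_cols <- grep("^snp[0-9]+$", names(candidates), value = TRUE)
  ord_args <- c(list(-candidates$mi, candidates$k2),
                lapply(snp_cols, function(cn) candidates[[cn]]))
  o <- do.call(order, ord_args)
  mi <- candidates$mi[o]; k2 <- candidates$k2[o]
  keep <- logical(length(o))
  best_k2 <- Inf; best_mi <- -Inf
  for (i in seq_along(o)) {
    if (k2[i] < best_k2) {
      keep[i] <- TRUE
      best_k2 <- k2[i]; best_mi <- mi[i]
    } else if (k2[i] == best_k2 && mi[i] == best_mi) {
      keep[i] <- TRUE  # exact score tie: mutually non-dominated
    }
  }
  on_front <- logical(NROW(candidates))
  on_front[o[keep]] <- TRUE
  front <- candidates[o[keep], , drop = FALSE]
  rownames(front) <- NULL
  structure(list(candidates = front,
                 n_evaluated = attr(candidates, "n_evaluated") %||% NROW(candidates),
                 order = attr(candidates, "order") %||% length(snp_cols),
                 on_front = on_front),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d non-dominated of %d evaluated combinations\n",
              NROW(x$candidates), x$n_evaluated))
  print(utils::head(x$candidates[, c("snps", "mi", "k2", "chi2", "pvalue")], 10))
  invisible(x)
}

#' Chi-square significance filter on a Pareto front
#'
#' Keeps front members whose chi-square p-value survives the significance
#' threshold: `pvalue <= alpha / n_tests` under Bonferroni correction
#' (default, with `n_tests` the number of combinations evaluated in the
#' scan), or `pvalue <= alpha` with no correction.
#'
#' @param front a [pareto_front()].
#' @param alpha family significance level in (0, 1).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param n_tests number of tests charged to the correction; defaults to
#'   the number of combinations the scan evaluated.
#' @return A `detection_result`: list with `front`, `significant` (subset
#'   data.frame), `alpha`, `correction`, `n_tests`, `threshold`.
#' @export
significance_filter <- function(front, alpha = 0.05,
                                correction = c("bonferroni", "none"),
                                n_tests = NULL) {
  stopifnot(inherits(front, "pareto_front"), alpha > 0, alpha < 1)
  correction <- match.arg(correction)
  n_tests <- as.numeric(n_tests %||% front$n_evaluated)
  if (n_tests < NROW(front$candidates))
    stop("n_tests must be at least the number of front members")
  threshold <- if (correction == "bonferroni") alpha / n_tests else alpha
  sig <- front$candidates[front$candidates$pvalue <= threshold, , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(front = front, significant = sig, alpha = alpha,
                 correction = correction, n_tests = n_tests,
                 threshold = threshold),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("Detection: %d of %d front members pass chi-square filter (%s, alpha = %g, threshold = %.3g)\n",
              NROW(x$significant), NROW(x$front$candidates), x$correction,
              x$alpha, x$threshold))
  if (NROW(x$significant)) print(x$significant[, c("snps", "mi", "k2", "chi2", "pvalue")])
  invisible(x)
}

# SNP index columns of a candidate table as an integer matrix.
candidate_snp_matrix <- function(candidates) {
  snp_cols <- grep("^snp[0-9]+$", names(candidates), value = TRUE)
  as.matrix(candidates[, snp_cols, drop = FALSE])
}

#' Union of SNP indices across detected candidates
#'
#' The epistatic feature set used by the clustering and prediction stages:
#' all SNP columns appearing in any of the given candidates.
#'
#' @param candidates rows of a candidate table (e.g. `$significant`).
#' @return Sorted integer vector of SNP column indices.
#' @export
candidate_snp_union <- function(candidates) {
  sort(unique(as.integer(candidate_snp_matrix(candidates))))
}

#' Write / read the candidate report
#'
#' Tab-separated report with one row per scored combination: SNP names,
#' the three scores, chi-square details, and front/significance markers.
#'
#' @param candidates full candidate table from [enumerate_and_score()].
#' @param result a [significance_filter()] result for markers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, result, path) {
  rep_df <- candidates
  rep_df$on_front <- result$front$on_front
  key <- function(df) apply(candidate_snp_matrix(df), 1, paste, collapse = "-")
  rep_df$significant <- key(candidates) %in% key(result$significant)
  rep_df$corrected_alpha <- result$threshold
  data.table::fwrite(rep_df, path, sep = "\t")
  invisible(path)
}
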