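#' Penetrance tables for multi-locus disease models
#'
#' A penetrance table gives, for every genotype combination of `order`
#' interacting biallelic SNPs (3^order combinations, minor-allele-count
#' coding 0/1/2 per locus), the probability that a carrier is affected.
#' Population prevalence and broad-sense heritability are derived under
#' Hardy-Weinberg equilibrium at the supplied minor allele frequencies:
#' prevalence \eqn{K = \sum_g P(g) f_g} and heritability
#' \eqn{h^2 = \sum_g P(g) (f_g - K)^2 / (K (1 - K))}.
#'
#' Two model families are supported. `"explicit"` takes the 3^order cell
#' probabilities directly (`params$probs`). `"parity"` is a canonical pure
#' epistasis family with near-zero marginal effects at symmetric MAFs:
#' cells whose summed genotype code is odd get `params$f_high`, even cells
#' get `params$f_low`.
#'
#' @param order integer number of interacting SNPs (k >= 1; typically 2 or 3).
#' @param mafs numeric vector of `order` minor allele frequencies in (0, 0.5].
#' @param model_name `"parity"` or `"explicit"`.
#' @param params for `"explicit"`, a list with `probs` (length 3^order, in
#'   \[0,1\]); for `"parity"`, a list with `f_low` and `f_high`,
#'   `0 <= f_low < f_high <= 1`.
#' @return An object of class `penetrance_table` with fields `order`, `mafs`,
#'   `probs`, `prevalence`, `heritability`.
#' @examples
#' pt <- make_penetrance_table(2, c(0.2, 0.2), "parity",
#'                             list(f_low = 0.05, f_high = 0.95))
#' pt$prevalence
#' @export
make_penetrance_table <- function(order, mafs, model_name = c("parity", "explicit"),
                                  params = list()) {
  model_name <- match.arg(model_name)
  stopifnot(is.numeric(order), length(order) == 1, order >= 1, order == round(order))
  order <- as.integer(order)
  if (length(mafs) != order)
    stop("`mafs` must have length `order` (", order, "), got ", length(mafs))
  if (any(mafs <= 0 | mafs > 0.5))
    stop("all MAFs must lie in (0, 0.5]")
  n_cells <- 3L^order

  if (model_name == "explicit") {
    probs <- params$probs
    if (is.null(probs) || length(probs) != n_cells)
      stop("explicit model requires `params$probs` of length 3^order = ",
           n_cells, ", got ", length(probs))
    if (any(probs < 0 | probs > 1)) stop("penetrance values must lie in [0, 1]")
  } else {
    f_low <- params$f_low; f_high <- params$f_high
    if (is.null(f_low) || is.null(f_high))
      stop("parity model requires `params$f_low` and `params$f_high`")
    if (!(f_low >= 0 && f_high <= 1 && f_low < f_high))
      stop("parity model requires 0 <= f_low < f_high <= 1")
    gsum <- genotype_code_sums(order)
    probs <- ifelse(gsum %% 2L == 1L, f_high, f_low)
  }

  w <- hwe_cell_probs(mafs)
  prevalence <- sum(w * probs)
  heritability <- if (prevalence > 0 && prevalence < 1)
    sum(w * (probs - prevalence)^2) / (prevalence * (1 - prevalence))
  else 0

  structure(list(order = order, mafs = as.numeric(mafs), probs = as.numeric(probs),
                 prevalence = prevalence, heritability = heritability),
            class = "penetrance_table")
}

# HWE genotype probabilities for one locus at allele frequency p,
# code = minor allele count: P(0)=(1-p)^2, P(1)=2p(1-p), P(2)=p^2.
hwe_locus_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# Joint HWE cell probabilities over all 3^k genotype combinations, indexed
# base-3 with the FIRST locus as the most significant digit.
hwe_cell_probs <- function(mafs) {
  w <- 1
  for (p in mafs) w <- as.vector(outer(hwe_locus_probs(p), w))
  w
}

# Sum of genotype codes for each combination index 0..3^k-1 (base-3 digits).
genotype_code_sums <- function(order) {
  idx <- 0:(3L^order - 1L)
  s <- integer(length(idx))
  for (d in seq_len(order)) {
    s <- s + idx %% 3L
    idx <- idx %/% 3L
  }
  s
}

#' Find a parity penetrance model matching a target heritability
#'
#' Solves for the symmetric parity model (`f_low = 0.5 - d`,
#' `f_high = 0.5 + d`) whose heritability under HWE equals `heritability`.
#' Useful for building simulation presets where effect size is specified as
#' heritability rather than raw penetrance values.
#'
#' @param order interaction order.
#' @param mafs minor allele frequencies, length `order`.
#' @param heritability target heritability in (0, h2_max); the attainable
#'   maximum (at d = 0.5) depends on the MAFs.
#' @return A `penetrance_table`.
#' @export
parity_table_for_heritability <- function(order, mafs, heritability) {
  stopifnot(heritability > 0)
  h2_of <- function(d) {
    make_penetrance_table(order, mafs, "parity",
                          list(f_low = 0.5 - d, f_high = 0.5 + d))$heritability
  }
  h2_max <- h2_of(0.5 - 1e-12)
  if (heritability >= h2_max)
    stop(sprintf("target heritability %.3f exceeds the attainable maximum %.3f at these MAFs",
                 heritability, h2_max))
  d <- stats::uniroot(function(d) h2_of(d) - heritability,
                      lower = 1e-9, upper = 0.5 - 1e-12, tol = 1e-12)$root
  make_penetrance_table(order, mafs, "parity",
                        list(f_low = 0.5 - d, f_high = 0.5 + d))
}

#' @export
print.penetrance_table <- function(x, ...) {
  cat(sprintf("Penetrance table: %d-locus model, MAFs (%s)\n",
              x$order, paste(format(x$mafs), collapse = ", ")))
  cat(sprintf("  prevalence %.4f, heritability %.4f\n", x$prevalence, x$heritability))
  invisible(x)
}

#' Designate the pathogenic SNP columns of a disease model
#'
#' Binds a penetrance table to the dataset columns that carry its
#' interacting SNPs.
#'
#' @param penetrance a [make_penetrance_table()] object.
#' @param snp_indices `penetrance$order` distinct column indices.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(penetrance, snp_indices) {
  stopifnot(inherits(penetrance, "penetrance_table"))
  snp_indices <- as.integer(snp_indices)
  if (length(snp_indices) != penetrance$order)
    stop("need exactly ", penetrance$order, " pathogenic SNP indices")
  if (anyDuplicated(snp_indices)) stop("pathogenic SNP indices must be distinct")
  if (any(snp_indices < 1)) stop("SNP indices must be positive")
  structure(list(penetrance = penetrance, snp_indices = snp_indices),
            class = "disease_model")
}
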