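# Shared fixture builders. Everything is generated in code under fixed seeds.

parity_model <- function(order, maf, f_low, f_high, idx) {
  disease_model(
    make_penetrance_table(order, rep(maf, order), "parity",
                          list(f_low = f_low, f_high = f_high)),
    idx)
}

# Dominant-dominant epistasis: penetrance f_high iff every locus carries at
# least one minor allele. Unlike the parity family this has marginal
# effects, so subtype clusters are geometrically separable.
domdom_model <- function(order, maf, f_low, f_high, idx) {
  cells <- 3L^order
  carries_all <- vapply(0:(cells - 1L), function(i) {
    g <- integer(order)
    for (d in order:1) { g[d] <- i %% 3L; i <- i %/% 3L }
    all(g >= 1L)
  }, logical(1))
  disease_model(
    make_penetrance_table(order, rep(maf, order), "explicit",
                          list(probs = ifelse(carries_all, f_high, f_low))),
    idx)
}

# Small deterministic dataset: 2 informative-ish SNPs + noise, fixed seed.
toy_dataset <- function(n = 200, n_snps = 5, seed = 42) {
  set.seed(seed)
  g <- matrix(rbinom(n * n_snps, 2, 0.3), n, n_snps)
  labels <- as.integer(g[, 1] >= 1)
  genotype_dataset(g, labels)
}

# Brute-force entropy oracle: plug-in entropies from explicit joint tables,
# independent of the package's count layout.
oracle_mi <- function(genotypes, labels, base = 2) {
  key <- apply(cbind(genotypes), 1, paste, collapse = "-")
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p)) / log(base)
  }
  ent(labels) + ent(key) - ent(paste(key, labels))
}

# Exact-integer factorial oracle for the K2 score on small tables.
oracle_k2 <- function(genotypes, labels) {
  key <- apply(cbind(genotypes), 1, paste, collapse = "-")
  total <- 0
  for (cell in unique(key)) {
    r1 <- sum(key == cell & labels == 0)
    r2 <- sum(key == cell & labels == 1)
    total <- total + log(factorial(r1 + r2 + 1)) -
      log(factorial(r1)) - log(factorial(r2))
  }
  total
}

# Quadratic dominance oracle for the Pareto front (maximize mi, minimize k2).
oracle_front <- function(mi, k2) {
  n <- length(mi)
  vapply(seq_len(n), function(i) {
    !any(mi >= mi[i] & k2 <= k2[i] & (mi > mi[i] | k2 < k2[i]))
  }, logical(1))
}

# Exhaustive two-cluster inertia oracle for tiny point sets.
oracle_best_bipartition_inertia <- function(x) {
  n <- nrow(x)
  best <- Inf
  # point 1 fixed in cluster A: all 2^(n-1) bipartitions up to symmetry
  for (mask in 0:(2^(n - 1) - 2)) {
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    inert <- function(m) {
      if (!any(m)) return(Inf)
      ctr <- colMeans(x[m, , drop = FALSE])
      sum(sweep(x[m, , drop = FALSE], 2, ctr)^2)
    }
    best <- min(best, inert(inA) + inert(!inA))
  }
  best
}
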