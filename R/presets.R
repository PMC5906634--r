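#' Built-in dataset presets
#'
#' Twenty standard simulation presets covering the usual evaluation grid for
#' epistasis methods: `Pure1..Pure5` (one 2-SNP disease model, MAFs
#' (0.2, 0.2)), `Pure6..Pure10` (one 3-SNP model, MAFs (0.2, 0.2, 0.2)),
#' `Hete1..Hete5` (two 2-SNP models H1/H2 at MAFs (0.2, 0.2) and (0.3, 0.3),
#' each generating 50% of the samples) and `Hete6..Hete10` (the 3-SNP
#' heterogeneous counterparts). Sample sizes run 1000, 2000, 3000, 4000,
#' 8000 within each block; every preset has 100 SNPs.
#'
#' Effect size is not part of the preset grid and is supplied as a target
#' heritability (see [simulate_preset()]).
#'
#' @return A data.frame with columns `name`, `n_samples`, `n_snps`, `order`,
#'   `maf_h1`, `maf_h2` (NA for pure presets), `proportion_h1`.
#' @export
dataset_presets <- function() {
  sizes <- c(1000L, 2000L, 3000L, 4000L, 8000L)
  rbind(
    data.frame(name = paste0("Pure", 1:5), n_samples = sizes, n_snps = 100L,
               order = 2L, maf_h1 = 0.2, maf_h2 = NA_real_, proportion_h1 = 1),
    data.frame(name = paste0("Pure", 6:10), n_samples = sizes, n_snps = 100L,
               order = 3L, maf_h1 = 0.2, maf_h2 = NA_real_, proportion_h1 = 1),
    data.frame(name = paste0("Hete", 1:5), n_samples = sizes, n_snps = 100L,
               order = 2L, maf_h1 = 0.2, maf_h2 = 0.3, proportion_h1 = 0.5),
    data.frame(name = paste0("Hete", 6:10), n_samples = sizes, n_snps = 100L,
               order = 3L, maf_h1 = 0.2, maf_h2 = 0.3, proportion_h1 = 0.5)
  )
}

#' Simulate a dataset from a named preset
#'
#' Instantiates a [dataset_presets()] row: pathogenic SNP columns are placed
#' by a seeded draw, penetrance follows the symmetric parity family solved
#' for the requested heritability (see [parity_table_for_heritability()]),
#' and the dataset is generated with [simulate_pure()] or
#' [simulate_heterogeneous()].
#'
#' @param name preset name, e.g. `"Pure1"` or `"Hete6"`.
#' @param seed integer seed.
#' @param heritability per-model heritability (default 0.2, a moderate
#'   realistic effect).
#' @param f_low,f_high optional explicit parity penetrance values; when
#'   given they override `heritability`.
#' @return A `genotype_dataset`.
#' @export
simulate_preset <- function(name, seed = 1L, heritability = 0.2,
                            f_low = NULL, f_high = NULL) {
  presets <- dataset_presets()
  row <- presets[presets$name == name, ]
  if (nrow(row) != 1) stop("unknown preset '", name, "'; see dataset_presets()")
  k <- row$order
  make_pt <- function(maf) {
    if (!is.null(f_low) && !is.null(f_high))
      make_penetrance_table(k, rep(maf, k), "parity",
                            list(f_low = f_low, f_high = f_high))
    else parity_table_for_heritability(k, rep(maf, k), heritability)
  }
  hete <- !is.na(row$maf_h2)
  idx <- with_seed(derive_seed(seed, "preset-snps"),
                   sample.int(row$n_snps, if (hete) 2 * k else k))
  if (hete) {
    m1 <- disease_model(make_pt(row$maf_h1), sort(idx[seq_len(k)]))
    m2 <- disease_model(make_pt(row$maf_h2), sort(idx[k + seq_len(k)]))
    simulate_heterogeneous(row$n_samples, row$n_snps, m1, m2,
                           row$proportion_h1, seed = derive_seed(seed, "simulate"))
  } else {
    m1 <- disease_model(make_pt(row$maf_h1), sort(idx))
    simulate_pure(row$n_samples, row$n_snps, m1, 0.5,
                  seed = derive_seed(seed, "simulate"))
  }
}
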