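#' Read a tab-separated genotype file
#'
#' Parses the GAMETES-style dialect: a header row of SNP names ending in the
#' literal column `Class`, then one tab-separated row of integer codes per
#' sample. Genotypes must be 0/1/2 (minor-allele count) and class 0/1; any
#' other value is rejected with the offending row and column named. If a
#' subtype sidecar file (`<path>.subtypes.tsv`, columns `sample_index`,
#' `subtype`) is present, case labels are upgraded to subtypes 1..K.
#'
#' @param path input file path.
#' @param sidecar read the subtype sidecar if present (default `TRUE`).
#' @return A `genotype_dataset`.
#' @export
read_gametes <- function(path, sidecar = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "integer")
  if (!"Class" %in% names(dt))
    stop("missing 'Class' column in ", path)
  if (names(dt)[ncol(dt)] != "Class")
    stop("'Class' must be the final column in ", path)
  labels <- dt$Class
  geno <- as.matrix(dt)[, setdiff(names(dt), "Class"), drop = FALSE]
  bad <- which(!(geno %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    r <- ((bad[1] - 1) %% nrow(geno)) + 1
    c <- ((bad[1] - 1) %/% nrow(geno)) + 1
    stop(sprintf("invalid genotype code %s at sample %d, SNP '%s'",
                 geno[bad[1]], r, colnames(geno)[c]))
  }
  if (!all(labels %in% c(0L, 1L)))
    stop("Class column must contain only 0 (control) and 1 (case)")
  side_path <- paste0(path, ".subtypes.tsv")
  if (sidecar && file.exists(side_path)) {
    sc <- data.table::fread(side_path, sep = "\t", header = TRUE)
    labels[sc$sample_index] <- as.integer(sc$subtype)
    return(genotype_dataset(geno, labels, colnames(geno),
                            binary_labels = dt$Class))
  }
  genotype_dataset(geno, labels, colnames(geno))
}

#' Write a genotype dataset as a tab-separated file
#'
#' Emits the dialect [read_gametes()] expects: SNP-name header plus `Class`,
#' tab-separated integer rows. Multi-class labels are collapsed to 0/1 in
#' the `Class` column; the subtype of each case is written to the sidecar
#' `<path>.subtypes.tsv` (columns `sample_index`, `subtype`).
#'
#' @param ds a `genotype_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gametes <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  out <- data.table::as.data.table(ds$genotypes)
  data.table::setnames(out, ds$snp_names)
  multi <- max(ds$labels, 0L) > 1L
  out$Class <- if (multi) as.integer(ds$labels >= 1L) else ds$labels
  data.table::fwrite(out, path, sep = "\t")
  if (multi) {
    cases <- which(ds$labels >= 1L)
    data.table::fwrite(data.table::data.table(sample_index = cases,
                                              subtype = ds$labels[cases]),
                       paste0(path, ".subtypes.tsv"), sep = "\t")
  }
  invisible(path)
}
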