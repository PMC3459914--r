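#' Genotype matrix container
#'
#' Effect-allele dosages for N individuals at M SNPs with an explicit
#' missingness mask. Dosages count copies of the manifest's effect allele,
#' so the additive regression coefficient is per effect-allele copy.
#'
#' @param individual_ids character vector, no duplicates.
#' @param manifest [snp_manifest()] describing the M columns.
#' @param dosage N x M integer matrix with entries in {0, 1, 2} (NA where
#'   missing).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(individual_ids, manifest, dosage) {
  individual_ids <- as.character(individual_ids)
  stopifnot(!anyDuplicated(individual_ids),
            inherits(manifest, "snp_manifest"),
            is.matrix(dosage),
            nrow(dosage) == length(individual_ids),
            ncol(dosage) == nrow(manifest))
  ok <- dosage[!is.na(dosage)]
  if (length(ok) && !all(ok %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(individual_ids, manifest$rsid)
  structure(list(individual_ids = individual_ids,
                 manifest = manifest,
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample effect-allele and minor-allele frequencies
#'
#' Computed over non-missing calls per SNP.
#'
#' @param g a [genotype_matrix()].
#' @return tibble with `rsid`, `eaf_hat` (effect-allele frequency),
#'   `maf_hat` (min(eaf_hat, 1 - eaf_hat)), `call_rate`, `n_called`.
#' @export
allele_frequencies <- function(g) {
  eaf <- colMeans(g$dosage, na.rm = TRUE) / 2
  n_called <- colSums(!is.na(g$dosage))
  tibble::tibble(
    rsid = g$manifest$rsid,
    eaf_hat = as.numeric(eaf),
    maf_hat = pmin(eaf, 1 - eaf),
    call_rate = n_called / nrow(g$dosage),
    n_called = as.integer(n_called)
  )
}

#' Subset a genotype matrix by SNP index or rsid
#'
#' @param g a [genotype_matrix()].
#' @param snps integer indices or rsid character vector; order preserved.
#' @return a [genotype_matrix()] restricted to the requested SNPs.
#' @export
subset_snps <- function(g, snps) {
  if (is.character(snps)) snps <- match(snps, g$manifest$rsid)
  stopifnot(!anyNA(snps), all(snps >= 1), all(snps <= ncol(g$dosage)))
  man <- g$manifest[snps, ]
  class(man) <- class(g$manifest)
  genotype_matrix(g$individual_ids, man, g$dosage[, snps, drop = FALSE])
}
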