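#' Correct recorded blood pressure for antihypertensive medication
#'
#' Adds 15 mmHg to SBP and 10 mmHg to DBP for individuals flagged as on
#' blood-pressure medication, the standard correction that restores the
#' untreated pressure scale before association modelling. Missing values
#' stay missing. The returned table carries a done-flag so applying the
#' correction twice is a no-op.
#'
#' @param pheno phenotype tibble with `medication_ht`.
#' @return the adjusted tibble (attribute `bp_adjusted = TRUE`).
#' @export
adjust_bp_for_medication <- function(pheno) {
  stopifnot(!is.null(pheno$medication_ht))
  if (isTRUE(attr(pheno, "bp_adjusted"))) return(pheno)
  flag <- !is.na(pheno$medication_ht) & pheno$medication_ht
  pheno$sbp[flag] <- pheno$sbp[flag] + 15
  pheno$dbp[flag] <- pheno$dbp[flag] + 10
  attr(pheno, "bp_adjusted") <- TRUE
  pheno
}

#' Code smoking exposure
#'
#' Exposure schemes: `binary_smoker` collapses light/heavy to 1 and
#' non-smokers (never and former alike) to 0; `three_level_quantity` is
#' non / 1-10 / >10 cigarettes per day; `three_level_history` is
#' never / former / current; `gender` codes sex as the "exposure" for
#' gender-interaction analyses. Current smokers reporting 0 cigarettes/day
#' are inconsistent: they are flagged and excluded (NA) from
#' exposure-stratified fits rather than silently recoded.
#'
#' @param pheno phenotype tibble.
#' @param scheme exposure scheme.
#' @return list with `scheme`, `values` (factor, NA where inconsistent),
#'   `smoker_indicator` (0/1/NA) and `inconsistent` (logical).
#' @export
code_smoking <- function(pheno,
                         scheme = c("binary_smoker", "three_level_quantity",
                                    "three_level_history", "gender")) {
  scheme <- match.arg(scheme)
  current <- pheno$smoking_status == "current"
  inconsistent <- !is.na(current) & current &
    (!is.na(pheno$cigs_per_day) & pheno$cigs_per_day == 0)
  cat3 <- rep(NA_character_, nrow(pheno))
  cat3[!is.na(current) & !current] <- "non"
  ok <- !is.na(current) & current & !inconsistent &
    !is.na(pheno$cigs_per_day)
  cat3[ok & pheno$cigs_per_day <= 10] <- "light"
  cat3[ok & pheno$cigs_per_day > 10] <- "heavy"
  smoker <- ifelse(is.na(cat3), NA_integer_,
                   as.integer(cat3 %in% c("light", "heavy")))
  values <- switch(scheme,
    binary_smoker = factor(ifelse(is.na(smoker), NA, c("non", "smoker")[smoker + 1L]),
                           levels = c("non", "smoker")),
    three_level_quantity = factor(cat3, levels = c("non", "light", "heavy")),
    three_level_history = factor(pheno$smoking_status,
                                 levels = c("never", "former", "current")),
    gender = factor(pheno$sex, levels = c("female", "male"))
  )
  list(scheme = scheme, values = values, smoker_indicator = smoker,
       inconsistent = inconsistent)
}

#' Keep common SNPs (sample MAF above threshold)
#'
#' MAF is computed from non-missing calls; SNP order is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min retention threshold (keep MAF > `maf_min`).
#' @return the filtered [genotype_matrix()]; errors if nothing survives.
#' @export
filter_common_snps <- function(g, maf_min = 0.05) {
  af <- allele_frequencies(g)
  keep <- which(!is.na(af$maf_hat) & af$maf_hat > maf_min)
  if (!length(keep)) stop("no SNP passes MAF > ", maf_min)
  subset_snps(g, keep)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness of fit of the observed genotype counts
#' (n0, n1, n2 copies of the counted allele) against the p^2 / 2pq / q^2
#' expectations at the sample allele frequency. Monomorphic SNPs return
#' chi-square 0, p 1 by convention.
#'
#' @param dosages vector of 0/1/2 dosages (NA ignored).
#' @return list with `chisq`, `p_value`, `n`.
#' @export
hwe_test <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n < 1) stop("no non-missing genotypes")
  obs <- c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p <= 0 || p >= 1) return(list(chisq = 0, p_value = 1, n = n))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((obs - e)^2 / e)
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = n)
}

#' Composite (genotypic) linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors over their shared
#' non-missing individuals. This composite estimate needs no phase
#' information and is the standard pruning statistic.
#'
#' @param a,b dosage vectors of equal length.
#' @return r^2 in [0, 1]; NA if fewer than 2 complete pairs or a vector is
#'   constant.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Select the stratification-PC SNP panel
#'
#' The screening recipe for the principal-component panel: keep SNPs with
#' MAF > 1%, Hardy-Weinberg p > 0.005 and call rate > 99.5%; then greedy
#' left-to-right LD pruning drops any SNP with r^2 > 0.2 against an
#' already-retained SNP; finally the pruned list is thinned to every 15th
#' SNP (positions 1, 16, 31, ... of the pruned order).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,hwe_p_min,callrate_min,prune_r2_max,thin_step thresholds.
#' @return the panel [genotype_matrix()]; the per-SNP filter decisions are
#'   attached as attribute `qc_log` (rsid, status, reason).
#' @export
select_pc_panel <- function(g, maf_min = 0.01, hwe_p_min = 0.005,
                            callrate_min = 0.995, prune_r2_max = 0.2,
                            thin_step = 15L) {
  af <- allele_frequencies(g)
  m <- ncol(g$dosage)
  reason <- rep("kept", m)
  reason[af$call_rate <= callrate_min] <- "call_rate"
  for (j in which(reason == "kept")) {
    if (is.na(af$maf_hat[j]) || af$maf_hat[j] <= maf_min) {
      reason[j] <- "maf"
    } else if (hwe_test(g$dosage[, j])$p_value <= hwe_p_min) {
      reason[j] <- "hwe"
    }
  }
  surv <- which(reason == "kept")
  retained <- integer(0)
  for (j in surv) {
    r2 <- vapply(retained, function(k) ld_r2(g$dosage[, j], g$dosage[, k]),
                 numeric(1))
    if (length(r2) && any(!is.na(r2) & r2 > prune_r2_max)) {
      reason[j] <- "ld_prune"
    } else {
      retained <- c(retained, j)
    }
  }
  thinned <- retained[seq(1L, length(retained), by = thin_step)]
  reason[setdiff(retained, thinned)] <- "thinned"
  if (!length(thinned)) stop("PC panel is empty after filtering")
  out <- subset_snps(g, thinned)
  attr(out, "qc_log") <- data.frame(rsid = g$manifest$rsid, status =
                                      ifelse(seq_len(m) %in% thinned,
                                             "kept", "dropped"),
                                    reason = reason,
                                    stringsAsFactors = FALSE)
  out
}

#' Principal components of the genotype panel
#'
#' Columns are standardized to mean 0, variance 1 under Hardy-Weinberg
#' (subtract 2p-hat, divide by sqrt(2 p-hat (1 - p-hat)); Patterson
#' scaling); missing calls are mean-imputed (0 after centering) for the
#' decomposition only. The top-k components of the individual-by-individual
#' covariance are computed via the SVD of the standardized matrix.
#'
#' @param panel a [genotype_matrix()] (as from [select_pc_panel()]).
#' @param k number of components (default 3).
#' @return list with `scores` (N x k), `loadings` (M x k), `eigenvalues`
#'   (length k, variances of the scores) and `snps_used`.
#' @export
compute_pcs <- function(panel, k = 3L) {
  X <- panel$dosage
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- which(p > 0 & p < 1)
  if (!length(keep)) stop("no polymorphic SNP in the panel")
  X <- X[, keep, drop = FALSE]
  Z <- sweep(X, 2, 2 * p[keep], "-")
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, colMeans(Z), "-")  # exact zero column means after imputation
  sv <- svd(Z)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds the rank (", rank, ") of the panel")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("pc", seq_len(k))
  list(scores = scores,
       loadings = sv$v[, seq_len(k), drop = FALSE],
       eigenvalues = sv$d[seq_len(k)]^2 / (nrow(Z) - 1),
       snps_used = panel$manifest$rsid[keep])
}
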