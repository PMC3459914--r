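#' Standard covariate set for the regional models
#'
#' The additive models adjust for sex and the top stratification PCs, and —
#' for blood-pressure outcomes only — for BMI. The BMI outcome never has
#' BMI as a covariate.
#'
#' @param pheno phenotype tibble.
#' @param pcs optional PC result from [compute_pcs()] (its `scores` are
#'   used) or a numeric matrix/data frame of per-individual scores.
#' @param outcome one of "bmi", "sbp", "dbp".
#' @return data frame of covariate columns aligned to `pheno` rows.
#' @export
default_covariates <- function(pheno, pcs = NULL, outcome = "sbp") {
  cov <- data.frame(sex = as.numeric(pheno$sex == "male"))
  if (outcome != "bmi") cov$bmi <- pheno$bmi
  if (!is.null(pcs)) {
    sc <- if (is.list(pcs) && !is.data.frame(pcs)) pcs$scores else as.matrix(pcs)
    stopifnot(nrow(sc) == nrow(pheno))
    cov <- cbind(cov, as.data.frame(sc))
  }
  cov
}

.assoc_design <- function(dosage, covariates) {
  X <- cbind(intercept = 1, snp = dosage)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    X <- cbind(X, as.matrix(as.data.frame(covariates)))
  X
}

#' Stratified additive single-marker association
#'
#' One additive linear fit per SNP per exposure stratum:
#' outcome ~ effect-allele dosage + covariates, over the stratum's complete
#' cases. Confidence intervals are normal-quantile (beta +/- 1.96 se) by
#' default; p-values are two-sided from the t distribution on the residual
#' degrees of freedom. Strata too small to fit are flagged, not dropped.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno phenotype tibble aligned with `geno` rows.
#' @param outcome one of "bmi", "sbp", "dbp".
#' @param strata factor over individuals (e.g. the `values` of
#'   [code_smoking()]); NA rows are excluded.
#' @param covariates data frame of covariates (see [default_covariates()]).
#' @param conf_level confidence level.
#' @param ci_quantile "normal" (z) or "t".
#' @return tibble with rsid, stratum, beta, se, ci_low, ci_high, p_value,
#'   n_used, flag.
#' @export
run_stratified <- function(geno, pheno, outcome, strata, covariates = NULL,
                           conf_level = 0.95, ci_quantile = c("normal", "t")) {
  ci_quantile <- match.arg(ci_quantile)
  stopifnot(nrow(pheno) == nrow(geno$dosage), length(strata) == nrow(pheno))
  y <- pheno[[outcome]]
  strata <- as.factor(strata)
  out <- list()
  for (lev in levels(strata)) {
    rows <- which(!is.na(strata) & strata == lev)
    for (j in seq_len(ncol(geno$dosage))) {
      X <- .assoc_design(geno$dosage[rows, j],
                         if (is.null(covariates)) NULL
                         else covariates[rows, , drop = FALSE])
      res <- tryCatch(fit_ols(X, y[rows]), error = function(e) e)
      if (inherits(res, "error")) {
        out[[length(out) + 1L]] <- tibble::tibble(
          rsid = geno$manifest$rsid[j], stratum = lev, beta = NA_real_,
          se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, n_used = sum(stats::complete.cases(X) & !is.na(y[rows])),
          flag = "too_small")
        next
      }
      b <- res$coefficients["snp"]
      se <- sqrt(res$vcov["snp", "snp"])
      q <- if (ci_quantile == "normal") stats::qnorm(1 - (1 - conf_level) / 2)
           else stats::qt(1 - (1 - conf_level) / 2, res$df_residual)
      pv <- 2 * stats::pt(abs(b / se), res$df_residual, lower.tail = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(
        rsid = geno$manifest$rsid[j], stratum = lev, beta = unname(b),
        se = unname(se), ci_low = unname(b - q * se),
        ci_high = unname(b + q * se), p_value = unname(pv),
        n_used = res$n, flag = "ok")
    }
  }
  do.call(rbind, out)
}

#' SNP-by-exposure interaction tests
#'
#' Per SNP fits outcome ~ dosage + covariates + exposure + dosage:exposure
#' on complete cases and reports the interaction coefficient with its t
#' statistic and two-sided t-distribution p-value.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno phenotype tibble.
#' @param outcome outcome column name.
#' @param exposure 0/1 exposure indicator per individual (e.g.
#'   `smoker_indicator` from [code_smoking()]); NA rows drop out.
#' @param covariates covariate data frame.
#' @return tibble with rsid, beta_int, se_int, t_stat, p_unadjusted,
#'   n_used.
#' @export
run_interaction <- function(geno, pheno, outcome, exposure,
                            covariates = NULL) {
  stopifnot(length(exposure) == nrow(pheno))
  ev <- as.numeric(exposure)
  if (!all(ev[!is.na(ev)] %in% c(0, 1)))
    stop("exposure must be a 0/1 indicator")
  y <- pheno[[outcome]]
  out <- lapply(seq_len(ncol(geno$dosage)), function(j) {
    g <- geno$dosage[, j]
    X <- .assoc_design(g, covariates)
    X <- cbind(X, exposure = ev, snp_x_exposure = g * ev)
    res <- fit_ols(X, y)
    b <- res$coefficients["snp_x_exposure"]
    se <- sqrt(res$vcov["snp_x_exposure", "snp_x_exposure"])
    tibble::tibble(
      rsid = geno$manifest$rsid[j], beta_int = unname(b), se_int = unname(se),
      t_stat = unname(b / se),
      p_unadjusted = unname(2 * stats::pt(abs(b / se), res$df_residual,
                                          lower.tail = FALSE)),
      n_used = res$n)
  })
  do.call(rbind, out)
}

#' Smoker-only fits adjusted for smoking quantity
#'
#' Re-runs the additive fits on smokers with cigarettes/day added as a
#' continuous covariate, the check that an apparent genotype effect in
#' smokers is not residual confounding by smoking quantity. All supplied
#' rows must be smokers.
#'
#' @param geno genotype matrix restricted to smokers.
#' @param pheno phenotype rows for the same smokers.
#' @param outcome outcome column name.
#' @param smoker_indicator 0/1 vector for the supplied rows; any 0 is an
#'   error.
#' @param covariates covariate data frame (cigarettes/day is appended).
#' @return tibble as [run_stratified()] with stratum
#'   "smokers_quantity_adj".
#' @export
adjust_for_quantity <- function(geno, pheno, outcome, smoker_indicator,
                                covariates = NULL) {
  si <- smoker_indicator[!is.na(smoker_indicator)]
  if (any(si == 0)) stop("non-smoker rows present: restrict to smokers first")
  cov <- if (is.null(covariates)) data.frame(row.names = seq_len(nrow(pheno)))
         else as.data.frame(covariates)
  cov$cigs_per_day <- pheno$cigs_per_day
  res <- run_stratified(geno, pheno, outcome,
                        strata = factor(rep("smokers_quantity_adj", nrow(pheno))),
                        covariates = cov)
  res
}
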