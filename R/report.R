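#' Round half away from zero
#'
#' The rounding the published tables use (2.345 -> 2.35, -2.345 -> -2.35),
#' as opposed to R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 2L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Gender-by-smoking strata summary
#'
#' Counts, percentages and outcome means/SDs per gender and smoking
#' category (non / light / heavy), plus the headline shares: overall
#' non-smoker percentage and per-gender heavy-smoker percentage, computed
#' over individuals with non-missing smoking data and rounded to integers.
#'
#' @param pheno phenotype tibble.
#' @return list with `table` (per-stratum tibble), `n_complete`,
#'   `pct_non_smokers`, `pct_heavy_by_sex` (named vector), `flag` ("ok" or
#'   "empty_smoking").
#' @export
summarize_strata <- function(pheno) {
  cs <- code_smoking(pheno, "three_level_quantity")
  cat3 <- cs$values
  ok <- !is.na(cat3) & !is.na(pheno$sex)
  if (!any(ok)) {
    return(list(table = tibble::tibble(), n_complete = 0L,
                pct_non_smokers = NA_real_,
                pct_heavy_by_sex = c(male = NA_real_, female = NA_real_),
                flag = "empty_smoking"))
  }
  rows <- list()
  for (sx in c("male", "female")) {
    for (cg in c("non", "light", "heavy")) {
      sel <- ok & pheno$sex == sx & cat3 == cg
      n_sex <- sum(ok & pheno$sex == sx)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sx, smoking = cg, n = sum(sel),
        pct = 100 * sum(sel) / n_sex,
        bmi_mean = mean(pheno$bmi[sel], na.rm = TRUE),
        bmi_sd = stats::sd(pheno$bmi[sel], na.rm = TRUE),
        sbp_mean = mean(pheno$sbp[sel], na.rm = TRUE),
        sbp_sd = stats::sd(pheno$sbp[sel], na.rm = TRUE),
        dbp_mean = mean(pheno$dbp[sel], na.rm = TRUE),
        dbp_sd = stats::sd(pheno$dbp[sel], na.rm = TRUE))
    }
  }
  tab <- do.call(rbind, rows)
  heavy <- vapply(c(male = "male", female = "female"), function(sx) {
    round(100 * sum(ok & pheno$sex == sx & cat3 == "heavy") /
            sum(ok & pheno$sex == sx))
  }, numeric(1))
  list(table = tab,
       n_complete = sum(ok),
       pct_non_smokers = round(100 * sum(ok & cat3 == "non") / sum(ok)),
       pct_heavy_by_sex = heavy,
       flag = "ok")
}

#' Pool per-SNP effects by unweighted averaging
#'
#' The headline pooled effect across a set of associated SNPs: the plain
#' arithmetic mean of the per-SNP betas and of the CI endpoints, rounded
#' half-away-from-zero to 2 decimals. (Inverse-variance weighting is
#' available but not the default, which reproduces the published summary
#' arithmetic.)
#'
#' @param results tibble with `beta`, `ci_low`, `ci_high` (one row per
#'   SNP), all sharing outcome, stratum and units.
#' @param weights optional inverse-variance weights (e.g. 1/se^2).
#' @param digits rounding.
#' @return list with `beta`, `ci_low`, `ci_high`, `n_snps`.
#' @export
average_effect <- function(results, weights = NULL, digits = 2L) {
  stopifnot(nrow(results) >= 1)
  avg <- function(v) {
    if (is.null(weights)) mean(v) else sum(v * weights) / sum(weights)
  }
  list(beta = round_half_away(avg(results$beta), digits),
       ci_low = round_half_away(avg(results$ci_low), digits),
       ci_high = round_half_away(avg(results$ci_high), digits),
       n_snps = nrow(results))
}

.fmt_beta_ci <- function(beta, lo, hi) {
  sprintf("%.2f (%.2f, %.2f)", round_half_away(beta),
          round_half_away(lo), round_half_away(hi))
}

#' Render publication-shaped association tables
#'
#' One TSV per outcome in the stratified-table layout: rsid, alleles
#' (minor allele flagged with *), per-stratum "beta (ci_low, ci_high)"
#' columns, and — when interaction results are supplied — unadjusted and
#' adjusted interaction p-values. Betas are printed to 2 decimals, p-values
#' to 2 decimals; the rendering is lossless at that precision.
#'
#' @param stratified tibble from [run_stratified()] for one outcome.
#' @param manifest the [snp_manifest()].
#' @param maxt optional tibble from [bootstrap_maxt_interaction()].
#' @param path output TSV path.
#' @return the rendered data frame, invisibly written to `path`.
#' @export
render_tables <- function(stratified, manifest, maxt = NULL, path) {
  alleles <- ifelse(manifest$effect_is_minor,
                    paste0(manifest$effect_allele, "*/", manifest$other_allele),
                    paste0(manifest$effect_allele, "/", manifest$other_allele,
                           "*"))
  out <- data.frame(rsid = manifest$rsid, alleles = alleles,
                    stringsAsFactors = FALSE)
  if (nrow(stratified)) {
    for (lev in unique(stratified$stratum)) {
      sub <- stratified[stratified$stratum == lev, ]
      idx <- match(manifest$rsid, sub$rsid)
      out[[paste0("beta_", lev)]] <- ifelse(
        is.na(idx), NA,
        .fmt_beta_ci(sub$beta[idx], sub$ci_low[idx], sub$ci_high[idx]))
    }
  }
  if (!is.null(maxt)) {
    idx <- match(manifest$rsid, maxt$rsid)
    out$p_interaction <- sprintf("%.2f", round_half_away(maxt$p_unadjusted[idx]))
    out$p_adjusted <- sprintf("%.2f", round_half_away(maxt$p_adjusted[idx]))
  }
  if (!nrow(stratified)) out <- out[0, , drop = FALSE]
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(out)
}
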