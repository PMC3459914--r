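#' SNP manifest constructor
#'
#' A manifest describes the candidate-region SNP panel: identifiers, physical
#' positions, the effect allele whose copy number (0/1/2) enters the additive
#' regressions, the other allele, and the minor allele frequency. The effect
#' allele is an analysis choice (here the smoking-increasing allele) and is
#' sometimes the major allele, so the manifest carries an explicit
#' `effect_is_minor` flag rather than inferring orientation from frequency.
#'
#' @param rsid character vector of SNP identifiers.
#' @param chrom chromosome labels (recycled if length 1).
#' @param position integer base-pair positions, strictly increasing.
#' @param effect_allele,other_allele single-character bases.
#' @param maf minor allele frequencies in (0, 0.5].
#' @param effect_is_minor logical; is the effect allele the minor allele?
#' @return A `snp_manifest` tibble with one row per SNP and an `eaf` column
#'   (effect-allele frequency, `maf` or `1 - maf` according to orientation).
#' @export
snp_manifest <- function(rsid, chrom, position, effect_allele, other_allele,
                         maf, effect_is_minor) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(rsid))
  stopifnot(
    length(rsid) >= 1L,
    !anyDuplicated(rsid),
    length(position) == length(rsid),
    all(maf > 0), all(maf <= 0.5),
    all(nchar(effect_allele) == 1L), all(nchar(other_allele) == 1L),
    all(effect_allele != other_allele)
  )
  if (is.unsorted(position, strictly = TRUE))
    stop("manifest positions must be strictly increasing")
  out <- tibble::tibble(
    rsid = as.character(rsid),
    chrom = as.character(chrom),
    position = as.integer(position),
    effect_allele = as.character(effect_allele),
    other_allele = as.character(other_allele),
    maf = as.numeric(maf),
    effect_is_minor = as.logical(effect_is_minor)
  )
  out$eaf <- ifelse(out$effect_is_minor, out$maf, 1 - out$maf)
  class(out) <- c("snp_manifest", class(out))
  out
}

#' Manifest of the 18 genotyped SNPs in the CHRNA5-CHRNA3-CHRNB4 region
#'
#' The directly genotyped common SNPs (MAF > 5%) covering the nicotinic
#' receptor subunit cluster at 15q25 and its flanks, with the
#' smoking-increasing allele as effect allele. Positions are NCBI build 35.
#'
#' @return A [snp_manifest()] with 18 rows.
#' @export
chrna_manifest <- function() {
  snp_manifest(
    rsid = c("rs8034191", "rs3885951", "rs2036534", "rs6495306", "rs680244",
             "rs621849", "rs1051730", "rs6495309", "rs1948", "rs950776",
             "rs12594247", "rs12900519", "rs1996371", "rs6495314",
             "rs8032156", "rs8038920", "rs4887077", "rs11638372"),
    chrom = "15",
    position = c(76593078L, 76612972L, 76614003L, 76652948L, 76658343L,
                 76659916L, 76681394L, 76702300L, 76704454L, 76713073L,
                 76733688L, 76736182L, 76743861L, 76747584L, 76751553L,
                 76761600L, 76765419L, 76770614L),
    effect_allele = c("G", "G", "A", "A", "G", "A", "A", "G", "G", "A",
                      "A", "A", "G", "C", "G", "G", "A", "A"),
    other_allele = c("A", "A", "G", "G", "A", "G", "G", "A", "A", "G",
                     "G", "G", "A", "A", "A", "A", "G", "G"),
    maf = c(0.33, 0.06, 0.28, 0.38, 0.38, 0.38, 0.32, 0.27, 0.34, 0.33,
            0.21, 0.14, 0.35, 0.35, 0.30, 0.27, 0.33, 0.33),
    effect_is_minor = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                        FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
                        TRUE, TRUE)
  )
}

#' Default haplotype-block definitions for the 15q25 panel
#'
#' Haplotype blocks are an input to the sliding-window analysis, not detected
#' automatically. These defaults group the strongly inter-correlated SNPs of
#' the CHRNA5/CHRNA3 core (panel indices 4-10) and the CHRNB4 5' flank
#' (indices 13-18).
#'
#' @return data frame with columns `name`, `start`, `end` (1-based SNP
#'   indices into the manifest, inclusive).
#' @export
default_blocks <- function() {
  data.frame(
    name = c("block1", "block2"),
    start = c(4L, 13L),
    end = c(10L, 18L),
    stringsAsFactors = FALSE
  )
}

#' Published strata characteristics for the reference cohort
#'
#' Gender-by-smoking-category counts and outcome summaries of the Finnish
#' birth-cohort sample the regional analysis was reported on (N = 5402
#' genotyped; 4996 with smoking data). Bundled as reference input for the
#' strata-arithmetic worked example and for parameterizing the synthetic
#' cohort generator.
#'
#' @return tibble with per-gender, per-category counts and means/SDs of BMI
#'   (kg/m^2), SBP and DBP (mmHg).
#' @export
reference_strata_counts <- function() {
  tibble::tibble(
    sex = rep(c("male", "female"), each = 3L),
    smoking = rep(c("non", "light", "heavy"), 2L),
    n = c(1219L, 431L, 726L, 1679L, 626L, 315L),
    bmi_mean = c(25.2, 25.0, 25.3, 24.0, 24.5, 24.5),
    bmi_sd = c(3.5, 3.6, 3.8, 4.5, 5.0, 5.6),
    sbp_mean = c(131.1, 129.9, 129.8, 120.8, 119.3, 118.6),
    sbp_sd = c(13.2, 12.5, 13.3, 12.7, 12.3, 13.2),
    dbp_mean = c(81.1, 80.2, 79.7, 75.4, 73.6, 73.4),
    dbp_sd = c(11.8, 11.2, 11.5, 10.8, 11.2, 11.6)
  )
}

#' Published per-SNP association estimates for the 15q25 region
#'
#' The reported stratified additive-model estimates (beta and 95% CI per
#' effect-allele copy, by smoking status) and interaction p-values for the
#' 18-SNP panel, for one outcome. These printed estimates are inputs to the
#' pooled-effect worked example ([average_effect()]); they are not computed
#' by this package.
#'
#' @param outcome one of "sbp", "dbp", "bmi".
#' @return tibble with columns `rsid`, `beta_non`, `ci_low_non`,
#'   `ci_high_non`, `beta_smk`, `ci_low_smk`, `ci_high_smk`, `p_interaction`,
#'   `p_adjusted`.
#' @export
reference_betas <- function(outcome = c("sbp", "dbp", "bmi")) {
  outcome <- match.arg(outcome)
  rsid <- chrna_manifest()$rsid
  tab <- switch(outcome,
    sbp = list(
      beta_non    = c(-0.07, 0.37, -0.03, -0.13, -0.13, -0.14, -0.13, 0.08,
                      -0.15, -0.12, 0.02, -0.49, -0.30, -0.37, 0.29, -0.28,
                      -0.33, -0.29),
      ci_low_non  = c(-0.76, -1.01, -0.75, -0.80, -0.80, -0.81, -0.83, -0.65,
                      -0.82, -0.80, -0.80, -1.40, -0.99, -1.07, -0.42, -1.01,
                      -1.04, -1.00),
      ci_high_non = c(0.62, 1.74, 0.69, 0.54, 0.54, 0.53, 0.57, 0.80, 0.52,
                      0.57, 0.83, 0.42, 0.40, 0.32, 1.00, 0.45, 0.37, 0.41),
      beta_smk    = c(-0.21, -0.43, 0.43, -0.58, -0.56, -0.57, -0.60, 0.18,
                      -1.24, -1.17, -0.56, -0.49, -0.23, -0.25, 0.11, -0.52,
                      -0.17, -0.17),
      ci_low_smk  = c(-0.99, -1.93, -0.40, -1.34, -1.32, -1.33, -1.38, -0.66,
                      -2.03, -1.97, -1.47, -1.57, -1.00, -1.02, -0.69, -1.36,
                      -0.96, -0.95),
      ci_high_smk = c(0.56, 1.07, 1.25, 0.18, 0.20, 0.19, 0.18, 1.02, -0.45,
                      -0.37, 0.35, 0.59, 0.55, 0.52, 0.91, 0.32, 0.61, 0.62),
      p_interaction = c(0.71, 0.40, 0.45, 0.36, 0.38, 0.38, 0.31, 0.90, 0.04,
                        0.04, 0.34, 0.98, 0.98, 0.90, 0.75, 0.57, 0.86, 0.91),
      p_adjusted  = c(1.00, 1.00, 1.00, 0.99, 0.99, 0.99, 0.99, 1.00, 0.49,
                      0.55, 0.99, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00)
    ),
    dbp = list(
      beta_non    = c(0.08, 0.12, 0.43, -0.34, -0.35, -0.37, 0.07, 0.36,
                      -0.27, -0.37, -0.23, -0.08, -0.24, -0.28, -0.15, -0.50,
                      -0.29, -0.29),
      ci_low_non  = c(-0.52, -1.07, -0.20, -0.92, -0.93, -0.95, -0.54, -0.27,
                      -0.85, -0.96, -0.93, -0.87, -0.84, -0.88, -0.76, -1.13,
                      -0.90, -0.90),
      ci_high_non = c(0.68, 1.31, 1.06, 0.24, 0.23, 0.21, 0.67, 1.00, 0.32,
                      0.23, 0.47, 0.71, 0.37, 0.32, 0.47, 0.14, 0.31, 0.32),
      beta_smk    = c(-0.14, 0.14, -0.12, -0.09, -0.08, -0.09, -0.27, -0.39,
                      -0.09, -0.14, -0.24, 0.58, -0.02, -0.04, -0.57, -0.73,
                      -0.04, -0.05),
      ci_low_smk  = c(-0.83, -1.18, -0.85, -0.76, -0.74, -0.76, -0.96, -1.13,
                      -0.78, -0.84, -1.04, -0.37, -0.70, -0.72, -1.27, -1.47,
                      -0.73, -0.74),
      ci_high_smk = c(0.54, 1.46, 0.60, 0.58, 0.59, 0.58, 0.42, 0.34, 0.61,
                      0.57, 0.56, 1.53, 0.66, 0.65, 0.13, 0.01, 0.65, 0.65),
      p_interaction = c(0.58, 0.98, 0.24, 0.60, 0.57, 0.57, 0.41, 0.12, 0.74,
                        0.66, 0.98, 0.35, 0.72, 0.68, 0.43, 0.62, 0.67, 0.69),
      p_adjusted  = c(1.00, 1.00, 0.99, 1.00, 1.00, 1.00, 0.99, 0.89, 1.00,
                      1.00, 1.00, 0.99, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00)
    ),
    bmi = list(
      beta_non    = c(0.02, -0.09, 0.00, 0.04, 0.04, 0.04, 0.03, -0.03,
                      0.01, -0.01, 0.04, -0.19, -0.02, -0.02, 0.03, 0.08,
                      -0.06, -0.07),
      ci_low_non  = c(-0.21, -0.55, -0.24, -0.19, -0.18, -0.18, -0.20, -0.27,
                      -0.22, -0.24, -0.23, -0.49, -0.25, -0.25, -0.21, -0.17,
                      -0.30, -0.30),
      ci_high_non = c(0.26, 0.37, 0.24, 0.26, 0.27, 0.26, 0.27, 0.21, 0.23,
                      0.21, 0.31, 0.11, 0.21, 0.22, 0.27, 0.32, 0.17, 0.17),
      beta_smk    = c(-0.26, 0.09, -0.35, 0.07, 0.07, 0.07, -0.24, -0.44,
                      -0.02, 0.02, 0.24, 0.11, -0.41, -0.41, 0.15, -0.22,
                      -0.33, -0.34),
      ci_low_smk  = c(-0.54, -0.46, -0.65, -0.21, -0.21, -0.21, -0.53, -0.75,
                      -0.31, -0.28, -0.10, -0.28, -0.70, -0.69, -0.15, -0.53,
                      -0.62, -0.62),
      ci_high_smk = c(0.03, 0.64, -0.05, 0.35, 0.35, 0.35, 0.04, -0.14,
                      0.27, 0.31, 0.57, 0.51, -0.13, -0.12, 0.45, 0.09,
                      -0.05, -0.05),
      p_interaction = c(0.14, 0.57, 0.08, 0.81, 0.84, 0.84, 0.17, 0.03, 0.97,
                        0.83, 0.38, 0.17, 0.05, 0.05, 0.64, 0.11, 0.19, 0.19),
      p_adjusted  = c(0.94, 1.00, 0.79, 1.00, 1.00, 1.00, 0.96, 0.46, 1.00,
                      1.00, 0.99, 0.96, 0.57, 0.57, 1.00, 0.89, 0.97, 0.97)
    )
  )
  tibble::as_tibble(c(list(rsid = rsid), tab))
}
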