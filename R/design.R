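#' Maximum attainable r-squared between two biallelic loci
#'
#' For allele frequencies pa, pb the disequilibrium coefficient D is bounded
#' by the haplotype-frequency non-negativity constraints, which caps the
#' attainable correlation. For positive association the cap is
#' min(pa(1-pb), (1-pa)pb); r2max is that bound squared over the product of
#' the allele variances.
#'
#' @param pa,pb allele frequencies in (0, 1).
#' @return attainable upper bound on r^2 in [0, 1].
#' @export
max_attainable_r2 <- function(pa, pb) {
  stopifnot(all(pa > 0 & pa < 1), all(pb > 0 & pb < 1))
  d_max <- pmin(pa * (1 - pb), (1 - pa) * pb)
  (d_max^2) / (pa * (1 - pa) * pb * (1 - pb))
}

.default_pheno_params <- function() {
  # Intercepts are the female non-smoker stratum means of the reference
  # cohort; sex effects the male-female non-smoker differences; noise SDs
  # close to the pooled within-stratum SDs. exposure_effect is the smoker
  # main effect (smokers run slightly lower in BP, marginally higher BMI).
  list(
    bmi = list(intercept = 24.0, sex_effect = 1.2, sd = 4.2,
               exposure_effect = 0.3),
    sbp = list(intercept = 120.8, sex_effect = 10.3, sd = 13.0,
               exposure_effect = -1.4),
    dbp = list(intercept = 75.4, sex_effect = 5.7, sd = 11.3,
               exposure_effect = -1.5)
  )
}

.zero_betas <- function(manifest) {
  m <- matrix(0, nrow(manifest), 3,
              dimnames = list(manifest$rsid, c("bmi", "sbp", "dbp")))
  m
}

.as_beta_matrix <- function(beta, manifest, what) {
  out <- .zero_betas(manifest)
  if (is.null(beta)) return(out)
  if (is.matrix(beta)) {
    stopifnot(nrow(beta) == nrow(manifest))
    cols <- intersect(colnames(beta), colnames(out))
    out[, cols] <- beta[, cols]
    return(out)
  }
  # named list of outcome -> named numeric vector of per-SNP effects
  stopifnot(is.list(beta))
  for (oc in names(beta)) {
    if (!oc %in% colnames(out)) stop(what, ": unknown outcome '", oc, "'")
    v <- beta[[oc]]
    if (is.null(names(v))) stop(what, ": per-SNP effects must be named by rsid")
    bad <- setdiff(names(v), manifest$rsid)
    if (length(bad)) stop(what, ": unknown rsid ", bad[1])
    out[names(v), oc] <- v
  }
  out
}

#' Specify a synthetic cohort design
#'
#' The design encodes the study conditions the generator emulates: a regional
#' SNP panel with LD blocks, gender-specific smoking-category frequencies,
#' Gaussian outcome models with configurable per-allele main effects and
#' SNP-by-smoking interaction effects, an antihypertensive-medication
#' indicator, and optional two-subpopulation structure for stratification
#' experiments. Defaults reproduce the reference birth-cohort conditions:
#' N = 5402, the 18-SNP 15q25 manifest, two LD blocks, smoking-category
#' frequencies and outcome means/SDs from the reference strata table.
#'
#' @param n_individuals cohort size.
#' @param manifest a [snp_manifest()].
#' @param ld_blocks data frame with `name`, `start`, `end` and optionally
#'   `r2` (target adjacent-pair haplotype r^2 within the block). When `r2`
#'   is absent it defaults per block to 0.9 times the smallest attainable
#'   bound over the block's adjacent frequency pairs, so the default panel
#'   always has valid within-block LD.
#' @param smoking_probs list with `male` and `female` probability vectors
#'   over categories (non, light, heavy); each must sum to 1.
#' @param pheno_params per-outcome list of `intercept`, `sex_effect`
#'   (added for males), `sd` (residual SD, > 0), `exposure_effect` (smoker
#'   main effect).
#' @param beta_main,beta_gxe per-SNP per-outcome effects per effect-allele
#'   copy: either an M x 3 matrix (columns bmi, sbp, dbp) or a named list
#'   like `list(sbp = c(rs1948 = -1.24))`. `beta_gxe` applies only in
#'   smokers (the exposure indicator).
#' @param bmi_on_bp coefficient of (BMI - 24) on SBP and DBP; 0 keeps BMI an
#'   independent covariate.
#' @param medication_prob probability of the antihypertensive-medication
#'   flag (default 95/5402 as in the reference cohort).
#' @param former_frac fraction of non-smokers who are former (vs never)
#'   smokers.
#' @param p_male probability of male sex (default 2592/5402).
#' @param missing_rate per-call genotype missingness (default 0.005,
#'   matching the per-SNP varying complete-case counts of the reference
#'   tables).
#' @param n_subpops 1 or 2; with 2, effect-allele frequencies are shifted by
#'   +/- `subpop_maf_shift`/2 in the two halves.
#' @param subpop_maf_shift frequency shift between subpopulations.
#' @param seed integer seed stored with the design.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_individuals = 5402L,
                          manifest = chrna_manifest(),
                          ld_blocks = default_blocks(),
                          smoking_probs = list(
                            male = c(non = 0.513, light = 0.181, heavy = 0.306),
                            female = c(non = 0.641, light = 0.239, heavy = 0.120)
                          ),
                          pheno_params = .default_pheno_params(),
                          beta_main = NULL,
                          beta_gxe = NULL,
                          bmi_on_bp = 0,
                          medication_prob = 95 / 5402,
                          former_frac = 0.3,
                          p_male = 2592 / 5402,
                          missing_rate = 0.005,
                          n_subpops = 1L,
                          subpop_maf_shift = 0,
                          seed = 1L) {
  stopifnot(n_individuals >= 1, inherits(manifest, "snp_manifest"),
            n_subpops >= 1L, missing_rate >= 0, missing_rate < 1,
            medication_prob >= 0, medication_prob <= 1)
  for (sx in c("male", "female")) {
    p <- smoking_probs[[sx]]
    stopifnot(length(p) == 3L, all(p >= 0))
    if (abs(sum(p) - 1) > 1e-8)
      stop("smoking_probs$", sx, " must sum to 1")
    smoking_probs[[sx]] <- p / sum(p)
  }
  for (oc in c("bmi", "sbp", "dbp")) {
    pp <- pheno_params[[oc]]
    if (is.null(pp)) stop("pheno_params missing outcome '", oc, "'")
    if (is.null(pp$exposure_effect)) pheno_params[[oc]]$exposure_effect <- 0
    stopifnot(pp$sd >= 0) # 0 allowed: the deterministic limit
  }
  ld_blocks <- as.data.frame(ld_blocks)
  if (nrow(ld_blocks)) {
    stopifnot(all(ld_blocks$start >= 1), all(ld_blocks$end <= nrow(manifest)),
              all(ld_blocks$start <= ld_blocks$end))
    o <- order(ld_blocks$start)
    ld_blocks <- ld_blocks[o, , drop = FALSE]
    if (nrow(ld_blocks) > 1 &&
        any(ld_blocks$start[-1] <= ld_blocks$end[-nrow(ld_blocks)]))
      stop("ld_blocks must not overlap")
    if (is.null(ld_blocks$r2)) {
      ld_blocks$r2 <- vapply(seq_len(nrow(ld_blocks)), function(i) {
        idx <- ld_blocks$start[i]:ld_blocks$end[i]
        if (length(idx) < 2) return(0)
        p <- manifest$eaf[idx]
        0.9 * min(max_attainable_r2(p[-length(p)], p[-1]))
      }, numeric(1))
    }
    # reject unattainable targets up front, naming the bound
    for (i in seq_len(nrow(ld_blocks))) {
      idx <- ld_blocks$start[i]:ld_blocks$end[i]
      if (length(idx) < 2) next
      p <- manifest$eaf[idx]
      bound <- min(max_attainable_r2(p[-length(p)], p[-1]))
      if (ld_blocks$r2[i] > bound + 1e-12)
        stop(sprintf(
          "ld_blocks[%d]: target r2 %.3f exceeds the attainable bound %.3f for the block's allele frequencies",
          i, ld_blocks$r2[i], bound))
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    manifest = manifest,
    ld_blocks = ld_blocks,
    smoking_probs = smoking_probs,
    pheno_params = pheno_params,
    beta_main = .as_beta_matrix(beta_main, manifest, "beta_main"),
    beta_gxe = .as_beta_matrix(beta_gxe, manifest, "beta_gxe"),
    bmi_on_bp = bmi_on_bp,
    medication_prob = medication_prob,
    former_frac = former_frac,
    p_male = p_male,
    missing_rate = missing_rate,
    n_subpops = as.integer(n_subpops),
    subpop_maf_shift = subpop_maf_shift,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("cohort_design: N =", x$n_individuals, "|", nrow(x$manifest), "SNPs |",
      nrow(x$ld_blocks), "LD block(s) | seed", x$seed, "\n")
  invisible(x)
}

#' Write / read a cohort design as YAML
#'
#' Serialises the scalar fields, block table, smoking probabilities and any
#' nonzero planted effects; the manifest is written in full so a design file
#' is self-contained.
#'
#' @param design a [cohort_design()].
#' @param path file path.
#' @return `read_design_yaml` returns a `cohort_design`.
#' @export
write_design_yaml <- function(design, path) {
  x <- unclass(design)
  x$manifest <- lapply(seq_len(nrow(design$manifest)), function(i)
    as.list(design$manifest[i, setdiff(names(design$manifest), "eaf")]))
  x$ld_blocks <- lapply(seq_len(nrow(design$ld_blocks)), function(i)
    as.list(design$ld_blocks[i, ]))
  x$beta_main <- .beta_matrix_to_list(design$beta_main)
  x$beta_gxe <- .beta_matrix_to_list(design$beta_gxe)
  x$smoking_probs <- lapply(design$smoking_probs, as.list)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

.beta_matrix_to_list <- function(m) {
  out <- list()
  for (oc in colnames(m)) {
    v <- m[, oc] # named column keeps rsid names even for one entry
    if (any(v != 0)) out[[oc]] <- as.list(v[v != 0])
  }
  out
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  man <- do.call(rbind, lapply(x$manifest, as.data.frame))
  manifest <- snp_manifest(man$rsid, man$chrom, man$position,
                           man$effect_allele, man$other_allele, man$maf,
                           man$effect_is_minor)
  blocks <- do.call(rbind, lapply(x$ld_blocks, as.data.frame))
  beta_l <- function(b) if (length(b)) lapply(b, unlist) else NULL
  cohort_design(
    n_individuals = x$n_individuals, manifest = manifest, ld_blocks = blocks,
    smoking_probs = lapply(x$smoking_probs, unlist),
    pheno_params = x$pheno_params,
    beta_main = beta_l(x$beta_main), beta_gxe = beta_l(x$beta_gxe),
    bmi_on_bp = x$bmi_on_bp, medication_prob = x$medication_prob,
    former_frac = x$former_frac, p_male = x$p_male,
    missing_rate = x$missing_rate, n_subpops = x$n_subpops,
    subpop_maf_shift = x$subpop_maf_shift, seed = x$seed
  )
}
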