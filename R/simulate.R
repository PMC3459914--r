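#' Simulate block-correlated genotypes
#'
#' Haplotypes are generated chromosome-by-chromosome with a first-order
#' chain along each LD block: for each adjacent SNP pair the disequilibrium
#' coefficient D is chosen to hit the block's target haplotype r^2 exactly
#' (D = r * sqrt(pa qa pb qb)), the next allele is drawn from the implied
#' conditional distribution, and dosage is the sum of the individual's two
#' haplotypes. SNPs outside any block, and SNPs in different blocks, are
#' independent. With two subpopulations the effect-allele frequencies are
#' shifted by +/- `subpop_maf_shift`/2 in the two halves of the cohort.
#'
#' Targets above the attainable r^2 bound for a frequency pair are rejected
#' at design construction ([cohort_design()]) with the bound in the message.
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed; defaults to the design's seed.
#' @return A [genotype_matrix()] with per-call missingness injected at the
#'   design's `missing_rate`. The pre-missingness dosages are kept in the
#'   `complete_dosage` attribute (the phenotype model uses them as the true
#'   genotypes), the realized chromosomes in `haplotypes` (2N x M; rows
#'   2i-1 and 2i belong to individual i — the ground truth for LD checks),
#'   and subpopulation labels in `subpop`.
#' @export
simulate_genotypes <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  n <- design$n_individuals
  man <- design$manifest
  m <- nrow(man)
  subpop <- rep_len(seq_len(design$n_subpops), n)

  in_block <- integer(m) # 0 = no block
  for (i in seq_len(nrow(design$ld_blocks)))
    in_block[design$ld_blocks$start[i]:design$ld_blocks$end[i]] <- i

  dosage <- matrix(0L, n, m)
  hap_all <- matrix(0L, 2L * n, m) # rows 2i-1, 2i: individual i's chromosomes
  for (s in seq_len(design$n_subpops)) {
    rows <- which(subpop == s)
    if (!length(rows)) next
    shift <- if (design$n_subpops > 1)
      design$subpop_maf_shift * (s - (design$n_subpops + 1) / 2) else 0
    p <- pmin(pmax(man$eaf + shift, 0.02), 0.98)
    nh <- 2L * length(rows)
    hap <- matrix(0L, nh, m)
    j <- 1L
    while (j <= m) {
      b <- in_block[j]
      if (b == 0L) {
        hap[, j] <- rbinom(nh, 1L, p[j])
        j <- j + 1L
      } else {
        idx <- design$ld_blocks$start[b]:design$ld_blocks$end[b]
        r <- sqrt(design$ld_blocks$r2[b])
        hap[, idx[1]] <- rbinom(nh, 1L, p[idx[1]])
        for (k in seq_along(idx)[-1]) {
          pa <- p[idx[k - 1]]; pb <- p[idx[k]]
          D <- r * sqrt(pa * (1 - pa) * pb * (1 - pb))
          p1 <- (pa * pb + D) / pa          # P(next=1 | prev=1)
          p0 <- (pb * (1 - pa) - D) / (1 - pa)
          prev <- hap[, idx[k - 1]]
          hap[, idx[k]] <- rbinom(nh, 1L, ifelse(prev == 1L, p1, p0))
        }
        j <- idx[length(idx)] + 1L
      }
    }
    h1 <- hap[seq_len(length(rows)), , drop = FALSE]
    h2 <- hap[length(rows) + seq_len(length(rows)), , drop = FALSE]
    dosage[rows, ] <- h1 + h2
    hap_all[2L * rows - 1L, ] <- h1
    hap_all[2L * rows, ] <- h2
  }

  complete <- dosage
  if (design$missing_rate > 0) {
    miss <- matrix(runif(n * m) < design$missing_rate, n, m)
    dosage[miss] <- NA_integer_
  }
  g <- genotype_matrix(sprintf("I%05d", seq_len(n)), man, dosage)
  attr(g, "complete_dosage") <- complete
  attr(g, "haplotypes") <- hap_all
  attr(g, "subpop") <- subpop
  g
}

#' Simulate phenotypes for a cohort
#'
#' Linear-Gaussian outcome model per individual i and outcome y:
#' y_i = intercept + sex_effect * male_i + exposure_effect * smoker_i
#'       + sum_j beta_main[j, y] g_ij + sum_j beta_gxe[j, y] g_ij smoker_i
#'       + bmi_on_bp * (BMI_i - 24) [SBP/DBP only] + N(0, sd_y),
#' with g the true (pre-missingness) effect-allele dosages. Smoking
#' categories are drawn per gender; non-smokers split into never/former;
#' cigarettes/day are uniform on 1-10 (light) and 11-40 (heavy). A
#' medication indicator is drawn independently, and recorded blood pressures
#' of medicated individuals are lowered by 15/10 mmHg (the treatment effect
#' the +15/+10 analysis correction undoes).
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param design the matching [cohort_design()].
#' @param seed RNG seed; defaults to the design seed + 1 (a distinct
#'   substream so genotypes and phenotypes can be regenerated independently).
#' @return tibble with columns `iid`, `sex`, `bmi`, `sbp`, `dbp`,
#'   `medication_ht`, `cigs_per_day`, `smoking_status`
#'   (never/former/current) and `subpop`.
#' @export
simulate_phenotypes <- function(g, design, seed = design$seed + 1L) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(design, "cohort_design"))
  G <- attr(g, "complete_dosage")
  if (is.null(G)) {
    G <- g$dosage
    G[is.na(G)] <- 0L
  }
  n <- nrow(G)
  stopifnot(n == design$n_individuals)
  set.seed(seed)

  male <- rbinom(n, 1L, design$p_male)
  sex <- ifelse(male == 1L, "male", "female")
  cat3 <- character(n)
  for (sx in c("male", "female")) {
    rows <- which(sex == sx)
    cat3[rows] <- sample(c("non", "light", "heavy"), length(rows),
                         replace = TRUE, prob = design$smoking_probs[[sx]])
  }
  smoker <- as.integer(cat3 != "non")
  status <- ifelse(cat3 == "non",
                   ifelse(runif(n) < design$former_frac, "former", "never"),
                   "current")
  cigs <- integer(n)
  cigs[cat3 == "light"] <- sample(1:10, sum(cat3 == "light"), replace = TRUE)
  cigs[cat3 == "heavy"] <- sample(11:40, sum(cat3 == "heavy"), replace = TRUE)
  medication <- runif(n) < design$medication_prob

  draw <- function(outcome, extra = 0) {
    pp <- design$pheno_params[[outcome]]
    pp$intercept + pp$sex_effect * male + pp$exposure_effect * smoker +
      as.numeric(G %*% design$beta_main[, outcome]) +
      as.numeric(G %*% design$beta_gxe[, outcome]) * smoker +
      extra + rnorm(n, 0, pp$sd)
  }
  bmi <- draw("bmi")
  bp_extra <- design$bmi_on_bp * (bmi - 24)
  sbp <- draw("sbp", bp_extra)
  dbp <- draw("dbp", bp_extra)
  # recorded values: treated individuals present lower pressures
  sbp[medication] <- sbp[medication] - 15
  dbp[medication] <- dbp[medication] - 10

  tibble::tibble(
    iid = g$individual_ids,
    sex = sex,
    bmi = bmi,
    sbp = sbp,
    dbp = dbp,
    medication_ht = medication,
    cigs_per_day = cigs,
    smoking_status = status,
    subpop = attr(g, "subpop") %||% rep(1L, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full synthetic cohort
#'
#' Genotypes then phenotypes under one design; the design (including the
#' planted effect matrices, the ground truth) travels with the result.
#'
#' @param design a [cohort_design()].
#' @return A `synthetic_cohort` list with elements `genotypes`,
#'   `phenotypes`, `design`.
#' @export
simulate_cohort <- function(design = cohort_design()) {
  g <- simulate_genotypes(design)
  ph <- simulate_phenotypes(g, design)
  structure(list(genotypes = g, phenotypes = ph, design = design),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  print(x$genotypes)
  cat("phenotypes:", nrow(x$phenotypes), "rows; planted effects:",
      sum(x$design$beta_main != 0), "main,",
      sum(x$design$beta_gxe != 0), "GxE\n")
  invisible(x)
}
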