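make_pheno <- function(sbp = c(130, 120), dbp = c(85, 70),
                       med = c(TRUE, FALSE)) {
  tibble::tibble(iid = paste0("I", seq_along(sbp)),
                 sex = rep("male", length(sbp)), bmi = 25,
                 sbp = sbp, dbp = dbp, medication_ht = med,
                 cigs_per_day = 0L, smoking_status = "never")
}

test_that("medication correction adds 15/10 mmHg, once, to flagged rows", {
  ph <- make_pheno()
  out <- adjust_bp_for_medication(ph)
  expect_equal(out$sbp, c(145, 120))
  expect_equal(out$dbp, c(95, 70))
  # idempotent via done-flag
  expect_equal(adjust_bp_for_medication(out)$sbp, c(145, 120))
  # missing SBP stays missing, DBP still adjusted
  ph2 <- make_pheno(sbp = c(NA, 120))
  out2 <- adjust_bp_for_medication(ph2)
  expect_true(is.na(out2$sbp[1]))
  expect_equal(out2$dbp[1], 95)
})

test_that("smoking exposure coding honours the category boundaries", {
  ph <- tibble::tibble(
    iid = paste0("I", 1:5), sex = "female", bmi = 24, sbp = 120, dbp = 75,
    medication_ht = FALSE,
    cigs_per_day = c(10L, 11L, 0L, 0L, 0L),
    smoking_status = c("current", "current", "former", "never", "current"))
  q <- code_smoking(ph, "three_level_quantity")
  expect_equal(as.character(q$values[1:4]),
               c("light", "heavy", "non", "non"))
  b <- code_smoking(ph, "binary_smoker")
  expect_equal(b$smoker_indicator[1:4], c(1L, 1L, 0L, 0L))
  # current smoker reporting 0/day is inconsistent: flagged, NA category
  expect_true(b$inconsistent[5])
  expect_true(is.na(b$values[5]))
  h <- code_smoking(ph, "three_level_history")
  expect_equal(as.character(h$values),
               c("current", "current", "former", "never", "current"))
})

test_that("common-SNP filter keeps the full reference panel and drops rare SNPs", {
  d <- cohort_design(n_individuals = 5402, seed = 16)
  g <- simulate_genotypes(d)
  kept <- filter_common_snps(g, 0.05)
  expect_equal(ncol(kept$dosage), 18L) # smallest design MAF is 0.06
  # injected rare and monomorphic SNPs are removed
  man3 <- snp_manifest(c("a", "b", "c"), "1", c(1L, 2L, 3L) * 100L,
                       rep("A", 3), rep("G", 3), c(0.3, 0.04, 0.01),
                       rep(TRUE, 3))
  dos <- cbind(rbinom(2000, 2, 0.3), rbinom(2000, 2, 0.04), 0L)
  gm <- genotype_matrix(paste0("I", 1:2000), man3, dos)
  kept2 <- filter_common_snps(gm, 0.05)
  expect_equal(kept2$manifest$rsid, "a")
  expect_error(filter_common_snps(subset_snps(gm, 3), 0.05), "no SNP passes")
})

test_that("HWE chi-square matches the closed form", {
  exact <- hwe_test(rep(c(0L, 1L, 2L), c(25, 50, 25)))
  expect_equal(exact$chisq, 0)
  expect_equal(exact$p_value, 1)
  mid <- hwe_test(rep(c(0L, 1L, 2L), c(30, 40, 30)))
  expect_equal(mid$chisq, 4.0, tolerance = 1e-12)
  expect_lt(hwe_test(rep(c(0L, 2L), c(50, 50)))$p_value, 0.005)
  expect_equal(hwe_test(rep(0L, 20))$p_value, 1) # monomorphic convention

  # exhaustive check against an independently coded formula, all tables n<=50
  oracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    p <- (n1 + 2 * n2) / (2 * n)
    if (p <= 0 || p >= 1) return(0)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum((c(n0, n1, n2) - e)^2 / e)
  }
  for (n in c(5L, 17L, 50L)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      got <- hwe_test(rep(c(0L, 1L, 2L), c(n0, n1, n2)))$chisq
      expect_equal(got, oracle(n0, n1, n2), tolerance = 1e-10)
    }
  }
})

test_that("composite r2 behaves at its edges and matches the haplotype oracle", {
  x <- rbinom(500, 2, 0.4)
  expect_equal(ld_r2(x, x), 1)
  set.seed(41)
  a <- rbinom(1e4, 2, 0.3); b <- rbinom(1e4, 2, 0.3)
  expect_lt(ld_r2(a, b), 0.01)
  expect_true(is.na(ld_r2(rep(1L, 10), rbinom(10, 2, 0.5))))
  d <- cohort_design(n_individuals = 2e4, manifest = two_snp_manifest(),
                     ld_blocks = data.frame(name = "b", start = 1, end = 2,
                                            r2 = 0.5),
                     missing_rate = 0, seed = 42)
  g <- simulate_genotypes(d)
  expect_lt(abs(ld_r2(g$dosage[, 1], g$dosage[, 2]) -
                  hap_r2_oracle(attr(g, "haplotypes"))), 0.05)
})

test_that("PC panel selection filters, prunes and thins as specified", {
  # 150 mutually independent SNPs all passing filters: 1-in-15 keeps 10
  d <- cohort_design(n_individuals = 1500, manifest = indep_manifest(150),
                     ld_blocks = data.frame(name = character(0),
                                            start = integer(0),
                                            end = integer(0)),
                     missing_rate = 0, seed = 17)
  g <- simulate_genotypes(d)
  panel <- select_pc_panel(g)
  expect_equal(ncol(panel$dosage), 10L)

  # duplicated SNP: the second copy is pruned at r2 = 1
  man2 <- indep_manifest(2)
  dos <- cbind(g$dosage[, 1], g$dosage[, 1])
  gd <- genotype_matrix(g$individual_ids, man2, dos)
  log <- attr(select_pc_panel(gd, thin_step = 1L), "qc_log")
  expect_equal(log$reason, c("kept", "ld_prune"))

  # a 5-SNP block at high r2 leaves exactly one survivor before thinning
  man15 <- indep_manifest(15)
  d3 <- cohort_design(n_individuals = 3000, manifest = man15,
                      ld_blocks = data.frame(name = "b", start = 1, end = 5,
                                             r2 = 0.9),
                      missing_rate = 0, seed = 18)
  g3 <- simulate_genotypes(d3)
  pruned <- select_pc_panel(g3, thin_step = 1L)
  expect_equal(ncol(pruned$dosage), 11L) # 1 from the block + 10 independent
})

test_that("principal components match a direct decomposition oracle", {
  d <- cohort_design(n_individuals = 300, manifest = indep_manifest(40),
                     ld_blocks = data.frame(name = character(0),
                                            start = integer(0),
                                            end = integer(0)),
                     missing_rate = 0, seed = 19)
  g <- simulate_genotypes(d)
  pcs <- compute_pcs(g, k = 3)
  expect_true(all(abs(colMeans(pcs$scores)) < 1e-8))
  expect_true(all(diff(pcs$eigenvalues) <= 1e-10))

  # oracle: eigendecomposition of the individual x individual covariance
  p <- colMeans(g$dosage) / 2
  Z <- sweep(sweep(g$dosage, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  Z <- sweep(Z, 2, colMeans(Z))
  ev <- eigen(tcrossprod(Z), symmetric = TRUE)
  for (k in 1:3) {
    sc_oracle <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_lt(min(max(abs(pcs$scores[, k] - sc_oracle)),
                  max(abs(pcs$scores[, k] + sc_oracle))), 1e-8)
  }

  # a single homogeneous population has no dominant component
  d2 <- cohort_design(n_individuals = 1000, manifest = indep_manifest(100),
                      ld_blocks = data.frame(name = character(0),
                                             start = integer(0),
                                             end = integer(0)),
                      missing_rate = 0, seed = 20)
  pcs2 <- compute_pcs(simulate_genotypes(d2), k = 3)
  expect_lt(pcs2$eigenvalues[1] / pcs2$eigenvalues[2], 2)
  expect_error(compute_pcs(simulate_genotypes(d), k = 60), "rank")
})
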