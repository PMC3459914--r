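test_that("sliding-window enumeration counts and orders correctly", {
  w3 <- sliding_windows(data.frame(name = "b", start = 4, end = 6))
  expect_equal(nrow(w3), 6L)
  expect_equal(w3$width, c(1, 1, 1, 2, 2, 3))
  expect_equal(w3$start[1:3], 4:6) # left to right within a width
  expect_equal(nrow(sliding_windows(data.frame(start = 4, end = 6),
                                    min_width = 2)), 3L)
  expect_equal(nrow(sliding_windows(data.frame(start = 1, end = 10))), 55L)
})

test_that("width-1 windows reduce to allele frequencies", {
  set.seed(80)
  G <- matrix(rbinom(500, 2, 0.35), ncol = 1)
  em <- em_haplotype_frequencies(G)
  p <- mean(G) / 2
  i1 <- which(em$hap_codes == 1L)
  expect_equal(em$frequencies[i1], p, tolerance = 1e-9)
  expect_equal(sum(em$frequencies), 1, tolerance = 1e-8)
})

test_that("phase-unambiguous data give direct counting frequencies", {
  # all individuals homozygous at locus 1: every diplotype is resolved
  set.seed(81)
  n <- 400
  g1 <- 2L * rbinom(n, 1, 0.6)
  g2 <- rbinom(n, 2, 0.4)
  em <- em_haplotype_frequencies(cbind(g1, g2))
  # direct chromosome counts: locus1 allele = g1/2 on both chromosomes
  counts <- c(`0` = 0, `1` = 0, `2` = 0, `3` = 0)
  for (i in 1:n) {
    a1 <- g1[i] / 2
    pair <- if (g2[i] == 1) c(0, 1) else c(g2[i] / 2, g2[i] / 2)
    for (b in pair) counts[as.character(a1 + 2 * b)] <-
        counts[as.character(a1 + 2 * b)] + 1
  }
  counts <- counts / (2 * n)
  got <- setNames(rep(0, 4), as.character(0:3))
  got[as.character(em$hap_codes)] <- em$frequencies
  expect_equal(unname(got), unname(counts), tolerance = 1e-6)
})

test_that("EM matches truth and the likelihood grid-search oracle", {
  truth <- c(0.5, 0.3, 0.15, 0.05) # haplotypes 11, 10, 01, 00
  G <- draw_2snp_genotypes(5000, truth, seed = 82)
  em <- em_haplotype_frequencies(G, tol = 1e-9)
  expect_true(em$converged)
  # bit code = snp1 + 2*snp2, so truth order (11, 10, 01, 00) = codes 3,1,2,0
  v <- setNames(rep(0, 4), as.character(0:3))
  v[as.character(em$hap_codes)] <- em$frequencies
  f_em <- unname(v[as.character(c(3, 1, 2, 0))])
  expect_lt(max(abs(f_em - truth)), 0.02)
  oracle <- grid_search_hapfreq(G)
  expect_lt(max(abs(f_em - oracle)), 1e-4)
})

test_that("expected dosages resolve double heterozygotes by posterior odds", {
  truth <- c(0.5, 0.3, 0.15, 0.05)
  G <- draw_2snp_genotypes(3000, truth, seed = 83)
  em <- em_haplotype_frequencies(G, tol = 1e-9)
  ed <- expected_dosages(G, em$hap_codes, em$frequencies)
  expect_true(all(abs(rowSums(ed) - 2) < 1e-8))
  # unambiguous double homozygote: integer dosages
  i_hom <- which(G[, 1] == 2 & G[, 2] == 2)[1]
  expect_true(all(ed[i_hom, ] %in% c(0, 2)))
  # double heterozygote splits cis/trans as f(AB)f(ab) : f(Ab)f(aB)
  i_het <- which(G[, 1] == 1 & G[, 2] == 1)[1]
  f <- setNames(rep(0, 4), as.character(0:3))
  f[as.character(em$hap_codes)] <- em$frequencies
  w_cis <- f["3"] * f["0"]
  w_trans <- f["1"] * f["2"]
  post_cis <- w_cis / (w_cis + w_trans)
  expect_equal(unname(ed[i_het, match(3L, em$hap_codes)]), unname(post_cis),
               tolerance = 1e-8)
  expect_equal(unname(ed[i_het, match(1L, em$hap_codes)]),
               unname(1 - post_cis), tolerance = 1e-8)
})

test_that("missing genotypes exclude individuals from that window only", {
  truth <- c(0.4, 0.3, 0.2, 0.1)
  G <- draw_2snp_genotypes(600, truth, seed = 84)
  G[1:15, 1] <- NA
  em <- em_haplotype_frequencies(G)
  expect_equal(em$n_used, 585L)
  ed <- expected_dosages(G, em$hap_codes, em$frequencies)
  expect_true(all(is.na(ed[1:15, ])))
  expect_true(all(!is.na(ed[16:600, ])))
})

test_that("one-SNP haplotype association equals the single-marker fit", {
  d <- cohort_design(n_individuals = 1000, seed = 85, missing_rate = 0.005)
  co <- simulate_cohort(d)
  sm <- code_smoking(co$phenotypes, "binary_smoker")
  cov <- default_covariates(co$phenotypes, NULL, "sbp")
  win <- phase_window(co$genotypes, 9, 9) # rs1948 alone
  smokers <- which(!is.na(sm$values) & sm$values == "smoker")
  ha <- haplotype_association(win, co$phenotypes, "sbp", smokers, cov)
  eff <- which(win$hap_codes == 1L)
  hb <- ha$results$beta[match(win$haplotypes[eff], ha$results$haplotype)]
  rs <- run_stratified(co$genotypes, co$phenotypes, "sbp", sm$values, cov)
  sb <- rs$beta[rs$rsid == "rs1948" & rs$stratum == "smoker"]
  expect_lt(abs(hb - sb), 1e-10)
})

test_that("rare haplotypes are excluded from testing but kept in the model", {
  truth <- c(0.6, 0.3, 0.091, 0.009)
  G <- draw_2snp_genotypes(20000, truth, seed = 86)
  em <- em_haplotype_frequencies(G)
  man <- two_snp_manifest()
  gm <- genotype_matrix(paste0("I", 1:20000), man, G)
  win <- phase_window(gm, 1, 2)
  expect_equal(length(win$frequencies), 4L) # EM keeps every haplotype
  ph <- tibble::tibble(iid = gm$individual_ids, sex = "male", bmi = 25,
                       sbp = rnorm(20000, 120, 10), dbp = 75,
                       medication_ht = FALSE, cigs_per_day = 0L,
                       smoking_status = "never")
  ha <- haplotype_association(win, ph, "sbp")
  expect_lt(nrow(ha$results), 4L) # the ~0.9% haplotype is not tested
  expect_true(all(ha$results$frequency > 0.01))
})

test_that("planted haplotype effects are recovered in the right stratum", {
  set.seed(87)
  seeds <- sample.int(1e6, 30)
  est <- t(vapply(seeds, function(s) {
    d <- cohort_design(n_individuals = 2500, seed = s,
                       beta_gxe = list(sbp = c(rs1948 = -1.0,
                                               rs950776 = -1.0)))
    co <- simulate_cohort(d)
    sm <- code_smoking(co$phenotypes, "binary_smoker")
    cov <- default_covariates(co$phenotypes, NULL, "sbp")
    win <- phase_window(co$genotypes, 9, 10)
    h_eff <- which(win$hap_codes == 3L) # effect alleles at both SNPs
    res <- vapply(c("smoker", "non"), function(lv) {
      rows <- which(!is.na(sm$values) & sm$values == lv)
      ha <- haplotype_association(win, co$phenotypes, "sbp", rows, cov)
      ha$results$beta[match(win$haplotypes[h_eff], ha$results$haplotype)]
    }, numeric(1))
    res
  }, numeric(2)))
  # expected marginal slope for the both-effect-alleles haplotype: with
  # per-chromosome effect-allele frequencies pA, pB and haplotype frequency
  # f3 = pA pB + D, regressing on that haplotype's dosage alone gives
  # (bA (1 - pA) + bB (1 - pB)) / (1 - f3)
  man <- chrna_manifest()
  pA <- man$eaf[9]; pB <- man$eaf[10]
  r <- sqrt(cohort_design()$ld_blocks$r2[1])
  f3 <- pA * pB + r * sqrt(pA * (1 - pA) * pB * (1 - pB))
  slope <- (-1 * (1 - pA) + -1 * (1 - pB)) / (1 - f3)
  expect_lt(abs(mean(est[, 1]) - slope), 3 * sd(est[, 1]) / sqrt(30) + 0.1)
  expect_lt(abs(mean(est[, 2])), 3 * sd(est[, 2]) / sqrt(30) + 0.1)
})
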