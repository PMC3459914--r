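test_that("OLS reproduces exact and oracle solutions", {
  g <- c(0, 1, 2, 0, 1, 2)
  X <- cbind(intercept = 1, snp = g)
  fit <- fit_ols(X, 2 * g)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(sum(fit$residuals^2), 0, tolerance = 1e-20)

  # normal-equations oracle on random small instances
  set.seed(50)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    colnames(X) <- c("i", "a", "b", "c")
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-10)
    s2 <- sum((y - X %*% oracle)^2) / (n - 4)
    expect_lt(max(abs(fit$vcov - s2 * solve(t(X) %*% X))), 1e-10)
  }
})

test_that("OLS is invariant to row order and catches rank deficiency", {
  set.seed(51)
  X <- cbind(intercept = 1, snp = rbinom(30, 2, 0.4), z = rnorm(30))
  y <- rnorm(30)
  f1 <- fit_ols(X, y)
  o <- sample(30)
  f2 <- fit_ols(X[o, ], y[o])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  Xbad <- cbind(X, z2 = X[, "z"])
  expect_error(fit_ols(Xbad, y), "collinear")
})

test_that("stratified fits flag small strata and track complete-case counts", {
  d <- cohort_design(n_individuals = 1200, missing_rate = 0.01, seed = 52)
  co <- simulate_cohort(d)
  sm <- code_smoking(co$phenotypes, "binary_smoker")
  cov <- default_covariates(co$phenotypes, NULL, "sbp")
  rs <- run_stratified(co$genotypes, co$phenotypes, "sbp", sm$values, cov)
  expect_equal(nrow(rs), 36L)
  expect_true(all(rs$flag == "ok"))
  expect_true(all(rs$ci_low < rs$beta & rs$beta < rs$ci_high))
  # complete-case n varies across SNPs by roughly rate * stratum size
  for (lev in c("non", "smoker")) {
    nn <- rs$n_used[rs$stratum == lev]
    expect_gt(max(nn) - min(nn), 0)
    expect_lt(max(nn) - min(nn), 0.05 * max(nn))
  }
  # a 3-individual stratum cannot support the model: flagged, not dropped
  tiny <- factor(c(rep("big", 1197), rep("tiny", 3)))
  rs2 <- run_stratified(co$genotypes, co$phenotypes, "sbp", tiny, cov)
  expect_true(all(rs2$flag[rs2$stratum == "tiny"] == "too_small"))
  expect_equal(sum(rs2$stratum == "tiny"), 18L)
})

test_that("nominal CI coverage holds under the null", {
  set.seed(53)
  seeds <- sample.int(1e6, 200)
  cover <- vapply(seeds, function(s) {
    d <- cohort_design(n_individuals = 400, manifest = indep_manifest(1),
                       ld_blocks = data.frame(name = character(0),
                                              start = integer(0),
                                              end = integer(0)),
                       missing_rate = 0, seed = s)
    co <- simulate_cohort(d)
    sm <- code_smoking(co$phenotypes, "binary_smoker")
    rs <- run_stratified(co$genotypes, co$phenotypes, "sbp",
                         factor(rep("all", 400)),
                         default_covariates(co$phenotypes, NULL, "sbp"))
    rs$ci_low <= 0 & 0 <= rs$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("interaction model equals the stratum-difference identity", {
  # with exposure as the only modifier and no other covariates, the
  # interaction coefficient is exactly the difference of stratum slopes
  set.seed(54)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  e <- rbinom(n, 1, 0.5)
  y <- 1 + 0.5 * g + 2 * e - 1.3 * g * e + rnorm(n)
  man <- indep_manifest(1)
  gm <- genotype_matrix(paste0("I", 1:n), man, matrix(g, ncol = 1))
  ph <- tibble::tibble(iid = paste0("I", 1:n), sex = "male", bmi = 25,
                       sbp = y, dbp = 75, medication_ht = FALSE,
                       cigs_per_day = ifelse(e == 1, 5L, 0L),
                       smoking_status = ifelse(e == 1, "current", "never"))
  ri <- run_interaction(gm, ph, "sbp", e, covariates = NULL)
  rs <- run_stratified(gm, ph, "sbp", factor(e), covariates = NULL)
  diff_strata <- rs$beta[rs$stratum == "1"] - rs$beta[rs$stratum == "0"]
  expect_lt(abs(ri$beta_int - diff_strata), 1e-8)
})

test_that("interaction p-values are calibrated under the global null", {
  set.seed(55)
  n <- 250
  pvals <- replicate(800, {
    g <- rbinom(n, 2, 0.3)
    e <- rbinom(n, 1, 0.4)
    y <- rnorm(n)
    X <- cbind(intercept = 1, snp = g, exposure = e, snp_x_exposure = g * e)
    fit <- fit_ols(X, y)
    t <- fit$coefficients["snp_x_exposure"] /
      sqrt(fit$vcov["snp_x_exposure", "snp_x_exposure"])
    2 * pt(abs(t), fit$df_residual, lower.tail = FALSE)
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("quantity adjustment requires smokers and preserves clean effects", {
  d <- cohort_design(n_individuals = 3000, seed = 56,
                     beta_gxe = list(sbp = c(rs1948 = -1.5)))
  co <- simulate_cohort(d)
  sm <- code_smoking(co$phenotypes, "binary_smoker")
  smokers <- which(sm$smoker_indicator == 1)
  gs <- genotype_matrix(co$genotypes$individual_ids[smokers],
                        co$genotypes$manifest,
                        co$genotypes$dosage[smokers, , drop = FALSE])
  ph_s <- co$phenotypes[smokers, ]
  cov_s <- default_covariates(ph_s, NULL, "sbp")
  expect_error(
    adjust_for_quantity(co$genotypes, co$phenotypes, "sbp",
                        sm$smoker_indicator),
    "non-smoker rows")
  adj <- adjust_for_quantity(gs, ph_s, "sbp", rep(1, length(smokers)), cov_s)
  plain <- run_stratified(gs, ph_s, "sbp",
                          factor(rep("smokers", length(smokers))), cov_s)
  i <- match("rs1948", adj$rsid)
  # the planted effect is independent of quantity: estimates agree within 1 SE
  expect_lt(abs(adj$beta[i] - plain$beta[i]), plain$se[i])
})
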