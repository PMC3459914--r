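#' Parametric-bootstrap maxT adjustment for SNP-by-exposure interactions
#'
#' Family-wise error control over the panel's interaction tests that
#' respects the LD-induced correlation between test statistics. Algorithm:
#' (1) per SNP, fit the no-interaction null model (SNP + covariates +
#' exposure) on that SNP's complete cases, storing fitted values and the
#' residual SD; (2) for each of B resamples, simulate outcomes as null
#' fitted values plus Gaussian noise at the null SD — genotypes, exposure
#' and covariates stay fixed, so the inter-SNP correlation structure is
#' preserved — refit every interaction model and record the maximum
#' absolute t statistic over SNPs; (3) the adjusted p-value of SNP j is
#' (1 + #\{b : max_b >= |t_obs_j|\}) / (1 + B). One standard-normal noise
#' vector per resample is shared across the per-SNP null models (scaled by
#' each SNP's null sigma on its rows), so simulated statistics co-vary
#' across SNPs exactly as the observed ones do.
#'
#' @inheritParams run_interaction
#' @param B number of bootstrap resamples (the full analysis uses 10000;
#'   values below 100 trigger a resolution warning).
#' @param seed RNG seed.
#' @param null_model "per_snp_reduced" (default: each SNP's own
#'   no-interaction model) or "shared_reduced" (covariates + exposure only,
#'   no SNP main effect).
#' @param chunk resamples per memory chunk.
#' @param keep_max keep the per-resample max statistics (attribute
#'   `max_stats`) for audit.
#' @return tibble with rsid, t_observed, p_unadjusted, p_adjusted and
#'   attributes `n_resamples`, `seed`.
#' @export
bootstrap_maxt_interaction <- function(geno, pheno, outcome, exposure,
                                       covariates = NULL, B = 10000L,
                                       seed = 1L,
                                       null_model = c("per_snp_reduced",
                                                      "shared_reduced"),
                                       chunk = 500L, keep_max = FALSE) {
  null_model <- match.arg(null_model)
  if (B < 100) warning("B = ", B, " gives adjusted-p resolution ",
                       signif(1 / (B + 1), 2), "; increase B")
  y <- pheno[[outcome]]
  ev <- as.numeric(exposure)
  n_all <- nrow(pheno)
  m <- ncol(geno$dosage)

  prep <- vector("list", m)
  for (j in seq_len(m)) {
    g <- geno$dosage[, j]
    X <- .assoc_design(g, covariates)
    X <- cbind(X, exposure = ev, snp_x_exposure = g * ev)
    full <- fit_ols(X, y) # errors here abort, as they must
    rows <- which(full$rows_used)
    Xc <- X[rows, , drop = FALSE]
    null_cols <- if (null_model == "per_snp_reduced")
      setdiff(colnames(Xc), "snp_x_exposure")
    else setdiff(colnames(Xc), c("snp", "snp_x_exposure"))
    nul <- fit_ols(Xc[, null_cols, drop = FALSE], y[rows])
    b <- full$coefficients["snp_x_exposure"]
    se <- sqrt(full$vcov["snp_x_exposure", "snp_x_exposure"])
    prep[[j]] <- c(
      .tfast_prep(Xc, "snp_x_exposure"),
      list(rows = rows,
           fitted0 = nul$fitted,
           sigma0 = sqrt(nul$sigma2),
           t_obs = unname(b / se),
           p_unadj = unname(2 * stats::pt(abs(b / se), full$df_residual,
                                          lower.tail = FALSE)),
           n_used = full$n))
  }

  set.seed(seed)
  max_stats <- numeric(B)
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Z <- matrix(stats::rnorm(n_all * nb), n_all, nb)
    mx <- rep(0, nb)
    for (j in seq_len(m)) {
      pj <- prep[[j]]
      Y <- pj$fitted0 + pj$sigma0 * Z[pj$rows, , drop = FALSE]
      mx <- pmax(mx, abs(.tfast(pj, Y)))
    }
    max_stats[done + seq_len(nb)] <- mx
    done <- done + nb
  }

  t_obs <- vapply(prep, `[[`, numeric(1), "t_obs")
  p_adj <- vapply(t_obs, function(t0)
    (1 + sum(max_stats >= abs(t0))) / (1 + B), numeric(1))
  out <- tibble::tibble(
    rsid = geno$manifest$rsid,
    t_observed = t_obs,
    p_unadjusted = vapply(prep, `[[`, numeric(1), "p_unadj"),
    p_adjusted = p_adj,
    n_used = vapply(prep, `[[`, integer(1), "n_used"))
  attr(out, "n_resamples") <- B
  attr(out, "seed") <- seed
  if (keep_max) attr(out, "max_stats") <- max_stats
  out
}

#' Bundle one regression for a permutation maxT family
#'
#' A fit unit exposes everything the Freedman-Lane scheme needs: the
#' response, the full design, the tested column, the reduced
#' (covariates-only) columns, and the global individual indices its rows
#' refer to, so families can be aligned across windows.
#'
#' @param y response vector (complete cases only).
#' @param X_full full design matrix (rows match `y`).
#' @param test_col name of the tested column in `X_full`.
#' @param reduced_cols names of the reduced-model columns (default: all but
#'   `test_col`).
#' @param rows global individual indices for the rows.
#' @param label identifier carried into results.
#' @return a `maxt_fit` list.
#' @export
maxt_fit <- function(y, X_full, test_col,
                     reduced_cols = setdiff(colnames(X_full), test_col),
                     rows = seq_along(y), label = test_col) {
  stopifnot(length(y) == nrow(X_full), test_col %in% colnames(X_full),
            all(reduced_cols %in% colnames(X_full)),
            length(rows) == length(y))
  structure(list(y = y, X_full = X_full, test_col = test_col,
                 reduced_cols = reduced_cols, rows = rows, label = label),
            class = "maxt_fit")
}

#' Freedman-Lane maxT permutation of residuals
#'
#' Permutation-based family-wise adjustment for covariate-adjusted tests
#' (the haplotype-window families): fit each unit's reduced model
#' (covariates only), permute its residuals with one shared permutation per
#' resample, rebuild pseudo-outcomes as reduced fitted values plus permuted
#' residuals, refit the full models and take the maximum |t| over the
#' family; adjusted p-values use the add-one convention. Units whose
#' individual sets differ are aligned to the common intersection with a
#' warning.
#'
#' @param fits list of [maxt_fit()] units forming one test family.
#' @param B permutations.
#' @param seed RNG seed.
#' @param chunk permutations per memory chunk.
#' @return tibble with label, t_observed, p_unadjusted, p_adjusted and
#'   attributes `n_resamples`, `seed`, `n_common`.
#' @export
permute_residuals_maxt <- function(fits, B = 10000L, seed = 1L,
                                   chunk = 500L) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "maxt_fit")))
  if (B < 100) warning("B = ", B, " gives adjusted-p resolution ",
                       signif(1 / (B + 1), 2), "; increase B")
  common <- Reduce(intersect, lapply(fits, `[[`, "rows"))
  if (length(common) < 2) stop("fewer than 2 individuals shared across fits")
  if (any(vapply(fits, function(f) length(f$rows), 1L) != length(common)))
    warning("individual sets differ across fits; aligned to the ",
            length(common), "-individual intersection")

  prep <- lapply(fits, function(f) {
    keep <- match(common, f$rows)
    y <- f$y[keep]
    Xf <- f$X_full[keep, , drop = FALSE]
    red <- fit_ols(Xf[, f$reduced_cols, drop = FALSE], y)
    full <- fit_ols(Xf, y)
    b <- full$coefficients[f$test_col]
    se <- sqrt(full$vcov[f$test_col, f$test_col])
    c(.tfast_prep(Xf, f$test_col),
      list(fitted_red = red$fitted, resid_red = red$residuals,
           t_obs = unname(b / se),
           p_unadj = unname(2 * stats::pt(abs(b / se), full$df_residual,
                                          lower.tail = FALSE)),
           label = f$label))
  })

  n <- length(common)
  set.seed(seed)
  max_stats <- numeric(B)
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    perm <- vapply(seq_len(nb), function(i) sample.int(n), integer(n))
    mx <- rep(0, nb)
    for (pj in prep) {
      Y <- pj$fitted_red + matrix(pj$resid_red[perm], n, nb)
      mx <- pmax(mx, abs(.tfast(pj, Y)))
    }
    max_stats[done + seq_len(nb)] <- mx
    done <- done + nb
  }

  t_obs <- vapply(prep, `[[`, numeric(1), "t_obs")
  out <- tibble::tibble(
    label = vapply(prep, `[[`, character(1), "label"),
    t_observed = t_obs,
    p_unadjusted = vapply(prep, `[[`, numeric(1), "p_unadj"),
    p_adjusted = vapply(t_obs, function(t0)
      (1 + sum(max_stats >= abs(t0))) / (1 + B), numeric(1)))
  attr(out, "n_resamples") <- B
  attr(out, "seed") <- seed
  attr(out, "n_common") <- n
  out
}
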