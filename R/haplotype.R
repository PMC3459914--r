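#' Enumerate sliding windows within a haplotype block
#'
#' Every contiguous sub-range of the block with width between `min_width`
#' and the block width, enumerated shorter-first and left-to-right within a
#' width. A block of w SNPs yields w(w+1)/2 windows at `min_width = 1`.
#'
#' @param block one row of a block table (list or data frame with `start`,
#'   `end`, optionally `name`).
#' @param min_width smallest window width.
#' @return data frame with `name`, `start`, `end`, `width`.
#' @export
sliding_windows <- function(block, min_width = 1L) {
  start <- block$start[1]; end <- block$end[1]
  stopifnot(start >= 1, end >= start, min_width >= 1)
  w <- end - start + 1L
  out <- list()
  for (width in seq(min_width, w)) {
    for (s in seq(start, end - width + 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        name = if (!is.null(block$name)) block$name[1] else "block",
        start = s, end = s + width - 1L, width = width,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# all (ordered) diplotype pairs compatible with one multilocus genotype.
# Haplotypes are bit codes over window positions: bit k set = effect allele
# at SNP k. Returns two integer vectors of equal length (codes of hap1/hap2).
.compatible_pairs <- function(g) {
  w <- length(g)
  bits <- 2L^(seq_len(w) - 1L)
  base <- sum(bits[g == 2L])
  het <- which(g == 1L)
  if (!length(het)) return(list(a = base, b = base))
  nh <- length(het)
  a <- integer(2^nh); b <- integer(2^nh)
  for (s in seq_len(2^nh) - 1L) {
    sel <- as.logical(bitwAnd(s, 2L^(seq_len(nh) - 1L)))
    a[s + 1L] <- base + sum(bits[het[sel]])
    b[s + 1L] <- base + sum(bits[het[!sel]])
  }
  list(a = a, b = b)
}

#' EM estimation of haplotype frequencies in a marker window
#'
#' Expectation-maximization over the diplotype sets compatible with each
#' individual's unphased multilocus genotype, under random mating (diplotype
#' probability proportional to the product of its two haplotype
#' frequencies). The E-step assigns each individual posterior diplotype
#' weights at the current frequencies; the M-step re-estimates frequencies
#' from the expected haplotype counts. Initialization is the
#' linkage-equilibrium point (product of allele frequencies), which is
#' deterministic and interior to the simplex. The log-likelihood is
#' non-decreasing across iterations (checked); convergence is a maximum
#' frequency change below `tol`. Individuals with any missing genotype in
#' the window are excluded from estimation.
#'
#' @param G n x w matrix of effect-allele dosages (0/1/2, NA allowed).
#' @param tol convergence tolerance on max frequency change.
#' @param max_iter iteration cap; hitting it returns the best iterate with
#'   `converged = FALSE`.
#' @return list with `hap_codes` (integer bit codes), `frequencies`,
#'   `loglik`, `n_used`, `iterations`, `converged`.
#' @export
em_haplotype_frequencies <- function(G, tol = 1e-6, max_iter = 1000L) {
  G <- as.matrix(G)
  w <- ncol(G)
  stopifnot(w >= 1)
  ok <- stats::complete.cases(G)
  Gc <- G[ok, , drop = FALSE]
  n <- nrow(Gc)
  if (n < 1) stop("no individual with complete genotypes in the window")

  key <- apply(Gc, 1, paste, collapse = ",")
  tab <- table(key)
  ug <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  cnt <- as.numeric(tab)

  pair_a <- integer(0); pair_b <- integer(0); pair_g <- integer(0)
  for (i in seq_len(nrow(ug))) {
    pr <- .compatible_pairs(ug[i, ])
    pair_a <- c(pair_a, pr$a); pair_b <- c(pair_b, pr$b)
    pair_g <- c(pair_g, rep(i, length(pr$a)))
  }
  haps <- sort(unique(c(pair_a, pair_b)))
  ia <- match(pair_a, haps); ib <- match(pair_b, haps)

  # linkage-equilibrium start from sample allele frequencies
  p <- colMeans(Gc) / 2
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  hap_bits <- matrix(vapply(haps, function(h)
    as.integer(as.logical(bitwAnd(h, 2L^(seq_len(w) - 1L)))), integer(w)),
    ncol = w, byrow = TRUE)
  f <- exp(hap_bits %*% log(p) + (1 - hap_bits) %*% log(1 - p))[, 1]
  f <- f / sum(f)

  loglik <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wts <- f[ia] * f[ib]
    denom <- as.numeric(rowsum(wts, pair_g))
    ll <- sum(cnt * log(denom))
    post <- wts * (cnt / denom)[pair_g]
    cb <- rep(0, length(haps))
    rb <- rowsum(post, ib)
    cb[as.integer(rownames(rb))] <- rb
    ca <- rep(0, length(haps))
    ra <- rowsum(post, ia)
    ca[as.integer(rownames(ra))] <- ra
    f_new <- (ca + cb) / (2 * n)
    delta <- max(abs(f_new - f))
    if (ll < loglik - 1e-8)
      warning("EM log-likelihood decreased; numerical issue")
    loglik <- ll
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(hap_codes = haps, frequencies = f, loglik = loglik, n_used = n,
       iterations = it, converged = converged)
}

#' Posterior-expected haplotype dosages
#'
#' Expected copy number of each haplotype per individual given their
#' unphased genotype and the population haplotype frequencies: posterior
#' diplotype weights proportional to the frequency products, summed over
#' each haplotype's appearances. Rows with missing genotypes are NA; each
#' complete row sums to 2.
#'
#' @param G n x w dosage matrix.
#' @param hap_codes,frequencies as returned by
#'   [em_haplotype_frequencies()].
#' @return n x H matrix of expected copy counts.
#' @export
expected_dosages <- function(G, hap_codes, frequencies) {
  G <- as.matrix(G)
  n <- nrow(G)
  H <- length(hap_codes)
  out <- matrix(NA_real_, n, H)
  ok <- which(stats::complete.cases(G))
  key <- apply(G[ok, , drop = FALSE], 1, paste, collapse = ",")
  for (k in unique(key)) {
    g <- as.integer(strsplit(k, ",")[[1]])
    pr <- .compatible_pairs(g)
    ia <- match(pr$a, hap_codes); ib <- match(pr$b, hap_codes)
    if (anyNA(ia) || anyNA(ib))
      stop("genotype incompatible with the supplied haplotype set")
    wts <- frequencies[ia] * frequencies[ib]
    if (sum(wts) <= 0) wts <- rep(1, length(wts)) # degenerate: flat posterior
    wts <- wts / sum(wts)
    ed <- rep(0, H)
    for (q in seq_along(ia)) {
      ed[ia[q]] <- ed[ia[q]] + wts[q]
      ed[ib[q]] <- ed[ib[q]] + wts[q]
    }
    out[ok[key == k], ] <- matrix(ed, sum(key == k), H, byrow = TRUE)
  }
  out
}

#' Phase one marker window
#'
#' Runs the EM on the window's genotypes and attaches expected dosages and
#' readable allele strings (effect allele at a SNP printed as the
#' manifest's effect allele).
#'
#' @param geno a [genotype_matrix()].
#' @param start,end 1-based SNP index range (inclusive) within the panel.
#' @param tol,max_iter EM controls.
#' @return a `haplo_window` list: `snp_indices`, `rsids`, `haplotypes`
#'   (allele strings), `hap_codes`, `frequencies`, `dosage_expect`
#'   (N x H, NA rows where the window genotype is incomplete), `loglik`,
#'   `converged`, `n_used`.
#' @export
phase_window <- function(geno, start, end, tol = 1e-6, max_iter = 1000L) {
  idx <- start:end
  G <- geno$dosage[, idx, drop = FALSE]
  em <- em_haplotype_frequencies(G, tol = tol, max_iter = max_iter)
  ed <- expected_dosages(G, em$hap_codes, em$frequencies)
  man <- geno$manifest[idx, ]
  strings <- vapply(em$hap_codes, function(h) {
    bits <- as.logical(bitwAnd(h, 2L^(seq_along(idx) - 1L)))
    paste0(ifelse(bits, man$effect_allele, man$other_allele), collapse = "")
  }, character(1))
  structure(list(snp_indices = idx, rsids = man$rsid, haplotypes = strings,
                 hap_codes = em$hap_codes, frequencies = em$frequencies,
                 dosage_expect = ed, loglik = em$loglik,
                 converged = em$converged, n_used = em$n_used),
            class = "haplo_window")
}

#' @export
print.haplo_window <- function(x, ...) {
  cat("haplo_window over", paste(range(x$snp_indices), collapse = "-"),
      ":", length(x$haplotypes), "haplotypes, loglik",
      sprintf("%.2f", x$loglik), "\n")
  invisible(x)
}

#' Haplotype-dosage association within an exposure stratum
#'
#' For each haplotype with estimated frequency above `freq_min` (default
#' 1%), regresses the outcome on that haplotype's expected copy number plus
#' covariates over the stratum's complete cases — the additive haplotype
#' model. Rare haplotypes stay in the frequency model but are not tested.
#' The returned `fits` are [maxt_fit()] units ready for
#' [permute_residuals_maxt()].
#'
#' @param window a `haplo_window` from [phase_window()].
#' @param pheno phenotype tibble for the full cohort.
#' @param outcome outcome column name.
#' @param rows integer indices of the stratum's individuals (default all).
#' @param covariates covariate data frame aligned to `pheno`.
#' @param freq_min haplotype frequency threshold for testing.
#' @param conf_level confidence level for normal-quantile CIs.
#' @return list with `results` tibble (haplotype, frequency, beta, se,
#'   ci_low, ci_high, p_value, n_used) and `fits`.
#' @export
haplotype_association <- function(window, pheno, outcome,
                                  rows = seq_len(nrow(pheno)),
                                  covariates = NULL, freq_min = 0.01,
                                  conf_level = 0.95) {
  keep_h <- which(window$frequencies > freq_min)
  if (!length(keep_h)) {
    warning("no haplotype exceeds frequency ", freq_min)
    return(list(results = tibble::tibble(), fits = list()))
  }
  y <- pheno[[outcome]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- list(); fits <- list()
  for (h in keep_h) {
    d <- window$dosage_expect[, h]
    X <- .assoc_design(d[rows],
                       if (is.null(covariates)) NULL
                       else covariates[rows, , drop = FALSE])
    colnames(X)[2] <- "hap"
    fit <- fit_ols(X, y[rows])
    b <- fit$coefficients["hap"]
    se <- sqrt(fit$vcov["hap", "hap"])
    lab <- sprintf("%s[%s]", paste(range(window$snp_indices), collapse = "-"),
                   window$haplotypes[h])
    res[[length(res) + 1L]] <- tibble::tibble(
      haplotype = window$haplotypes[h],
      frequency = window$frequencies[h],
      beta = unname(b), se = unname(se),
      ci_low = unname(b - z * se), ci_high = unname(b + z * se),
      p_value = unname(2 * stats::pt(abs(b / se), fit$df_residual,
                                     lower.tail = FALSE)),
      n_used = fit$n)
    used <- which(fit$rows_used)
    fits[[length(fits) + 1L]] <- maxt_fit(
      y = y[rows][used], X_full = X[used, , drop = FALSE], test_col = "hap",
      rows = rows[used], label = lab)
  }
  list(results = do.call(rbind, res), fits = fits)
}
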