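# shared fixtures and independent oracles, built in code

two_snp_manifest <- function(maf1 = 0.33, maf2 = 0.27) {
  snp_manifest(c("s1", "s2"), "1", c(100L, 200L), c("A", "A"), c("G", "G"),
               c(maf1, maf2), c(TRUE, TRUE))
}

indep_manifest <- function(m, maf = 0.3) {
  snp_manifest(sprintf("m%03d", seq_len(m)), "1", seq_len(m) * 1000L,
               rep("A", m), rep("G", m), rep(maf, m), rep(TRUE, m))
}

# r^2 computed from realized two-locus chromosome counts (the ground truth
# the composite dosage estimate approximates)
hap_r2_oracle <- function(haps) {
  pA <- mean(haps[, 1]); pB <- mean(haps[, 2])
  D <- mean(haps[, 1] == 1 & haps[, 2] == 1) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# nested grid search maximizing the unphased-genotype multinomial likelihood
# over the 2-SNP haplotype frequency simplex -- the independent oracle for
# the EM. Haplotype order: (11, 10, 01, 00) over effect alleles; the first
# three frequencies are free, the fourth implied.
grid_search_hapfreq <- function(G, steps = c(0.01, 1e-3, 1e-4, 2e-5)) {
  # precompute, per unique genotype, the ordered compatible haplotype pairs
  key <- paste(G[, 1], G[, 2])
  tab <- table(key)
  hs <- expand.grid(a1 = 0:1, b1 = 0:1, a2 = 0:1, b2 = 0:1)
  hidx <- function(a, b) 1L + (1L - a) * 2L + (1L - b) # maps 11,10,01,00 -> 1..4
  units <- lapply(names(tab), function(k) {
    g <- as.integer(strsplit(k, " ")[[1]])
    ok <- hs$a1 + hs$a2 == g[1] & hs$b1 + hs$b2 == g[2]
    list(a = hidx(hs$a1[ok], hs$b1[ok]), b = hidx(hs$a2[ok], hs$b2[ok]),
         n = tab[[k]])
  })
  ll_of <- function(f3) {
    f <- c(f3, 1 - sum(f3))
    if (any(f < 0)) return(-Inf)
    sum(vapply(units, function(u) u$n * log(sum(f[u$a] * f[u$b])),
               numeric(1)))
  }
  centre <- rep(0.25, 3)
  best <- centre
  for (st in steps) {
    span <- if (st == steps[1]) 0.25 else 2 * steps[match(st, steps) - 1]
    grid <- seq(-span, span, by = st)
    best_ll <- -Inf
    for (d1 in grid) for (d2 in grid) for (d3 in grid) {
      f3 <- centre + c(d1, d2, d3)
      ll <- ll_of(f3)
      if (ll > best_ll) { best_ll <- ll; best <- f3 }
    }
    centre <- best
  }
  c(best, 1 - sum(best))
}

# draw unphased 2-SNP genotypes from known haplotype frequencies
draw_2snp_genotypes <- function(n, freqs, seed) {
  set.seed(seed)
  # haplotypes coded 11, 10, 01, 00 over (snp1, snp2) effect alleles
  hap_alleles <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  pick <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = freqs), n, 2)
  hap_alleles[pick[, 1], ] + hap_alleles[pick[, 2], ]
}

# small null cohort for resampling tests
null_cohort <- function(n = 400, m = 6, seed = 1, maf = 0.3) {
  d <- cohort_design(n_individuals = n, manifest = indep_manifest(m, maf),
                     ld_blocks = data.frame(name = character(0),
                                            start = integer(0),
                                            end = integer(0)),
                     missing_rate = 0, seed = seed)
  simulate_cohort(d)
}
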