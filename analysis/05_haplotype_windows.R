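#!/usr/bin/env Rscript
# Stage 5: EM-phased sliding-window haplotype association within the two
# LD blocks, separately in non-smokers and smokers, with
# permutation-of-residuals maxT per block family (windows capped at width 4
# and B = 1000 at desk scale).

library(snpgxe)

in_dir <- "results/cohort"
out_dir <- "results/haplotype"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- read_design_yaml(file.path(in_dir, "design.yaml"))
geno <- filter_common_snps(
  read_ped_map(file.path(in_dir, "cohort.ped"),
               file.path(in_dir, "cohort.map"), design$manifest), 0.05)
pheno <- adjust_bp_for_medication(
  read_phenotypes(file.path(in_dir, "phenotypes.tsv")))
pc_scores <- utils::read.delim("results/qc/pc_scores.tsv")[, -1]
binary <- code_smoking(pheno, "binary_smoker")
covars <- default_covariates(pheno, pc_scores, "sbp")

blocks <- default_blocks()
for (bi in seq_len(nrow(blocks))) {
  wins <- sliding_windows(blocks[bi, ])
  wins <- wins[wins$width <= 4, ]
  for (strat in c("non", "smoker")) {
    rows <- which(!is.na(binary$values) & binary$values == strat)
    all_res <- list(); fits <- list()
    for (wi in seq_len(nrow(wins))) {
      win <- phase_window(geno, wins$start[wi], wins$end[wi])
      ha <- haplotype_association(win, pheno, "sbp", rows, covars)
      if (!nrow(ha$results)) next
      ha$results$window <- sprintf("%d-%d", wins$start[wi], wins$end[wi])
      all_res[[length(all_res) + 1L]] <- ha$results
      fits <- c(fits, ha$fits)
    }
    res <- do.call(rbind, all_res)
    pm <- suppressWarnings(
      permute_residuals_maxt(fits, B = 1000L, seed = 20260930L))
    res$p_adjusted <- pm$p_adjusted[match(
      sprintf("%s[%s]", res$window, res$haplotype),
      sub("^([0-9]+-[0-9]+)\\[", "\\1[", pm$label))]
    fn <- sprintf("%s_sbp_%s.tsv", blocks$name[bi], strat)
    utils::write.table(res, file.path(out_dir, fn), quote = FALSE,
                       sep = "\t", row.names = FALSE)
    top <- res[order(res$p_value), ][1, ]
    cat(sprintf("%s %s: top window %s haplotype %s beta %.2f (p %.3g, adj %.3g), %d tests\n",
                blocks$name[bi], strat, top$window, top$haplotype, top$beta,
                top$p_value, top$p_adjusted, nrow(res)))
  }
}
cat("Haplotype tables written to", out_dir, "\n")
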