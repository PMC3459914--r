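#!/usr/bin/env Rscript
# Stage 2: phenotype corrections, exposure coding, variant QC and
# stratification PCs.
#
# Reads the stage-1 cohort from disk through the PLINK-text reader (so the
# I/O layer is exercised, not bypassed), applies the +15/+10 mmHg
# medication correction, codes smoking exposures and filters to common
# SNPs (MAF > 5%).
#
# Stratification PCs must come from a background panel, not from the
# candidate region itself: PCs computed from the 18 analyzed SNPs are
# linear combinations of the very dosages under test and absorb their
# signal. The reference recipe screens genome-wide autosomal SNPs; as the
# stand-in for those (synthetic, like the cohort) we simulate 600
# independent background SNPs for the same individuals and run the full
# screen on them: MAF > 1%, HWE p > 0.005, call rate > 99.5%, r2 > 0.2
# pruning, 1-in-15 thinning.

library(snpgxe)

in_dir <- "results/cohort"
out_dir <- "results/qc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- read_design_yaml(file.path(in_dir, "design.yaml"))
geno <- read_ped_map(file.path(in_dir, "cohort.ped"),
                     file.path(in_dir, "cohort.map"), design$manifest)
pheno <- read_phenotypes(file.path(in_dir, "phenotypes.tsv"))

pheno <- adjust_bp_for_medication(pheno)
cat("Medication correction applied to", sum(pheno$medication_ht),
    "individuals (+15 SBP / +10 DBP mmHg).\n")

smoking <- code_smoking(pheno, "binary_smoker")
cat("Exposure coding:", sum(smoking$smoker_indicator == 1, na.rm = TRUE),
    "smokers,", sum(smoking$smoker_indicator == 0, na.rm = TRUE),
    "non-smokers.\n")

geno_common <- filter_common_snps(geno, 0.05)
cat(ncol(geno_common$dosage), "of", ncol(geno$dosage),
    "SNPs pass MAF > 5%.\n")

m_bg <- 600L
bg_manifest <- snp_manifest(
  rsid = sprintf("bg%04d", seq_len(m_bg)), chrom = "1",
  position = seq_len(m_bg) * 10000L,
  effect_allele = rep("A", m_bg), other_allele = rep("G", m_bg),
  maf = rep(seq(0.05, 0.5, length.out = 60L), length.out = m_bg),
  effect_is_minor = rep(TRUE, m_bg))
bg_design <- cohort_design(
  n_individuals = design$n_individuals, manifest = bg_manifest,
  ld_blocks = data.frame(name = character(0), start = integer(0),
                         end = integer(0)),
  missing_rate = 0.002, seed = design$seed + 7L)
bg_geno <- simulate_genotypes(bg_design)

panel <- select_pc_panel(bg_geno)
pcs <- compute_pcs(panel, k = 3)
cat("PC panel:", length(pcs$snps_used), "of", m_bg,
    "background SNPs after screening, pruning and 1-in-15 thinning;",
    "top eigenvalues:", paste(sprintf("%.2f", pcs$eigenvalues),
                              collapse = ", "), "\n")
log <- attr(panel, "qc_log")
print(table(log$reason))

utils::write.table(data.frame(iid = bg_geno$individual_ids, pcs$scores),
                   file.path(out_dir, "pc_scores.tsv"),
                   quote = FALSE, sep = "\t", row.names = FALSE)
utils::write.table(log, file.path(out_dir, "pc_panel_log.tsv"),
                   quote = FALSE, sep = "\t", row.names = FALSE)
cat("PC scores and panel log written to", out_dir, "\n")
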