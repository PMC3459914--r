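#' Run the full candidate-region analysis
#'
#' Orchestrates the stages in study order: blood-pressure medication
#' correction, exposure coding, common-SNP filtering, stratification PCs,
#' stratified single-marker fits, SNP-by-smoking interaction tests with
#' parametric-bootstrap maxT adjustment, and (optionally) sliding-window
#' haplotype association with permutation-of-residuals maxT per block.
#' Rerunning with the same cohort, B and seed is bit-identical.
#'
#' The stratification-PC panel is drawn from the analysis genotypes with
#' the standard screen (MAF > 1%, HWE p > 0.005, call rate > 99.5%,
#' r^2 > 0.2 pruning, 1-in-15 thinning); if thinning leaves fewer SNPs than
#' requested components, the un-thinned pruned panel is used instead (a
#' regional panel is far smaller than the genome-wide panel the recipe was
#' written for).
#'
#' @param cohort a `synthetic_cohort` (or list with `genotypes`,
#'   `phenotypes`).
#' @param outcomes outcome columns to analyse.
#' @param B resamples for both maxT procedures.
#' @param seed RNG seed for the resampling stages.
#' @param blocks haplotype-block table (`name`, `start`, `end` as indices
#'   into the post-filter panel); NULL skips the haplotype stage.
#' @param haplo_outcomes outcomes for the haplotype stage (default first of
#'   `outcomes`).
#' @param window_min_width,window_max_width sliding-window width bounds.
#' @param freq_min haplotype testing frequency threshold.
#' @param maf_min common-SNP filter threshold.
#' @param n_pcs number of stratification PCs.
#' @param pc_genotypes genotype matrix the PC panel is drawn from. Defaults
#'   to the analysis genotypes, which is only appropriate for smoke tests:
#'   PCs computed from the candidate region itself are linear combinations
#'   of the analyzed dosages and will absorb genetic signal. For real use
#'   supply a background (genome-wide) panel, as the screening recipe
#'   assumes.
#' @param outdir optional directory; when given, publication-shaped TSVs, a
#'   strata summary JSON and a run log (seed, B, design checksum) are
#'   written under it.
#' @return list with `pheno`, `geno`, `smoking`, `pcs`, `stratified`,
#'   `interaction`, `maxt`, `haplotype`, `strata_summary`.
#' @export
run_region_analysis <- function(cohort, outcomes = c("sbp", "dbp", "bmi"),
                                B = 1000L, seed = 1L, blocks = NULL,
                                haplo_outcomes = outcomes[1],
                                window_min_width = 1L,
                                window_max_width = Inf,
                                freq_min = 0.01, maf_min = 0.05,
                                n_pcs = 3L, pc_genotypes = NULL,
                                outdir = NULL) {
  pheno <- adjust_bp_for_medication(cohort$phenotypes)
  smoking <- code_smoking(pheno, "binary_smoker")
  geno <- filter_common_snps(cohort$genotypes, maf_min)

  if (is.null(pc_genotypes)) pc_genotypes <- cohort$genotypes
  panel <- select_pc_panel(pc_genotypes)
  if (ncol(panel$dosage) < n_pcs + 1L)
    panel <- select_pc_panel(pc_genotypes, thin_step = 1L)
  pcs <- compute_pcs(panel, k = min(n_pcs, ncol(panel$dosage) - 1L))

  stratified <- list(); interaction <- list(); maxt <- list()
  for (oc in outcomes) {
    covars <- default_covariates(pheno, pcs, oc)
    stratified[[oc]] <- run_stratified(geno, pheno, oc, smoking$values,
                                       covars)
    interaction[[oc]] <- run_interaction(geno, pheno, oc,
                                         smoking$smoker_indicator, covars)
    maxt[[oc]] <- bootstrap_maxt_interaction(geno, pheno, oc,
                                             smoking$smoker_indicator,
                                             covars, B = B, seed = seed)
  }

  haplo <- NULL
  if (!is.null(blocks)) {
    haplo <- list()
    for (bi in seq_len(nrow(blocks))) {
      wins <- sliding_windows(blocks[bi, ], window_min_width)
      wins <- wins[wins$width <= window_max_width, , drop = FALSE]
      for (oc in haplo_outcomes) {
        covars <- default_covariates(pheno, pcs, oc)
        for (strat in c("non", "smoker")) {
          rows <- which(!is.na(smoking$values) & smoking$values == strat)
          fits <- list(); res <- list()
          for (wi in seq_len(nrow(wins))) {
            win <- phase_window(geno, wins$start[wi], wins$end[wi])
            ha <- haplotype_association(win, pheno, oc, rows, covars,
                                        freq_min)
            if (nrow(ha$results)) {
              ha$results$window <- sprintf("%d-%d", wins$start[wi],
                                           wins$end[wi])
              res[[length(res) + 1L]] <- ha$results
              fits <- c(fits, ha$fits)
            }
          }
          key <- sprintf("%s_%s_%s", blocks$name[bi], oc, strat)
          haplo[[key]] <- list(
            results = do.call(rbind, res),
            maxt = if (length(fits))
              permute_residuals_maxt(fits, B = B, seed = seed) else NULL)
        }
      }
    }
  }

  strata_summary <- summarize_strata(pheno)

  out <- list(pheno = pheno, geno = geno, smoking = smoking, pcs = pcs,
              stratified = stratified, interaction = interaction,
              maxt = maxt, haplotype = haplo,
              strata_summary = strata_summary,
              seed = seed, B = B)
  if (!is.null(outdir)) .write_run_outputs(out, cohort, outdir)
  invisible(out)
}

.write_run_outputs <- function(out, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (oc in names(out$stratified)) {
    dir.create(file.path(outdir, oc), showWarnings = FALSE)
    render_tables(out$stratified[[oc]], out$geno$manifest,
                  maxt = out$maxt[[oc]],
                  path = file.path(outdir, oc, "by_smoking.tsv"))
  }
  if (!is.null(out$haplotype)) {
    for (key in names(out$haplotype)) {
      h <- out$haplotype[[key]]
      if (!is.null(h$results))
        utils::write.table(h$results, file.path(outdir,
                                                paste0("haplo_", key, ".tsv")),
                           quote = FALSE, sep = "\t", row.names = FALSE)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(n_complete = out$strata_summary$n_complete,
           pct_non_smokers = out$strata_summary$pct_non_smokers,
           pct_heavy_by_sex = as.list(out$strata_summary$pct_heavy_by_sex)),
      file.path(outdir, "summary.json"), auto_unbox = TRUE)
  }
  design_path <- file.path(outdir, "design.yaml")
  if (!is.null(cohort$design)) {
    write_design_yaml(cohort$design, design_path)
    cks <- unname(tools::md5sum(design_path))
  } else cks <- NA_character_
  writeLines(c(sprintf("seed: %d", out$seed),
               sprintf("resamples: %d", out$B),
               sprintf("design_md5: %s", cks),
               sprintf("package_version: %s",
                       as.character(utils::packageVersion("snpgxe")))),
             file.path(outdir, "run_log.txt"))
  invisible(NULL)
}
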