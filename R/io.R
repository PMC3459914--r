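#' Write a cohort in PLINK text format
#'
#' `.ped`: six leading columns (FID IID PAT MAT SEX PHENO) then two
#' whitespace-separated allele columns per SNP; missing calls are "0 0".
#' `.map`: chrom, rsid, 0 (genetic distance), 1-based position.
#'
#' @param g a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param pheno optional phenotype table supplying SEX (1 = male,
#'   2 = female); 0 (unknown) otherwise.
#' @export
write_ped_map <- function(g, ped_path, map_path, pheno = NULL) {
  man <- g$manifest
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  sex_code <- rep("0", n)
  if (!is.null(pheno)) {
    idx <- match(g$individual_ids, pheno$iid)
    sex_code <- ifelse(is.na(idx), "0",
                       ifelse(pheno$sex[idx] == "male", "1", "2"))
  }
  alle <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- g$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, man$effect_allele[j],
                                       man$other_allele[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, man$effect_allele[j],
                                       man$other_allele[j]))
    alle[, 2L * j - 1L] <- a1
    alle[, 2L * j] <- a2
  }
  ped <- cbind(g$individual_ids, g$individual_ids, "0", "0", sex_code, "-9",
               alle)
  utils::write.table(ped, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  map <- cbind(man$chrom, man$rsid, "0", man$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read PLINK text genotypes into effect-allele dosages
#'
#' Allele pairs are converted to counts of the manifest's effect allele;
#' orientation always comes from the manifest, never from sample frequency.
#' "0 0" is missing; any other allele not matching the manifest's two
#' alleles is an error naming the SNP and ped line.
#'
#' @param ped_path,map_path PLINK text files; map SNP order must match the
#'   ped allele-pair order and the manifest.
#' @param manifest a [snp_manifest()].
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path, manifest) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  if (!identical(map$V2, manifest$rsid))
    stop("map SNP order does not match the manifest")
  m <- nrow(manifest)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  dosage <- matrix(NA_integer_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop(sprintf("ragged ped line %d: %d fields, expected %d",
                   i, length(f), 6L + 2L * m))
    ids[i] <- f[2]
    a <- matrix(f[-(1:6)], nrow = 2L)
    for (j in seq_len(m)) {
      pair <- a[, j]
      if (all(pair == "0")) next
      eff <- manifest$effect_allele[j]; oth <- manifest$other_allele[j]
      bad <- setdiff(pair, c(eff, oth))
      if (length(bad))
        stop(sprintf("unknown allele '%s' at %s, ped line %d",
                     bad[1], manifest$rsid[j], i))
      dosage[i, j] <- sum(pair == eff)
    }
  }
  genotype_matrix(ids, manifest, dosage)
}

#' Write a phenotype table as TSV
#'
#' Tab-separated with header IID SEX BMI SBP DBP MEDICATION_HT CIGS_PER_DAY
#' SMOKING_STATUS; missing values as NA; an optional leading comment line
#' records the generating seed.
#'
#' @param pheno phenotype tibble (as from [simulate_phenotypes()]).
#' @param path output path.
#' @param seed optional integer recorded as a `# seed:` header comment.
#' @export
write_phenotypes <- function(pheno, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  out <- data.frame(
    IID = pheno$iid,
    SEX = pheno$sex,
    BMI = pheno$bmi,
    SBP = pheno$sbp,
    DBP = pheno$dbp,
    MEDICATION_HT = as.integer(pheno$medication_ht),
    CIGS_PER_DAY = pheno$cigs_per_day,
    SMOKING_STATUS = pheno$smoking_status
  )
  utils::write.table(out, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}

#' Read a phenotype TSV
#'
#' Validates the mandatory columns and the closed category vocabularies
#' (SEX in male/female, SMOKING_STATUS in never/former/current). Rows with
#' SBP <= DBP are flagged with a warning, not rejected. Decimal separator is
#' the dot regardless of locale.
#'
#' @param path TSV path; `#`-prefixed lines are comments.
#' @return phenotype tibble with lowercase column names.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, dec = ".")
  need <- c("IID", "SEX", "BMI", "SBP", "DBP", "MEDICATION_HT",
            "CIGS_PER_DAY", "SMOKING_STATUS")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  bad_sex <- setdiff(unique(df$SEX[!is.na(df$SEX)]), c("male", "female"))
  if (length(bad_sex)) stop("unknown SEX category '", bad_sex[1], "'")
  bad_sm <- setdiff(unique(df$SMOKING_STATUS[!is.na(df$SMOKING_STATUS)]),
                    c("never", "former", "current"))
  if (length(bad_sm)) stop("unknown SMOKING_STATUS category '", bad_sm[1], "'")
  both <- !is.na(df$SBP) & !is.na(df$DBP)
  if (any(df$SBP[both] <= df$DBP[both]))
    warning(sum(df$SBP[both] <= df$DBP[both]),
            " row(s) with SBP <= DBP retained")
  tibble::tibble(
    iid = as.character(df$IID),
    sex = df$SEX,
    bmi = as.numeric(df$BMI),
    sbp = as.numeric(df$SBP),
    dbp = as.numeric(df$DBP),
    medication_ht = as.logical(df$MEDICATION_HT),
    cigs_per_day = as.integer(df$CIGS_PER_DAY),
    smoking_status = df$SMOKING_STATUS
  )
}
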