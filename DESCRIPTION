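Package: snpgxe
Title: Candidate-Region SNP-by-Smoking Interaction Analysis with Resampling-Based Multiplicity Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A candidate-gene association pipeline for quantitative traits
    (blood pressure, body mass index) built around the CHRNA5-CHRNA3-CHRNB4
    nicotinic receptor cluster at 15q25: synthetic cohort simulation with
    linkage-disequilibrium blocks and planted gene-by-smoking effects, PLINK
    text genotype input/output, variant quality control and stratification
    principal components, additive covariate-adjusted single-marker models
    stratified by smoking exposure, SNP-by-smoking interaction tests with
    parametric-bootstrap maxT family-wise error control, and EM-based
    sliding-window haplotype association with Freedman-Lane permutation of
    residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
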