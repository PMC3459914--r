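---
title: "Candidate-region gene-by-smoking interaction analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-region gene-by-smoking interaction analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The nicotinic acetylcholine receptor subunit cluster *CHRNA5-CHRNA3-CHRNB4*
at 15q25 is robustly associated with smoking quantity and nicotine
dependence, and the receptor subunits it encodes are expressed in autonomic
ganglia, making the region a candidate for cardiovascular regulation as
well. The analysis this package implements asks whether common variation in
an 18-SNP panel covering the cluster is associated with systolic and
diastolic blood pressure (SBP, DBP) and body mass index (BMI) in a young
adult cohort, and — the central question — whether those associations are
modified by smoking. Because the smoking-increasing alleles tend to lower
SBP and BMI *in smokers specifically*, the statistical machinery centres on
gene-by-environment (G×E) interaction tests and on honest family-wise error
control across a correlated SNP panel.

The original cohort data are not publicly deposited, so the package pairs
the analysis machinery with a synthetic-cohort generator that reproduces
the study's statistical structure (panel frequencies, LD blocks, strata
composition, outcome distributions, planted effects). Every stage is
therefore testable against known ground truth.

## Models

### Single-marker models

All models are linear-Gaussian on the outcome's original scale, with an
additive genetic effect: the dosage g ∈ {0, 1, 2} counts copies of the
manifest's *effect allele* (the smoking-increasing allele, which is not
always the minor allele — orientation is taken from the manifest, never
inferred from frequency).

Stratified model, fit separately in non-smokers and smokers:

    y = b0 + b_g g + b_s sex + [b_bmi BMI] + Σ_k c_k PC_k + e

BMI enters as a covariate for blood-pressure outcomes only; the BMI outcome
never adjusts for itself. The interaction model adds the exposure main
effect and one product term:

    y = b0 + b_g g + b_s sex + [b_bmi BMI] + Σ_k c_k PC_k
        + b_e smoker + b_ge (g × smoker) + e

`b_ge` is the effect-modification parameter; its t statistic (two-sided,
t-distribution p on the residual degrees of freedom) is the tested
quantity. Exposure-specific covariate slopes are deliberately not included:
the main-effects-plus-one-product form is the reported model. Confidence
intervals use the normal quantile (±1.96 SE) by default — at stratum sizes
in the thousands the difference from the t quantile is below 0.1% — with a
t-quantile switch available.

### Smoking exposure

Smoking is coded from current behaviour and quantity: non-smokers (never
and former smokers together), light smokers (1–10 cigarettes/day), heavy
smokers (>10/day). The binary smoker indicator collapses light and heavy.
A current smoker reporting 0 cigarettes/day is internally inconsistent and
is flagged and excluded from exposure-stratified fits rather than recoded.
Blood pressure of individuals on antihypertensive medication is corrected
by +15 mmHg (SBP) and +10 mmHg (DBP) before modelling, the standard
offsets for restoring the untreated scale; the correction carries a
done-flag so it cannot be applied twice.

### Stratification principal components

PCs are computed from a screened genotype panel: MAF > 1%, Hardy-Weinberg
p > 0.005 (1-df chi-square — the cited threshold names no test, and the
chi-square is deterministic and closed-form checkable), call rate > 99.5%,
greedy left-to-right pruning at composite r² > 0.2, then 1-in-15 thinning
(positions 1, 16, 31, … of the pruned order; "1 in 15" fixes no phase, so
the leftmost alignment is used). Columns are standardized by 2p̂ and
√(2p̂(1−p̂)) (Patterson scaling; the source recipe is silent on scaling) and
missing calls are mean-imputed for the decomposition only — association
fits always use per-SNP complete cases, which is what makes per-SNP N vary.
The decomposition is the SVD of the standardized matrix, equivalent to the
eigendecomposition of the individual-by-individual covariance. When the
recipe's 1-in-15 thinning is applied to a *regional* panel (18 SNPs rather
than a genome-wide set) it can leave fewer SNPs than requested components;
the pipeline then falls back to the un-thinned pruned panel and the
analysis drivers simulate a 600-SNP independent background panel as the
genome-wide stand-in for exactly this reason: PCs computed from the
candidate region itself are linear combinations of the analyzed dosages
and absorb their signal, so `run_region_analysis()` accepts a separate
`pc_genotypes` source and only falls back to the analysis panel for smoke
tests. Per-individual call-rate screening is not applied (the recipe
states per-SNP filters only).

### Parametric-bootstrap maxT for the interaction family

Family-wise error control across the 18 interaction tests uses the maxT
principle: compare each observed |t| to the null distribution of the
*maximum* |t| over the family, which respects the LD-induced correlation
between tests and is therefore less conservative than Bonferroni. The null
distribution is built by parametric bootstrap:

1. per SNP, fit the no-interaction null model (SNP + covariates +
   exposure) on that SNP's complete cases, keeping fitted values and the
   residual SD σ̂;
2. for each resample, simulate outcomes as null fitted values + Gaussian
   noise at σ̂ with genotypes, exposure and covariates held fixed, refit
   all interaction models, and record max |t*|;
3. adjusted p for SNP j = (1 + #{b : max_b ≥ |t_obs_j|}) / (1 + B).

Two choices here were genuinely open. First, the null model: the per-SNP
reduced model is the default (it tests the interaction coefficient
specifically while preserving the observed main-effect structure); a
shared covariates-only null is available as a switch. Second, the noise
coupling: one standard-normal vector per resample is *shared* across the
per-SNP null models, scaled by each SNP's σ̂ on its rows. Independent
per-SNP draws would decorrelate the simulated statistics and defeat the
point of maxT; sharing the draw preserves the inter-SNP dependence exactly
as the fixed genotypes induce it. Resamples are full-cohort parametric
draws (not case resampling), matching the parametric-bootstrap reading of
the procedure; the add-one convention avoids zero p-values. The reference
analysis used B = 10000; desk-scale runs here use B in the 400–2000 range,
which changes only the Monte-Carlo resolution of the adjusted p-values.

### EM haplotype phasing and sliding windows

Haplotype blocks are an *input* (they were identified by visual inspection
in the source analysis); the package ships pragmatic defaults — block 1 =
panel SNPs 4–10, block 2 = SNPs 13–18, the two groups of strongly
inter-correlated markers. Within a block, every contiguous window of width
≥ 1 is enumerated (w(w+1)/2 windows for a block of w SNPs), and each
window is phased by EM under random mating: the E-step weights each
individual's compatible diplotypes by products of current haplotype
frequencies, the M-step re-estimates frequencies from expected counts.
Initialization is the linkage-equilibrium point (deterministic, interior
to the simplex); convergence is max frequency change < 1e-6 with a
1000-iteration cap (window widths ≤ 10 keep the state space small), and
the log-likelihood is checked to be non-decreasing every iteration.
Phasing is per-window (whether the source collapsed block-wide phasings
per window is not stated; per-window EM is the simpler, self-contained
reading).

Association uses the posterior-*expected* haplotype dosage (fractional
copies, 0–2), not best-guess phase assignment; each tested haplotype is
regressed with the same covariates as the single-marker models, separately
by stratum. Only haplotypes with estimated frequency > 1% are tested; rare
haplotypes remain in the frequency model — the filter applies to tests,
not to the EM. Individuals with a missing genotype anywhere in a window
are excluded from that window only.

### Permutation of residuals for haplotype families

Because covariates are present, raw-outcome permutation would be
anticonservative; the Freedman-Lane scheme is used instead: fit the
reduced (covariates-only) model, permute its residuals (one shared
permutation per resample across the whole family), rebuild pseudo-outcomes
as reduced fitted values + permuted residuals, refit the full models, and
take max |t| over all windows/haplotypes in the block family. Adjusted
p-values use the same add-one convention. Units whose complete-case sets
differ (window-specific missingness) are aligned to the common
intersection, with a warning.

## The synthetic cohort generator

The generator's defaults *are* the study conditions: N = 5402; the 18-SNP
manifest at the published minor allele frequencies with the
smoking-increasing allele as effect allele; two LD blocks; smoking-category
probabilities per gender from the published strata counts (males
0.513/0.181/0.306, females 0.641/0.239/0.120 over non/light/heavy); sex
ratio 2592:2810; Gaussian outcomes with intercepts at the female
non-smoker strata means (BMI 24.0, SBP 120.8, DBP 75.4), male offsets from
the male strata (1.2, 10.3, 5.7) and residual SDs near the pooled
within-stratum SDs (4.2, 13.0, 11.3); a 95/5402 medication rate; and 0.5%
uniform genotype missingness, which reproduces the per-SNP varying
complete-case counts of the reference tables.

LD is generated by a two-locus haplotype-frequency construction chained
along each block: for each adjacent pair the disequilibrium coefficient D
is chosen to hit the target haplotype r² exactly (D = r·√(pA qA pB qB)),
and each chromosome's next allele is drawn from the implied conditional.
This gives exact control of adjacent-pair r² with a closed-form check
against realized chromosome counts. The attainable r² between two loci is
capped by their allele frequencies (D ≤ min(pA qB, qA pB)); a uniform
high target is therefore impossible across the panel's heterogeneous
frequencies, so the default design sets each block's target to 0.9 × the
minimum attainable bound over its adjacent pairs (~0.16 for both default
blocks), and explicit targets above the bound are rejected with the bound
in the error message. Correlation decays geometrically with distance along
the chain; across blocks SNPs are independent.

Phenotypes follow the linear-Gaussian model of the analysis, with
configurable per-SNP main effects and SNP-by-smoking interaction effects
(the planted ground truth travels with the cohort). Choices the source
leaves open, fixed once here: heavy smokers' cigarettes/day are uniform on
11–40 (only ">10" is stated); light smokers uniform on 1–10; 30% of
non-smokers are former smokers; BMI is an independent covariate for blood
pressure unless a `bmi_on_bp` coefficient is configured (the joint
BMI-BP distribution used by nature is unknown); recorded blood pressures
of medicated individuals are *lowered* by 15/10 mmHg so that the analysis
correction restores the latent scale. Two-subpopulation structure (allele
frequencies shifted by ±shift/2) supports stratification experiments.

What the generator does **not** emulate: coalescent-realistic
recombination and allele-frequency spectra, genome-wide panels,
relatedness, genotyping batch effects, non-Gaussian outcome tails, and any
dependence of missingness on genotype or phenotype. Passing tests
demonstrate the statistical machinery is correct under the stated model;
they do not certify behaviour under real-data pathologies excluded by
design (sample-level QC is assumed done upstream).

## Numerical and testing choices

* OLS is QR-based; rank deficiency is an error naming the collinear
  column. Repeated-refit paths (bootstrap, permutation) use a precomputed
  orthonormal basis and coefficient extractor, so each resample costs two
  matrix products.
* The EM is deterministic given data; random restarts are unnecessary at
  the window widths used (likelihood surfaces for ≤ 2^10 haplotypes from
  common variation are well behaved in practice) but the initialization is
  a single documented point, so any multimodality would be reproducible.
* Monomorphic SNPs return Hardy-Weinberg p = 1 by convention and are
  removed by the MAF filter.
* Degenerate strata (n ≤ number of model columns) yield flagged results,
  never silent drops.
* Pooled "headline" effects are unweighted means of per-SNP betas and of
  CI endpoints, rounded half-away-from-zero to 2 decimals. The endpoint
  mean reproduces the reference pooled intervals only to within 0.01
  (e.g. (−2.00, −0.41) vs the quoted (−2.01, −0.40) for SBP; (−0.67,
  −0.09) vs (−0.68, −0.08) for BMI), suggesting the quoted intervals came
  from a slightly different pooling; the discrepancy is documented rather
  than forced, and the pooled *betas* agree exactly.

## Problem sizes

The test suite and the acceptance script verify the statistical properties
at desk scale, the package's own working sizes: family-wise error rates
from 300–500 null cohorts of N = 1500–2000 with B = 400–500 resamples per
cohort (18-SNP bootstrap family; 10-window permutation family);
planted-effect recovery and CI coverage from 300–500 cohorts of
N = 4000–5000; oracle equivalences (normal equations, likelihood grid
search, single-test degeneracies) at tolerances 1e-10 to 1e-4. The
full-depth configuration (N = 5402, B = 10000) runs through exactly the
same code paths.

## Known limitations

* The LD chain is first-order: only adjacent-pair r² is controlled;
  longer-range r² follows geometrically and is not matched to any
  empirical pattern.
* Haplotype-block definitions are user inputs; no automated block
  detection (confidence-interval or four-gamete methods) is provided.
* Outcomes are strictly Gaussian; no robust or sandwich variances, no
  logistic/ordinal outcomes, no dominance coding.
* The PLINK text reader handles the two-allele .ped/.map dialect only; no
  binary .bed, no VCF.
* Imputation of untyped variants is out of scope; the panel is analysed
  as genotyped.
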