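---
title: "Models and methods in mixprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mixprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mixprs` implements a complete two-ancestry genetic-epidemiology workflow:
quality control, stratified dosage GWAS, random-effects pooling,
cohort-specific variant discovery, enrichment screens, and
thresholding-pruning / multiethnic polygenic risk scores, together with a
seeded generator that produces cohorts with the statistical structure the
downstream stages assume. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and the places where
the design was genuinely open.

## The synthetic cohort generator

**Genotypes.** A population is a set of independent linkage blocks. Every
variant in a block shares one base allele frequency (tightly linked
variants in real data have similar minor-allele frequencies), drawn
uniformly from `allele_freq_range` (default 0.05–0.5). Each of the two
strata, labelled "EA" and "AA" after the two sub-cohorts the workflow
targets, perturbs the base frequency by a Balding–Nichols beta draw with
divergence parameter `fst_divergence` (default 0.05, a typical
continental-scale F_ST). Each gamete is a thresholded latent Gaussian: a
block-level factor plus variant-level noise with exchangeable correlation
ρ, dichotomized at the frequency quantile, and a dosage is the sum of two
independent gametes, so dosages are exact allele counts in {0, 1, 2}. The
latent ρ is calibrated per block and stratum by numerically inverting the
tetrachoric relation (a 1-D integral of the bivariate-normal orthant
probability over the realized thresholds) so that the *mean pairwise
genotype r²* inside a block matches `within_block_r2`. When the
heterogeneous thresholds make the target unreachable the latent
correlation saturates rather than erroring. Variants in different blocks
are independent; blocks are placed 1 Mb apart so positional windows in
clumping behave sensibly.

This emulates what the analysis needs — tunable LD, frequency divergence,
stratum labels — and nothing more: there are no haplotype-scale LD decay
patterns, recombination maps, admixture tracts, or imputation-error
structure. Tests passing on these cohorts show the *statistics* behave as
designed, not that the generator reproduces any particular real
population.

**Phenotypes.** Quantitative traits follow
`y = √h² · g + Σ γ_c · c + √(1−h²) · ε`, where `g` is the causal genetic
value standardized *within stratum* (so h² holds in each stratum even when
allele frequencies diverge) and ε is standard normal. Causal effects are
drawn per stratum from a bivariate normal with correlation
`ancestry_effect_corr`; 1 gives a fully shared architecture, 0.3 the
partially shared architecture used to exercise the multiethnic scoring
path. Binary traits use the liability-threshold model: the same
construction defines a liability, standardized cohort-wide, and cases
exceed `qnorm(1 − prevalence)`. This is the standard device linking a
score's R² on the liability scale to odds-ratio stratification, which is
exactly the property the risk-stratification stage measures.

**Reference summary statistics.** Published-consortium statistics are
emulated at the marginal-effect level: for each variant the true marginal
(LD-including) effect of the standardized trait per dosage unit is
computed from the genotype panel and the causal effects, and the reported
effect is drawn with standard error `1/√(2f(1−f)·n_reference)` — the
large-sample SE of a standardized-trait regression slope. `n_reference`
defaults to 10^5–10^6 in the examples, which makes the reference
"well-powered" relative to a 10³-scale cohort, the regime the
specificity filter assumes. Monomorphic variants are emitted with missing
statistics rather than dropped, since real summary files contain such
rows.

**Clinical records.** Lipid panels are built so that total cholesterol
equals LDL + HDL + TG/5 in expectation, letting the Friedewald derivation
recover the target; each intended diabetes case is routed through at least
one adjudication criterion (HbA1c, diabetes-specific medication, or
related medication plus diagnosis), and statin flags generate baseline
lipid-lowering records so the exclusion rule has work to do.

## Quality control

Filters run in a fixed order with strict inequalities, and every removal
is attributed to the first failing filter: variant call rate < 0.95, MAF
< 0.01, exact Hardy–Weinberg p < 1e-5; sample call rate < 0.90, sex
mismatch, pi-hat > 0.9. Boundary values are kept. The HWE test is the
exact conditional test on the heterozygote count, computed in log space
and summing all configurations no more probable than the observed one; it
matches brute-force enumeration on all tables with n ≤ 20 and is
conservative under the null. HWE is tested on hard-called genotypes
(nearest integer within 0.1, else missing) within each ancestry stratum —
pooling strata would flag Wahlund-style heterozygote deficits that are
structure, not genotyping error.

Relatedness is method-of-moments IBD from identity-by-state counts. The
expected IBS-state probabilities treat the pair's four (IBD 0), three
(IBD 1) or two alleles as draws *without replacement* from the 2N observed
alleles; this finite-sample correction removes the upward bias that
plugging sample frequencies into the infinite-population formulas causes
at small n. Estimates are clipped to [0, 1]; of a flagged pair the member
with the lower call rate is removed, ties going to the lexicographically
larger id (a deterministic rule; the choice is arbitrary but must be
fixed for reproducibility). Principal components are the unit-norm left
singular vectors of the centered, `√(2f(1−f))`-scaled dosage matrix, with
the sign fixed so each component's largest-magnitude variant loading is
positive; an optional interval (an MHC/HLA analog) is dropped first.

## Association and meta-analysis

The linear path residualizes the trait and all dosages on the covariate
design once (Frisch–Waugh) — algebraically identical to per-variant OLS,
orders of magnitude faster, and exact to the `lm` oracle in tests. The
logistic path fits each variant by IRLS with at most 50 iterations at
tolerance 1e-8; non-convergence yields a missing record, counted.
P-values use the normal reference for the Wald z in both paths, keeping
`p` consistent with `beta/se` across the whole output. Missing dosages
are mean-imputed; monomorphic variants are skipped and counted.

Cross-stratum pooling is DerSimonian–Laird: the classical closed-form
moment estimator of τ², chosen over REML-type iterative estimators
because it is the historical default of standard meta-analysis software
and is testable by hand arithmetic; whenever Q ≤ k−1 it reduces exactly
to fixed-effects pooling. Allele harmonization matches variants on
chromosome and position, flips swapped alleles (negating β, reflecting
eaf), resolves strand flips by complement, and drops strand-ambiguous
A/T and C/G variants when eaf lies in (0.4, 0.6); outside that band the
orientation whose frequency is closer to the reference is used. The
operation is idempotent.

## Cohort-specific discovery

A variant is cohort-specific when cohort p < 0.01, reference p ≥ 0.05,
and the 99% confidence intervals `β ± 2.5758293·se` are disjoint;
intervals sharing even an endpoint count as overlapping (the conservative
reading). The two sources must be on a comparable effect scale; the
pipeline standardizes quantitative traits (per-SD trait, per-dosage
allele) before the cohort GWAS so its betas match the reference's
standardized scale. Specific calls are clumped greedily by ascending p
(ties by position, then id) into loci with a 500 kb window and r² > 0.5
join rule. Gene-set screening is a one-sided Fisher over-representation
test against user-supplied GMT libraries with BH adjustment — a local
replacement for web-service enrichment tools, identical in its 2×2
construction. The eQTL screen first excludes variants with reference
p < 1e-6 (their reference signal makes "cohort-specific" moot), LD-prunes
at r² > 0.2, then compares eSNP proportions between specific and
remaining variants with a 1-df chi-squared test without continuity
correction (matching the large-count regime), falling back to Fisher's
exact test, flagged, when a cell is empty.

## Polygenic risk scores

Thresholding-pruning: variants with reference p below each threshold in
1e-1 … 1e-8 are LD-pruned greedily (removal at r² ≥ 0.5, priority by
ascending p) and their harmonized betas become weights. Scoring is the
dosage-weight inner product with REF-oriented weights flipping the dosage
and missing dosages mean-imputed at 2·eaf — the behavior of standard
scoring tools, keeping scores comparable across samples.

The multiethnic score is `α₁·PRS_EA + α₂·PRS_AA` with α̂ the two score
coefficients from a linear regression of the phenotype on both scores
plus covariates. The weights are unconstrained — a negative weight is
informative, not an error. Performance is the *incremental* adjusted R²
of the two scores over the covariate-only model,
`1 − (1−R²)(n−1)/(n−k−1)` with k = 2 (k = 1 for single-score
comparators): with covariates like age and sex in the model, total R²
would be dominated by them and mask what the scores add. Near-collinear
scores (|r| > 0.999) fall back to the single-score model, flagged.

Cross-validation uses ten folds, stratified by case status for binary
traits so every fold preserves the case:control ratio (a fold with zero
cases is an error naming the fold, not a silent skip). Per fold the
target-stratum GWAS runs on the training 90% — with principal components
computed on the target stratum only, since reference-ancestry PCs would
not capture the target's structure — and mixing weights are fitted on the
held-out 10%. Folds, and hence all downstream numbers, are a
deterministic function of the seed.

Risk stratification takes the top q ∈ {5%, …, 30%} of each score (ties at
the cutoff included, so the top group may slightly exceed q·n), forms the
2×2 disease table, and reports the cross-product odds ratio with a Wald
95% CI on the log scale, adding the Haldane–Anscombe 0.5 to every cell
(and flagging the row) when any cell is zero. The raw 2×2 is the primary
definition — it matches "prevalence among the top-scoring group" — and a
covariate-adjusted logistic alternative can be read off
`prs_phenotype_matrix`. BH adjustment runs across all (score, fraction)
tests per disease.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; stage seeds are derived
  from one global seed by a stable hash, so partial pipeline reruns
  reproduce bit-identical outputs (verified by MD5 in the run manifest).
* The HWE test works in log space with a max-subtraction, so counts in
  the thousands do not overflow.
* Probability comparisons in the exact test use a 1 + 1e-12 relative
  slack to make "no more probable than observed" robust to rounding.
* Empty strata are omitted with a warning; an all-variants-removed QC
  result is an error carrying the per-filter report.
* Dosages are validated into [0, 2] at container construction.

## Problem sizes

The test suite and the acceptance script run, by design, at desk scale:
null calibrations at 2000 variants × 1000 samples and 500 replicates,
weight recovery at n = 3000, cross-validation at 1200 target samples ×
120 variants over 10 seeds, stratification at 2000 samples over 50
phenotype draws. These sizes put Monte-Carlo noise well inside the
asserted tolerances while keeping the whole suite in minutes.

## Limitations

* The generator's LD is exchangeable within blocks — no decay with
  distance — so window-based clumping is exercised only coarsely.
* Reference summary statistics are simulated at the marginal-effect
  level; they do not model imputation quality, allele-frequency
  mismatch between the reference panel and its GWAS sample, or
  between-study heterogeneity inside the reference.
* The specificity filter's CI-disjointness criterion assumes both
  sources' betas are on the same scale; feeding it unstandardized cohort
  effects against standardized reference effects will silently produce
  nonsense. The pipeline standardizes, but direct callers must too.
* MI-style outcomes enter as labels; no event adjudication beyond the
  diabetes rule is modelled.
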