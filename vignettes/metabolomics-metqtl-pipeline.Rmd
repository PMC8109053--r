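---
title: "From batch-structured intensities to phenotype-driven network modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From batch-structured intensities to phenotype-driven network modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlnet)
```

## The analysis problem

Untargeted plasma metabolomics in a COPD cohort produces a sample x
metabolite intensity table with three structural nuisances — multiplicative
run-day (batch) variation from instrument inter-day tuning, missing cells,
and occasional aberrant subjects — alongside three scientific questions:

1. which metabolites are associated with COPD phenotypes (FEV1 percent
   predicted, FEV1/FVC, percent emphysema, exacerbation frequency, chronic
   bronchitis)?
2. how much metabolite variance is genetic — which SNPs are metabolite
   quantitative trait loci (met-QTLs), how many independent signals exist
   per metabolite, and how does the genetic share compare with the
   clinical/environmental share?
3. do *sets* of partially correlated metabolites associate with phenotypes
   even when no single member does — i.e., does aggregating co-abundant
   metabolites buy statistical power?

`mqtlnet` implements the full chain, and ships a synthetic-cohort
generator with a planted-effect truth registry so every stage has a
recovery test.

## Pre-analysis chain

The QC order is fixed and enforced by a stage tag on the abundance
container: run-day normalization, then missingness filtering, then
imputation, then outlier removal, then transformation.

**Run-day normalization.** Each intensity is divided by its metabolite's
run-day median and multiplied by the metabolite's overall median (missing
cells excluded from all medians; even-count medians are the midpoint of
the two central order statistics). This removes a per-day multiplicative
factor exactly at the median. A caveat the tests respect: because the day
medians are *estimated from the data*, a naive one-way ANOVA of a null
metabolite on run day after normalization is conservative (p-values pile
near 1), not uniform — the estimated day effects absorb degrees of freedom
the F test does not know about. The meaningful property, which the tests
assert, is that no residual batch signal remains while a planted
`runday_scale >= 0.2` factor is detected with p < 0.01 before correction.

**Missingness filter.** Metabolites missing in strictly more than 20% of
samples are removed; a metabolite at exactly 20% is kept.

**kNN imputation (k = 10).** Neighbors are metabolites, distance is the
root-mean-square difference over samples where both metabolites are
observed (scaling by the shared-sample count makes pairs with different
overlap comparable). A missing cell takes the unweighted mean of its k
nearest metabolites' values at that sample; if none of the k neighbors is
observed there, the metabolite's own mean is used and the fallback is
logged. Imputation happens after normalization and before outlier
removal.

**Outlier subjects.** Metabolites are z-scored across subjects; each
subject's aggregate is the *median* of its z-scores; these medians are
standardized and subjects beyond 3.5 SD are removed. The default is
two-sided (`|z| > 3.5`): a subject whose intensities are globally
suppressed is as suspect as an inflated one; a one-sided flag is
available. With fewer than three subjects the standardization is
degenerate and nothing is removed.

**Inverse normal transform.** Blom scores
`qnorm((rank - 3/8) / (n + 1/4))`, average ranks for ties. The offset is
configurable; 3/8 is the common metabolomics default. After this step the
marginal distribution of every metabolite is standard normal up to
rank discreteness, which is why the generator's log-normal choice of raw
intensity marginal is immaterial downstream.

## Phenotype associations

Model families follow the phenotype's type: linear regression with the
*metabolite as response* for the three continuous phenotypes; logistic
regression with the phenotype as response and the metabolite as predictor
for chronic bronchitis; negative binomial (Poisson fallback when the
dispersion fit fails) for exacerbation counts. The default covariate set
is age, sex, BMI, current smoking, pack-years and clinical center,
configurable per phenotype. Significance is Bonferroni within phenotype
over the number of metabolites: with 995 metabolites the threshold is
`0.05/995 = 5.03e-5`. Non-converged GLMs yield a record with missing p
and a convergence flag rather than a silent drop.

`cohort_table_tests()` reproduces demographics-table group comparisons:
Pearson chi-square without continuity correction for binary traits
(excluding the missing-spirometry column, which is what reproduces the
published Discovery-table p-values), and one-way ANOVA reconstructed
exactly from per-group n/mean/SD for continuous traits.

## Met-QTL scan, conditioning, variance decomposition

The scan residualizes both the transformed metabolite matrix and the
dosage matrix on the covariate design (clinical covariates plus ancestry
PCs, default 5) and tests the residual correlation with
`df = n - 1 - rank(design)`. By the Frisch–Waugh theorem this equals the
per-pair full regression exactly — the tests assert agreement with the
brute-force oracle to 1e-10 — while costing one matrix product for the
whole grid. Genome-wide significance is `alpha / (n_metabolites x n_snps)`.
Missing dosages are mean-imputed per SNP for the scan; conditioning
refits are complete-case. SNPs with MAF at or below 1% are removed first,
frequencies computed from the analysis sample.

Recursive conditioning mirrors the stepwise selection used for
independent association signals: admit the top SNP; then, with T
remaining candidates, refit `metabolite ~ candidate + admitted + covariates`
for each and admit the best candidate only while its conditional p beats
`0.05/T`. Perfect-LD candidates alias in the refit and are dropped with a
log entry; p ties break on (chromosome, position, id) so reruns are
identical. Ancestry PCs are kept in the conditioning covariates by
default for consistency with the scan (a flag restores the shorter
clinical-only list).

Variance decomposition reports the covariate-only r-squared next to per-SNP
increments from nested genotype-only models in admission order (top SNP
first), so a metabolite with two independent signals shows two positive
increments that sum to the joint genetic r-squared when the SNPs are
uncorrelated. Incremental (not marginal) r-squared is the default for
secondary SNPs; marginal values are recoverable by calling
`variance_explained()` per SNP.

## The Gaussian graphical model and module search

With roughly as many metabolites as samples the sample correlation matrix
is ill-conditioned, so the GGM uses a Schaefer–Strimmer analytic shrinkage
of the correlation matrix toward the identity; the data-driven intensity
is recorded in the network metadata. Full-order partial correlations come
from the inverse of the shrunk matrix. Edge p-values use the Fisher z
transform with effective df `n - 3`; the conditioning count is *not*
subtracted because shrinkage invalidates the classical df — this is an
approximation, stated as such. An edge requires both
`p < alpha / denominator` and partial correlation strictly above 0.2;
negative partial correlations are never edged (they are typically
artifacts of the conditioning). The Bonferroni denominator defaults to
the square of the metabolite count, switchable to the pair count
n(n-1)/2; the printed test count in the source analysis reads as the
squared convention.

One consequence worth knowing: the shrinkage intensity is the ratio of
the summed sampling variance of the correlations to their summed squared
magnitude. In a data set where most metabolite pairs are uncorrelated the
intensity approaches 1 and the `pcor > 0.2` rule then admits no edges at
all — correct behavior for a null metabolome, but it means network tests
must be run on cohorts with realistic block-correlation structure, which
is what the generator's planted modules provide.

The greedy module search follows the phenotype-driven
candidate-expansion algorithm: each metabolite node seeds a module; at
every step the best graph neighbor (by the score of the averaged profile
against the covariate-residualized phenotype; score = -log10 p) is
admitted only if the extended module strictly beats both the current
module score and every single member's score. Expansion admits one
neighbor per iteration; ties break on metabolite order, and the tests
assert invariance of the returned member sets to column permutation.
After all seeds run, modules are Bonferroni-corrected over the number of
seeds — the search initiates one candidate test per seed; the published
"adjusted score" does not name its correction, so this is a documented
package choice, not an assertion about the source — and overlapping
significant modules merge by union when the merged profile still beats
every member, otherwise the higher-scoring module survives. Module-level
genetics are summarized by the first principal component of the members
(sign fixed so the mean loading is non-negative; r-squared is sign-invariant)
regressed on the members' independent met-QTL SNPs and, separately, on
the clinical covariates.

## Enrichment

Over-representation of significant features in annotation groups
(metabolite subpathways, SNP consequence classes) uses the upper-tail
hypergeometric test — the one-tailed Fisher's exact direction implied by
"enrichment" — with Benjamini–Hochberg correction across groups at
alpha 0.05. Unannotated features form their own group; groups smaller
than two are reported but flagged underpowered rather than dropped.

## What the synthetic cohort emulates

The generator draws each metabolite's latent value as an orthogonal
variance-budgeted mixture: planted SNP effects (`beta = sqrt(r2)` on the
standardized dosage, so the target variance-explained fraction is exact
in expectation), covariate effects, a shared factor per planted module
(intra-module correlation `rho`), and Gaussian noise. Budgets summing to
one or more are rejected at configuration time naming the offending
metabolite. Latents are exponentiated (log-normal intensities), scaled by
a per-run-day multiplicative factor (per-(day, metabolite) factors via a
flag), masked missing-at-random, and outlier subjects are shifted +6
latent SD on a random 80% of metabolites so the median-z detector can
find them. Phenotypes derive from latent models matched to the
association families — linear for the spirometric and CT phenotypes,
log-linear Poisson for exacerbations, logistic for chronic bronchitis —
with planted module-phenotype correlations parameterized as the
*per-member* standardized correlation. Genotypes are binomial(2, EAF);
LD exists only as optional pairwise correlates (sufficient to exercise
conditioning), not as realistic haplotype structure.

What it does **not** emulate: heavy-tailed or structured missingness
(missingness is MCAR; real dropout is intensity-dependent),
platform-specific peak artifacts, realistic LD and allele-frequency
spectra, population stratification (the ancestry PCs are pure noise), or
annotation error. Passing recovery tests therefore demonstrates
correctness of the estimators under the model's assumptions, not
robustness to everything real data can do.

## Numerical choices and problem sizes

Defaults: missingness cutoff 0.20; k = 10 neighbors; outlier cutoff 3.5
SD two-sided; Blom offset 3/8; MAF cutoff 0.01; 5 ancestry PCs;
`pcor_min = 0.2`; per-metabolite sub-threshold record cap 100. Scan ties
and module-expansion ties break deterministically as described above.
Degenerate inputs are handled explicitly: zero-variance metabolites get
zero z-scores (warned), constant columns transform to zeros (warned),
monomorphic SNPs are skipped (logged), rank-deficient covariate designs
error naming the collinear columns.

The test and acceptance workloads run at desk scale by design: oracle
comparisons at n = 50, recovery at n = 1000–2000 subjects with tens of
metabolites, calibration over 50–100 replicate cohorts, and an
end-to-end run at 500 subjects x 150–200 metabolites x 1000–2000 SNPs.
These sizes keep every property computable in seconds to a few minutes
while leaving the estimators in their asymptotic regime.

## Known limitations

- Edge p-values after shrinkage are approximate (Fisher z, df `n - 3`);
  an empirical permutation null is the alternative when exact error
  control on edges matters.
- The greedy search maximizes the score during expansion, so the final
  module p-value is mildly optimistic for multi-member modules; the
  Bonferroni-over-seeds correction absorbs this in the null calibrations
  we run, but it is not a proof of family-wise control.
- Negative-binomial fits on short count vectors can fail to converge;
  such records carry a missing p and a flag rather than a value.
- r-squared recovered from rank-transformed abundances is slightly
  attenuated relative to the latent target (a monotone-transform
  effect familiar from Spearman-vs-Pearson comparisons); recovery tests
  use bounds wide enough to cover this.
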