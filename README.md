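# mqtlnet

Metabolite QTL mapping and phenotype-driven network modules for plasma
metabolomics cohorts.

`mqtlnet` is aimed at analysts working with untargeted plasma metabolomics
in clinical cohorts — the motivating setting is COPD (spirometric airflow
obstruction, percent emphysema, exacerbations, chronic bronchitis) with
genome-wide genotype dosages available on the same subjects. It covers the
whole path from a batch-structured raw intensity table to an integrated
gene–metabolite–phenotype network:

1. **Pre-analysis**: run-day median normalization
   (`x * median_overall / median_day`), removal of metabolites missing in
   more than 20% of samples, k-nearest-neighbor imputation across
   metabolites (k = 10), removal of subjects whose standardized median
   metabolite z-score exceeds 3.5 SD, and the rank-based inverse normal
   transform with Blom offset, `Φ⁻¹((r − 3/8)/(n + 1/4))`.
2. **Phenotype associations**: per-metabolite regressions with
   phenotype-matched families (linear / logistic / negative binomial),
   covariate adjustment, and Bonferroni significance within phenotype
   (`0.05/995 = 5.03e-5` at the reference metabolome size). Cohort-table
   group tests (chi-square from counts, one-way ANOVA reconstructed from
   n/mean/SD) are included.
3. **Met-QTL scan**: for every (SNP, metabolite) pair, the additive
   linear-model t-test computed by residualizing both sides on the
   covariate design (clinical covariates + ancestry PCs) — exactly equal
   to the per-pair regression, at matrix-product cost. Genome-wide
   Bonferroni over the full grid (`0.05/(995 × 7,641,295) = 6.6e-12` at
   reference scale), MAF > 1% filter.
4. **Recursive conditioning**: admit the top SNP per metabolite, then
   iteratively admit the best remaining candidate while its conditional
   p-value (refit with all admitted SNPs and covariates) beats `0.05/T`,
   `T` the number of remaining candidates — yielding independent met-QTL
   loci. Variance decomposition reports covariate-only r² next to
   per-SNP incremental r² in admission order.
5. **Network and modules**: a Gaussian graphical model on
   covariate-residualized metabolites using Schaefer–Strimmer shrinkage of
   the correlation matrix; edges require positive partial correlation
   above 0.2 and Fisher-z significance after Bonferroni correction;
   independent met-QTL SNPs enter as typed SNP nodes. A greedy
   phenotype-driven search grows modules by averaging neighbor profiles,
   admitting a neighbor only when the module score (−log₁₀ p against the
   covariate-residualized phenotype) strictly beats every single member;
   overlapping modules merge; module genetics are summarized by the first
   PC regressed on member met-QTL SNPs versus clinical covariates.
6. **Enrichment**: one-tailed (upper-tail hypergeometric) Fisher tests of
   annotation groups with Benjamini–Hochberg correction.

A synthetic-cohort generator (`simulation_config()` / `generate_cohort()`)
plants SNP effects of exact target variance-explained, correlated
metabolite modules, covariate effects, batch factors, outliers and
missingness, and returns a truth registry, so every stage of the pipeline
has a recovery test.

## Worked example

```r
library(mqtlnet)

# a 500-subject cohort: one strong met-QTL (50% variance explained),
# one fev1pp-associated module, and a block of correlated null modules
mods <- c(list(list(members = 5:8, rho = 0.7, phenotype = "fev1pp", effect = 0.2)),
          lapply(0:7, function(k) list(members = 20 + 3*k + 0:2, rho = 0.65,
                                       phenotype = "fev1_fvc", effect = 0)))
cohort <- generate_cohort(simulation_config(
  n_subjects = 500, n_metabolites = 100, n_snps = 500, n_rundays = 8,
  missing_rate = 0.04, n_outlier_subjects = 2,
  planted_qtls = data.frame(metabolite = 1, snp = 10, eaf = 0.64, r2 = 0.50),
  planted_modules = mods, seed = 2026))

qc <- qc_preprocess(cohort$abundance)
qc$report$subjects_removed
#>   sample median_z
#> 1  S0115 14.86512
#> 2  S0136 16.60274      # the two planted outlier subjects

scan <- metqtl_scan(qc$abundance, maf_filter(cohort$dosage), cohort$covariates)
subset(scan$records, significant)
#>       snp metabolite  beta     se        p    r2 significant
#> 2 rs00010       M001 0.994 0.0516 6.99e-62 0.437        TRUE

y <- setNames(qc$abundance$values[, "M001"], rownames(qc$abundance$values))
variance_explained(y, cohort$dosage, "rs00010", cohort$covariates[, 1:6])
#> variance decomposition: covariates 0.022; SNPs rs00010=0.437; remainder 0.554

net <- estimate_ggm(qc$abundance, cohort$covariates[, 1:6])
#> 100 nodes, 26 edges (shrinkage intensity 0.45)

ph  <- setNames(cohort$phenotypes$fev1pp, rownames(cohort$phenotypes))
df  <- data.frame(y = ph, cohort$covariates[names(ph), 1:6])
res <- setNames(resid(lm(y ~ ., df)), names(ph))
greedy_module_search(net, qc$abundance, res, phenotype_name = "fev1pp")
#> phenotype_modules (fev1pp): 1 significant module(s) from 100 seeds
#>   phenotype module_id             members n_members       beta            p
#> 1    fev1pp         1 M005,M006,M007,M008         4 0.01005417 1.575297e-06
#>      score adjusted_score
#> 1 5.802638   0.0001575297
```

The planted outliers are removed; the planted met-QTL is genome-wide
significant with r² ≈ 0.44 (the slight attenuation from the 0.50 target is
the rank-transform effect); and the module search returns exactly the four
planted module members, each of which falls short of the single-metabolite
threshold on its own — the power gain from aggregating co-abundant
metabolites.

`run_pipeline(run_config(...))` chains all stages from files on disk
(abundance TSV, phenotype/covariate TSV, genotype TSV or VCF) and writes
every intermediate table plus a run report;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

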