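# shared fixture builders; everything is generated in code at test time

make_abundance <- function(values, runday = NULL, stage = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
  if (is.null(runday)) runday <- rep("D1", nrow(values))
  abundance_matrix(values, runday, stage = stage)
}

# a small latent-Gaussian matrix pushed through the whole QC chain
transformed_abundance <- function(values) {
  m <- make_abundance(values, stage = "imputed")
  inverse_normal_transform(m)
}

# standard small cohort used across module tests
small_cohort <- function(seed = 11, n = 300, missing_rate = 0, ...) {
  generate_cohort(simulation_config(
    n_subjects = n, n_metabolites = 40, n_snps = 60, n_rundays = 3,
    missing_rate = missing_rate, seed = seed, ...))
}

pheno_residuals <- function(cohort, phenotype, covariates = NULL) {
  y <- cohort$phenotypes[[phenotype]]
  names(y) <- rownames(cohort$phenotypes)
  if (is.null(covariates)) return(y - mean(y))
  df <- data.frame(y = y, covariates[names(y), , drop = FALSE])
  stats::setNames(stats::resid(stats::lm(y ~ ., data = df)), names(y))
}
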