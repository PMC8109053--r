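#' Synthetic cohort configuration
#'
#' Describes a synthetic plasma-metabolomics cohort with planted,
#' recoverable effects. Metabolite latents are standard-normal mixtures of
#' orthogonal components (SNP effects, covariate effects, shared module
#' factors, noise) with an explicit variance budget per metabolite;
#' intensities are log-normal (latent exponentiated) and multiplied by a
#' per-run-day batch factor.
#'
#' @param n_subjects,n_metabolites,n_snps,n_rundays cohort dimensions (all
#'   positive).
#' @param missing_rate fraction of cells masked missing-at-random, in
#'   \[0, 1).
#' @param n_outlier_subjects number of subjects shifted +6 latent SD on a
#'   random 80% of metabolites.
#' @param planted_qtls data frame with columns `metabolite` (index), `snp`
#'   (index), `eaf` in (0.01, 0.99) and `r2` (target variance-explained
#'   fraction in \[0, 1)).
#' @param planted_modules list of lists with fields `members` (metabolite
#'   indices), `rho` (intra-module correlation in (0, 1)), `phenotype`
#'   (one of the phenotype names) and `effect` (per-member standardized
#'   correlation between member metabolites and the phenotype latent).
#' @param covariate_effects named numeric vector mapping a covariate
#'   (`age`, `sex`, `bmi`, `current_smoker`, `pack_years`) to the target
#'   per-metabolite variance fraction it explains in affected metabolites.
#' @param covariate_fraction fraction of metabolites affected by each
#'   entry of `covariate_effects`; default 0.4, matching the scale of
#'   demographic associations typically seen in plasma metabolomes.
#' @param runday_scale log-SD of the multiplicative run-day factor.
#' @param per_metabolite_runday draw a separate day factor per metabolite
#'   (default: one factor per day).
#' @param ld_pairs optional data frame (`snp1`, `snp2`, `r`) forcing SNP
#'   `snp2` to be a correlate of `snp1` with approximate correlation `r`
#'   (exact copy when `r` is 1); used to exercise conditional analysis.
#' @param seed integer seed; identical configs generate bit-identical
#'   cohorts.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 500, n_metabolites = 200,
                              n_snps = 500, n_rundays = 8,
                              missing_rate = 0.05, n_outlier_subjects = 0,
                              planted_qtls = NULL, planted_modules = list(),
                              covariate_effects = numeric(),
                              covariate_fraction = 0.4,
                              runday_scale = 0.1,
                              per_metabolite_runday = FALSE,
                              ld_pairs = NULL, seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_metabolites = n_metabolites,
              n_snps = n_snps, n_rundays = n_rundays)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (is.null(planted_qtls))
    planted_qtls <- data.frame(metabolite = integer(), snp = integer(),
                               eaf = numeric(), r2 = numeric())
  stopifnot(all(c("metabolite", "snp", "eaf", "r2") %in% names(planted_qtls)))
  if (nrow(planted_qtls)) {
    if (any(planted_qtls$metabolite < 1 | planted_qtls$metabolite > n_metabolites))
      stop("planted QTL metabolite index out of range")
    if (any(planted_qtls$snp < 1 | planted_qtls$snp > n_snps))
      stop("planted QTL SNP index out of range")
    if (any(planted_qtls$eaf <= 0.01 | planted_qtls$eaf >= 0.99))
      stop("planted effect-allele frequencies must lie in (0.01, 0.99)")
  }
  for (mod in planted_modules) {
    stopifnot(all(c("members", "rho", "phenotype", "effect") %in% names(mod)))
    if (any(mod$members < 1 | mod$members > n_metabolites))
      stop("planted module member index out of range")
    if (mod$rho <= 0 || mod$rho >= 1)
      stop("intra-module correlation must lie in (0, 1)")
  }
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_metabolites = as.integer(n_metabolites),
         n_snps = as.integer(n_snps), n_rundays = as.integer(n_rundays),
         missing_rate = missing_rate,
         n_outlier_subjects = as.integer(n_outlier_subjects),
         planted_qtls = planted_qtls, planted_modules = planted_modules,
         covariate_effects = covariate_effects,
         covariate_fraction = covariate_fraction,
         runday_scale = runday_scale,
         per_metabolite_runday = per_metabolite_runday,
         ld_pairs = ld_pairs, seed = as.integer(seed)),
    class = "simulation_config")
  # variance budget check (worst case: every covariate effect assigned)
  budget <- rep(sum(covariate_effects), n_metabolites)
  if (nrow(planted_qtls))
    for (i in seq_len(nrow(planted_qtls)))
      budget[planted_qtls$metabolite[i]] <-
        budget[planted_qtls$metabolite[i]] + planted_qtls$r2[i]
  for (mod in planted_modules)
    budget[mod$members] <- budget[mod$members] + mod$rho
  if (any(budget >= 1))
    stop(sprintf(
      "infeasible variance budget for metabolite %d (fractions sum to %.2f >= 1)",
      which.max(budget), max(budget)))
  cfg
}

phenotype_names <- c("fev1pp", "fev1_fvc", "pct_emphysema",
                     "exacerbation_count", "chronic_bronchitis")

#' Generate a synthetic cohort
#'
#' Draws genotypes binomial(2, EAF), builds metabolite latents from the
#' config's variance budget, maps latents to log-normal intensities with a
#' multiplicative run-day factor, masks cells missing-at-random, shifts
#' outlier subjects, and derives the five COPD phenotypes from latent
#' Gaussian/log-linear/logistic models so that downstream GLM families are
#' correctly specified.
#'
#' @param config a [simulation_config()].
#' @return list with components `abundance` (stage `raw`), `dosage`,
#'   `covariates`, `phenotypes`, `annotation` (metabolite super/subpathway
#'   labels) and `truth` (the planted-effect registry, see
#'   [truth_report()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$n_metabolites
  s <- config$n_snps
  sid <- sprintf("S%04d", seq_len(n))
  mid <- sprintf("M%03d", seq_len(p))
  snp_id <- sprintf("rs%05d", seq_len(s))

  ## covariates
  cov <- data.frame(
    age = round(pmin(pmax(stats::rnorm(n, 68, 8), 45), 90)),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = round(pmax(stats::rnorm(n, 29, 6), 16), 1),
    current_smoker = stats::rbinom(n, 1, 0.21),
    pack_years = round(pmax(stats::rnorm(n, 46, 25), 0), 1),
    center = factor(sample(c("A", "B"), n, replace = TRUE)),
    row.names = sid)
  pcs <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(sid, paste0("PC", 1:5)))
  cov <- cbind(cov, pcs)

  ## genotypes
  eaf <- stats::runif(s, 0.05, 0.95)
  if (nrow(config$planted_qtls))
    eaf[config$planted_qtls$snp] <- config$planted_qtls$eaf
  G <- vapply(seq_len(s), function(j) stats::rbinom(n, 2, eaf[j]),
              numeric(n))
  dimnames(G) <- list(sid, snp_id)
  if (!is.null(config$ld_pairs)) {
    for (i in seq_len(nrow(config$ld_pairs))) {
      a <- config$ld_pairs$snp1[i]; b <- config$ld_pairs$snp2[i]
      r <- config$ld_pairs$r[i]
      keep <- stats::runif(n) < r
      G[keep, b] <- G[keep, a]
    }
  }
  consequence_classes <- c("intron", "intergenic", "missense", "3_prime_UTR",
                           "upstream_gene", "downstream_gene", "synonymous")
  info <- data.frame(
    snp = snp_id,
    chrom = sort(sample(1:22, s, replace = TRUE)),
    pos = NA_integer_,
    effect_allele = sample(c("A", "C", "G", "T"), s, replace = TRUE),
    other_allele = sample(c("A", "C", "G", "T"), s, replace = TRUE),
    eaf = eaf,
    consequence = sample(consequence_classes, s, replace = TRUE,
                         prob = c(0.55, 0.2, 0.05, 0.05, 0.06, 0.06, 0.03)),
    gene = sprintf("GENE%03d", sample(100, s, replace = TRUE)))
  info$pos <- as.integer(stats::ave(seq_len(s), info$chrom,
                                    FUN = function(i) seq_along(i) * 1e4))
  info$other_allele[info$other_allele == info$effect_allele] <- "T"
  info$other_allele[info$other_allele == info$effect_allele] <- "G"

  ## variance budget per metabolite
  v_qtl <- matrix(0, nrow(config$planted_qtls), 1)
  covvars <- names(config$covariate_effects)
  cov_assign <- list()
  for (cv in covvars) {
    n_aff <- max(1L, floor(config$covariate_fraction * p))
    cov_assign[[cv]] <- sort(sample(p, n_aff))
  }
  z_cov <- lapply(covvars, function(cv) as.numeric(scale(as.numeric(cov[[cv]]))))
  names(z_cov) <- covvars

  module_factor <- lapply(config$planted_modules,
                          function(mod) stats::rnorm(n))

  ## latent construction
  L <- matrix(0, n, p, dimnames = list(sid, mid))
  used <- rep(0, p)
  Gz <- scale(G)
  if (nrow(config$planted_qtls)) {
    for (i in seq_len(nrow(config$planted_qtls))) {
      q <- config$planted_qtls[i, ]
      L[, q$metabolite] <- L[, q$metabolite] + sqrt(q$r2) * Gz[, q$snp]
      used[q$metabolite] <- used[q$metabolite] + q$r2
    }
  }
  cov_truth <- list()
  for (cv in covvars) {
    r2c <- config$covariate_effects[[cv]]
    sgn <- sample(c(-1, 1), length(cov_assign[[cv]]), replace = TRUE)
    for (k in seq_along(cov_assign[[cv]])) {
      j <- cov_assign[[cv]][k]
      L[, j] <- L[, j] + sgn[k] * sqrt(r2c) * z_cov[[cv]]
      used[j] <- used[j] + r2c
    }
    cov_truth[[cv]] <- data.frame(metabolite = mid[cov_assign[[cv]]],
                                  covariate = cv, r2 = r2c,
                                  sign = sgn)
  }
  for (mi in seq_along(config$planted_modules)) {
    mod <- config$planted_modules[[mi]]
    f <- module_factor[[mi]]
    L[, mod$members] <- L[, mod$members] + sqrt(mod$rho) * scale(f)[, 1]
    used[mod$members] <- used[mod$members] + mod$rho
  }
  noise_var <- 1 - used
  L <- L + sweep(matrix(stats::rnorm(n * p), n, p), 2, sqrt(noise_var), `*`)

  ## realized QTL r2 on the clean latent (before outliers/noise masking)
  qtl_truth <- config$planted_qtls
  if (nrow(qtl_truth)) {
    qtl_truth$metabolite_id <- mid[qtl_truth$metabolite]
    qtl_truth$snp_id <- snp_id[qtl_truth$snp]
    qtl_truth$realized_latent_r2 <- vapply(seq_len(nrow(qtl_truth)),
      function(i) stats::cor(G[, qtl_truth$snp[i]],
                             L[, qtl_truth$metabolite[i]])^2, 0)
  }

  ## phenotypes from latent models
  ph_load <- stats::setNames(rep(0, length(phenotype_names)), phenotype_names)
  ph_latent <- matrix(0, n, length(phenotype_names),
                      dimnames = list(sid, phenotype_names))
  loads <- stats::setNames(vector("list", length(phenotype_names)),
                           phenotype_names)
  for (ph in phenotype_names) loads[[ph]] <- numeric(0)
  for (mi in seq_along(config$planted_modules)) {
    mod <- config$planted_modules[[mi]]
    c_load <- mod$effect / sqrt(mod$rho)  # per-member corr = effect
    loads[[mod$phenotype]] <- c(loads[[mod$phenotype]], c_load)
    ph_latent[, mod$phenotype] <- ph_latent[, mod$phenotype] +
      c_load * scale(module_factor[[mi]])[, 1]
  }
  # mild covariate structure so adjustment matters
  base_cov <- list(
    fev1pp = -0.25 * z_cov_safe(cov, "pack_years") -
      0.10 * z_cov_safe(cov, "age"),
    fev1_fvc = -0.25 * z_cov_safe(cov, "pack_years") -
      0.15 * z_cov_safe(cov, "age"),
    pct_emphysema = 0.20 * z_cov_safe(cov, "pack_years") +
      0.15 * z_cov_safe(cov, "age"),
    exacerbation_count = 0.15 * z_cov_safe(cov, "pack_years"),
    chronic_bronchitis = 0.25 * as.numeric(scale(cov$current_smoker)))
  for (ph in phenotype_names) {
    planted_var <- sum(loads[[ph]]^2)
    covpart <- base_cov[[ph]]
    resid_var <- max(1 - planted_var - stats::var(covpart), 0.05)
    ph_latent[, ph] <- ph_latent[, ph] + covpart +
      sqrt(resid_var) * stats::rnorm(n)
  }
  fev1pp <- pmin(pmax(77 + 20 * ph_latent[, "fev1pp"], 10), 150)
  fev1_fvc <- pmin(pmax(0.65 + 0.12 * ph_latent[, "fev1_fvc"], 0.05), 0.95)
  pct_emphysema <- pmin(pmax(10 + 6 * ph_latent[, "pct_emphysema"], 0), 100)
  exac <- stats::rpois(n, exp(-0.7 + 0.5 * ph_latent[, "exacerbation_count"]))
  cb <- stats::rbinom(n, 1, stats::plogis(-1.6 +
                                            0.6 * ph_latent[, "chronic_bronchitis"]))
  gold <- ifelse(fev1_fvc < 0.70, "COPD",
                 ifelse(fev1pp < 80, "PRISm", "control"))
  gold[sample(n, max(0, round(0.01 * n)))] <- "missing"
  pheno <- data.frame(fev1pp = fev1pp, fev1_fvc = fev1_fvc,
                      pct_emphysema = pct_emphysema,
                      exacerbation_count = exac, chronic_bronchitis = cb,
                      gold_group = gold, row.names = sid)

  ## outlier subjects: +6 latent SD on a random 80% of metabolites
  outlier_ids <- character(0)
  if (config$n_outlier_subjects > 0) {
    who <- sample(n, config$n_outlier_subjects)
    outlier_ids <- sid[who]
    for (w in who) {
      cols <- sample(p, round(0.8 * p))
      L[w, cols] <- L[w, cols] + 6
    }
  }

  ## intensities: log-normal with run-day batch factor
  mu <- stats::rnorm(p, 10, 1)
  sigma <- stats::runif(p, 0.4, 0.8)
  X <- exp(sweep(sweep(L, 2, sigma, `*`), 2, mu, `+`))
  runday <- factor(sample(rep_len(sprintf("D%02d", seq_len(config$n_rundays)),
                                  n)))
  if (config$runday_scale > 0) {
    if (config$per_metabolite_runday) {
      fac <- matrix(exp(config$runday_scale *
                          stats::rnorm(config$n_rundays * p)),
                    config$n_rundays, p,
                    dimnames = list(levels(runday), mid))
      X <- X * fac[as.integer(runday), ]
    } else {
      fac <- exp(config$runday_scale * stats::rnorm(config$n_rundays))
      X <- X * fac[as.integer(runday)]
    }
  }
  if (config$missing_rate > 0) {
    X[stats::runif(n * p) < config$missing_rate] <- NA
  }

  super <- sample(c("lipid", "amino acid", "xenobiotics", "nucleotide",
                    "carbohydrate", "cofactors and vitamins"),
                  p, replace = TRUE,
                  prob = c(0.44, 0.21, 0.26, 0.035, 0.025, 0.03))
  annotated <- stats::runif(p) > 0.1
  annotation <- data.frame(
    metabolite = mid,
    display_name = ifelse(annotated, paste0("metab_", mid),
                          paste0("X - ", 10000 + seq_len(p))),
    super_pathway = ifelse(annotated, super, "Unannotated"),
    subpathway = ifelse(annotated, paste0(super, " subclass ",
                                          sample(1:4, p, replace = TRUE)),
                        "Unannotated"),
    annotated = annotated)

  truth <- structure(list(
    qtls = qtl_truth,
    modules = lapply(seq_along(config$planted_modules), function(mi) {
      mod <- config$planted_modules[[mi]]
      mod$member_ids <- mid[mod$members]
      mod
    }),
    outliers = outlier_ids,
    covariate_effects = if (length(cov_truth)) do.call(rbind, cov_truth)
      else data.frame(metabolite = character(), covariate = character(),
                      r2 = numeric(), sign = numeric()),
    seed = config$seed,
    config = config), class = "synthetic_truth")

  list(abundance = abundance_matrix(X, runday, stage = "raw"),
       dosage = dosage_matrix(G, info),
       covariates = cov,
       phenotypes = pheno,
       annotation = annotation,
       truth = truth)
}

z_cov_safe <- function(cov, name) {
  v <- as.numeric(cov[[name]])
  s <- stats::sd(v)
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Tabular summary of planted effects
#'
#' @param truth the `truth` component of [generate_cohort()] output.
#' @return data frame with one row per planted effect (QTLs, modules,
#'   covariate effects, outlier subjects) and its parameters.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- list()
  if (nrow(truth$qtls)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "qtl", id = truth$qtls$metabolite_id,
      partner = truth$qtls$snp_id,
      parameter = truth$qtls$r2,
      detail = sprintf("eaf=%.3f realized_latent_r2=%.3f",
                       truth$qtls$eaf, truth$qtls$realized_latent_r2))
  }
  for (mod in truth$modules) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "module", id = paste(mod$member_ids, collapse = ","),
      partner = mod$phenotype, parameter = mod$effect,
      detail = sprintf("rho=%.2f", mod$rho))
  }
  if (nrow(truth$covariate_effects)) {
    ce <- truth$covariate_effects
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "covariate", id = ce$metabolite, partner = ce$covariate,
      parameter = ce$r2, detail = sprintf("sign=%+d", ce$sign))
  }
  if (length(truth$outliers)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "outlier", id = truth$outliers, partner = NA_character_,
      parameter = 6, detail = "latent shift (SD)")
  }
  if (!length(rows))
    return(data.frame(kind = character(), id = character(),
                      partner = character(), parameter = numeric(),
                      detail = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
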