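#' Pipeline run configuration
#'
#' @param abundance,phenotypes,genotypes,snp_info,annotation input file
#'   paths (see [io]); `genotypes = NULL` disables the genetic stages
#'   (met-QTL scan, conditioning, variance decomposition, SNP nodes).
#' @param out_dir output directory for all stage tables.
#' @param alpha family-wise alpha used throughout, default 0.05.
#' @param max_missing,k,z_cut QC parameters.
#' @param min_maf MAF filter threshold.
#' @param pcor_min GGM minimum partial correlation.
#' @param n_pcs number of ancestry PCs used in the scan, default 5.
#' @param seed integer seed recorded with the run.
#' @return a validated `run_config` list.
#' @export
run_config <- function(abundance, phenotypes, genotypes = NULL,
                       snp_info = NULL, annotation = NULL,
                       out_dir = "mqtlnet_out", alpha = 0.05,
                       max_missing = 0.20, k = 10, z_cut = 3.5,
                       min_maf = 0.01, pcor_min = 0.2, n_pcs = 5,
                       seed = 1L) {
  for (p in c(abundance, phenotypes, genotypes, snp_info, annotation))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(alpha > 0, alpha < 1, max_missing >= 0, max_missing < 1,
            k >= 1, z_cut > 0, min_maf >= 0, min_maf < 0.5,
            pcor_min >= 0, pcor_min < 1)
  structure(list(abundance = abundance, phenotypes = phenotypes,
                 genotypes = genotypes, snp_info = snp_info,
                 annotation = annotation, out_dir = out_dir, alpha = alpha,
                 max_missing = max_missing, k = k, z_cut = z_cut,
                 min_maf = min_maf, pcor_min = pcor_min, n_pcs = n_pcs,
                 seed = as.integer(seed)),
            class = "run_config")
}

clinical_covariate_names <- c("age", "sex", "bmi", "current_smoker",
                              "pack_years", "center")

phenotype_families <- c(fev1pp = "linear", fev1_fvc = "linear",
                        pct_emphysema = "linear",
                        exacerbation_count = "negbin",
                        chronic_bronchitis = "logistic")

#' Run the full analysis pipeline
#'
#' Chains QC/normalization, phenotype-metabolite association, the
#' met-QTL scan with recursive conditioning and variance decomposition,
#' the GGM network with SNP nodes, the greedy phenotype-driven module
#' search, and subpathway / consequence-class enrichment. Every stage
#' writes its table to `out_dir` before the next stage starts, so a
#' failing stage leaves completed intermediates behind; the error names
#' the failing stage.
#'
#' @param cfg a [run_config()].
#' @return the run report: a named list of stage counts, also written to
#'   `out_dir/report.tsv`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  report <- list(seed = cfg$seed)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  ## inputs
  inp <- with_stage("read_inputs", {
    ab <- read_abundance(cfg$abundance)
    ph <- read_phenotypes(cfg$phenotypes)
    ann <- if (!is.null(cfg$annotation)) read_tsv(cfg$annotation) else NULL
    geno <- if (!is.null(cfg$genotypes))
      read_genotypes(cfg$genotypes, cfg$snp_info) else NULL
    common <- intersect(sample_ids(ab), rownames(ph$phenotypes))
    if (!is.null(geno)) common <- intersect(common, rownames(geno$dosages))
    if (!length(common)) stop("zero sample overlap across input files")
    list(ab = ab, ph = ph, ann = ann, geno = geno, common = common)
  })
  report$n_samples_input <- nrow(inp$ab$values)
  report$n_samples_aligned <- length(inp$common)

  ## QC chain
  qc <- with_stage("qc", qc_preprocess(inp$ab, max_missing = cfg$max_missing,
                                       k = cfg$k, z_cut = cfg$z_cut))
  write_abundance(qc$abundance, file.path(cfg$out_dir, "qc_abundance.tsv"))
  write_tsv(qc$report$metabolites_removed,
            file.path(cfg$out_dir, "qc_metabolites_removed.tsv"),
            "metabolites removed by missingness")
  write_tsv(qc$report$subjects_removed,
            file.path(cfg$out_dir, "qc_subjects_removed.tsv"),
            "outlier subjects removed")
  m <- qc$abundance
  report$n_metabolites_retained <- ncol(m$values)
  report$n_subjects_removed <- nrow(qc$report$subjects_removed)

  covs <- inp$ph$covariates[, intersect(clinical_covariate_names,
                                        names(inp$ph$covariates)),
                            drop = FALSE]

  ## phenotype associations
  assoc <- with_stage("assoc", {
    do.call(rbind, lapply(intersect(names(phenotype_families),
                                    names(inp$ph$phenotypes)), function(ph) {
      fit_metabolite_phenotype(
        m, stats::setNames(inp$ph$phenotypes[[ph]],
                           rownames(inp$ph$phenotypes)),
        covs, family = phenotype_families[[ph]], phenotype_name = ph,
        alpha = cfg$alpha)
    }))
  })
  write_tsv(assoc, file.path(cfg$out_dir, "associations.tsv"),
            "phenotype-metabolite associations")
  report$n_significant_associations <- sum(assoc$significant, na.rm = TRUE)
  report$n_metabolites_phenotype_associated <-
    length(unique(assoc$metabolite[assoc$significant]))

  ## genetic stages
  scan <- NULL; ind_sets <- list()
  if (!is.null(inp$geno)) {
    pc_names <- paste0("PC", seq_len(cfg$n_pcs))
    scan_covs <- inp$ph$covariates[, intersect(c(clinical_covariate_names,
                                                 pc_names),
                                               names(inp$ph$covariates)),
                                   drop = FALSE]
    geno <- with_stage("maf_filter", maf_filter(inp$geno, cfg$min_maf))
    report$n_snps_after_maf <- ncol(geno$dosages)
    scan <- with_stage("mwas_scan",
                       metqtl_scan(m, geno, scan_covs, alpha = cfg$alpha))
    write_tsv(scan$records, file.path(cfg$out_dir, "metqtl.tsv"),
              "met-QTL scan records",
              sprintf("# threshold %g", scan$threshold))
    sig <- scan$records[scan$records$significant, , drop = FALSE]
    report$n_metqtl_pairs <- nrow(sig)
    report$n_metabolites_with_metqtl <- length(unique(sig$metabolite))

    ind_sets <- with_stage("conditioning", {
      lapply(split(sig, sig$metabolite), function(cand) {
        met <- cand$metabolite[1]
        recursive_conditioning(
          stats::setNames(m$values[, met], sample_ids(m)), geno,
          cand[, c("snp", "p")], scan_covs, alpha = cfg$alpha,
          metabolite = met)
      })
    })
    ind_df <- do.call(rbind, lapply(ind_sets, function(s)
      if (nrow(s$snps)) cbind(metabolite = s$metabolite, s$snps) else NULL))
    if (is.null(ind_df))
      ind_df <- data.frame(metabolite = character(), snp = character(),
                           p = numeric(), round = integer(),
                           threshold = numeric())
    write_tsv(ind_df, file.path(cfg$out_dir, "independent_snps.tsv"),
              "independent met-QTL SNPs")
    report$n_independent_snps <- length(unique(ind_df$snp))

    vd <- with_stage("vardecomp", {
      do.call(rbind, lapply(ind_sets, function(s) {
        v <- variance_explained(
          stats::setNames(m$values[, s$metabolite], sample_ids(m)),
          geno, s, scan_covs)
        data.frame(metabolite = s$metabolite,
                   snp = names(v$snp_increments),
                   r2_snp = unname(v$snp_increments),
                   r2_covariates = v$r2_covariates,
                   remainder = v$remainder)
      }))
    })
    if (is.null(vd))
      vd <- data.frame(metabolite = character(), snp = character(),
                       r2_snp = numeric(), r2_covariates = numeric(),
                       remainder = numeric())
    write_tsv(vd, file.path(cfg$out_dir, "variance_decomposition.tsv"),
              "genetic vs clinical variance decomposition")
  }

  ## network + modules
  net <- with_stage("ggm", estimate_ggm(m, covs, alpha = cfg$alpha,
                                        pcor_min = cfg$pcor_min))
  if (length(ind_sets)) net <- add_snp_nodes(net, ind_sets)
  write_network_graphml(net, file.path(cfg$out_dir, "network.graphml"))
  write_network_sif(net, file.path(cfg$out_dir, "network.sif"))
  vtypes <- igraph::V(net)$type
  report$n_nodes <- igraph::vcount(net)
  report$n_metabolite_nodes <- sum(vtypes == "metabolite")
  report$n_snp_nodes <- sum(vtypes == "snp")
  report$n_edges <- igraph::ecount(net)

  modules <- with_stage("modules", {
    do.call(rbind, lapply(intersect(names(phenotype_families),
                                    names(inp$ph$phenotypes)), function(ph) {
      y <- inp$ph$phenotypes[[ph]]
      ids <- intersect(rownames(inp$ph$phenotypes), rownames(covs))
      df <- data.frame(y = y[match(ids, rownames(inp$ph$phenotypes))],
                       covs[ids, , drop = FALSE])
      df <- df[stats::complete.cases(df), , drop = FALSE]
      res <- stats::setNames(stats::resid(stats::lm(y ~ ., data = df)),
                             rownames(df))
      as.data.frame(greedy_module_search(net, m, res, alpha = cfg$alpha,
                                         phenotype_name = ph))
    }))
  })
  write_tsv(modules, file.path(cfg$out_dir, "modules.tsv"),
            "phenotype-driven modules")
  report$n_modules <- nrow(modules)

  if (!is.null(scan) && nrow(modules)) {
    modvd <- with_stage("module_vardecomp", {
      do.call(rbind, lapply(seq_len(nrow(modules)), function(i) {
        members <- strsplit(modules$members[i], ",")[[1]]
        if (length(members) < 2) return(NULL)
        v <- module_variance_decomposition(members, m, inp$geno, ind_sets,
                                           covs)
        data.frame(phenotype = modules$phenotype[i],
                   module_id = modules$module_id[i],
                   members = modules$members[i],
                   r2_genetic = sum(v$snp_increments),
                   r2_covariates = v$r2_covariates,
                   snps = paste(v$snps, collapse = ","))
      }))
    })
    if (!is.null(modvd))
      write_tsv(modvd, file.path(cfg$out_dir, "module_vardecomp.tsv"),
                "module first-PC variance decomposition")
  }

  ## enrichment
  if (!is.null(inp$ann)) {
    enr <- with_stage("enrichment", {
      ann <- inp$ann[match(metabolite_ids(m), inp$ann$metabolite), ]
      grouping <- stats::setNames(ann$subpathway, ann$metabolite)
      hits <- unique(assoc$metabolite[assoc$significant])
      fisher_enrichment(hits, metabolite_ids(m), grouping)
    })
    write_tsv(enr, file.path(cfg$out_dir, "enrichment_subpathway.tsv"),
              "subpathway enrichment of phenotype-associated metabolites")
    report$n_enriched_subpathways <- sum(enr$significant)
    if (!is.null(scan)) {
      enr2 <- with_stage("enrichment_snp", {
        sig_snps <- unique(scan$records$snp[scan$records$significant])
        grouping <- stats::setNames(inp$geno$info$consequence,
                                    inp$geno$info$snp)
        if (length(sig_snps))
          fisher_enrichment(sig_snps, inp$geno$info$snp, grouping)
        else NULL
      })
      if (!is.null(enr2))
        write_tsv(enr2, file.path(cfg$out_dir, "enrichment_consequence.tsv"),
                  "consequence-class enrichment of met-QTL SNPs")
    }
  }

  rep_df <- data.frame(key = names(report),
                       value = vapply(report, as.character, ""))
  write_tsv(rep_df, file.path(cfg$out_dir, "report.tsv"), "run report")
  report
}
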