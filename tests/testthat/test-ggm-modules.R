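# helper: transformed abundance straight from a latent matrix
latent_to_transformed <- function(L, ids = NULL) {
  if (is.null(rownames(L))) rownames(L) <- sprintf("S%04d", seq_len(nrow(L)))
  if (is.null(colnames(L))) colnames(L) <- sprintf("M%03d", seq_len(ncol(L)))
  m <- abundance_matrix(exp(L), rep("D1", nrow(L)), stage = "imputed")
  inverse_normal_transform(m)
}

test_that("a Gaussian chain yields exactly its two direct edges", {
  # A -> B -> C with corr(A,B) = corr(B,C) = sqrt(0.5): marginal
  # corr(A,C) = 0.5 but pcor(A,C | B) = 0
  set.seed(61)
  n <- 5000
  a <- rnorm(n)
  b <- sqrt(0.5) * a + sqrt(0.5) * rnorm(n)
  c_ <- sqrt(0.5) * b + sqrt(0.5) * rnorm(n)
  m <- latent_to_transformed(cbind(A = a, B = b, C = c_))
  colnames(m$values) <- c("A", "B", "C")
  net <- estimate_ggm(m)
  el <- apply(igraph::as_edgelist(net), 1, paste, collapse = "-")
  expect_setequal(el, c("A-B", "B-C"))
  # oracle: pcor from the inverse of the true covariance
  S <- matrix(c(1, sqrt(.5), .5,
                sqrt(.5), 1, sqrt(.5),
                .5, sqrt(.5), 1), 3, 3)
  P <- solve(S)
  pc_true <- -P / sqrt(outer(diag(P), diag(P)))
  pcors <- igraph::E(net)$pcor
  expect_equal(sort(pcors), sort(c(pc_true[1, 2], pc_true[2, 3])),
               tolerance = 0.05)
  # shrinkage estimate of the excluded pair is near zero
  sh <- mqtlnet:::shrink_cor(scale(m$values))
  pc <- mqtlnet:::pcor_from_cor(sh$cor)
  expect_lt(abs(pc["A", "C"]), 0.05)
})

test_that("shrinkage partial correlations match the unregularized oracle at large n", {
  set.seed(62)
  n <- 5000; p <- 12
  # random sparse positive structure
  L <- matrix(rnorm(n * p), n, p)
  L[, 2] <- 0.6 * L[, 1] + 0.8 * rnorm(n)
  L[, 3] <- 0.5 * L[, 2] + 0.87 * rnorm(n)
  m <- latent_to_transformed(L)
  Y <- m$values
  sh <- mqtlnet:::shrink_cor(Y)
  pc_shrunk <- mqtlnet:::pcor_from_cor(sh$cor)
  pc_raw <- mqtlnet:::pcor_from_cor(stats::cor(Y))
  expect_lt(max(abs(pc_shrunk - pc_raw)), 0.02)
})

test_that("negative partial correlations are never edged", {
  set.seed(63)
  n <- 2000
  a <- rnorm(n)
  b <- -0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  m <- latent_to_transformed(cbind(A = a, B = b, C = rnorm(n)))
  colnames(m$values) <- c("A", "B", "C")
  # raw pcor(A,B) is about -0.5, strongly significant, but must not edge
  net <- estimate_ggm(m)
  expect_equal(igraph::ecount(net), 0)
})

test_that("independent metabolites give an empty network", {
  empties <- vapply(1:5, function(s) {
    set.seed(640 + s)
    m <- latent_to_transformed(matrix(rnorm(1000 * 50), 1000, 50))
    # with no real correlation the analytic shrinkage may hit 1 (warns)
    igraph::ecount(suppressWarnings(estimate_ggm(m)))
  }, 0)
  expect_true(all(empties == 0))
})

test_that("edge counts are monotone in pcor_min and alpha", {
  co <- generate_cohort(simulation_config(
    n_subjects = 500, n_metabolites = 30, n_snps = 5, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_modules = list(list(members = 1:6, rho = 0.6,
                                phenotype = "fev1pp", effect = 0),
                           list(members = 7:12, rho = 0.5,
                                phenotype = "fev1_fvc", effect = 0)),
    seed = 65))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  e <- function(pm, al) igraph::ecount(estimate_ggm(m, alpha = al,
                                                    pcor_min = pm))
  expect_gte(e(0.1, 0.05), e(0.2, 0.05))
  expect_gte(e(0.2, 0.05), e(0.3, 0.05))
  expect_gte(e(0.2, 0.05), e(0.2, 0.001))
  expect_gt(e(0.1, 0.05), 0)
  # confounder residualization requires enough subjects
  expect_error(estimate_ggm(
    abundance_matrix(m$values[1:31, ], rep("D1", 31), stage = "transformed"),
    confounders = as.data.frame(matrix(rnorm(31 * 31), 31,
                                       dimnames = list(rownames(m$values)[1:31],
                                                       paste0("c", 1:31))))),
    "confounder")
})

test_that("SNP nodes attach by met-QTL links without touching metabolite edges", {
  co <- generate_cohort(simulation_config(
    n_subjects = 400, n_metabolites = 12, n_snps = 6, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_modules = list(list(members = 1:4, rho = 0.7,
                                phenotype = "fev1pp", effect = 0)),
    seed = 66))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  net <- estimate_ggm(m)
  e0 <- igraph::ecount(net)
  expect_identical(igraph::ecount(add_snp_nodes(net, list())), e0)
  links <- data.frame(snp = c("rs00001", "rs00001"),
                      metabolite = c("M001", "M002"))
  net2 <- add_snp_nodes(net, links)
  expect_identical(sum(igraph::V(net2)$type == "snp"), 1L)
  expect_identical(igraph::ecount(net2), e0 + 2L)
  expect_identical(sum(igraph::E(net2)$provenance == "metqtl"), 2L)
  # unknown metabolite is skipped with a warning
  expect_warning(
    net3 <- add_snp_nodes(net, data.frame(snp = "rs9", metabolite = "Mxx")),
    "skipped")
  expect_identical(igraph::ecount(net3), e0)
})

test_that("score_profile behaves at its extremes and under the null", {
  set.seed(67)
  ph <- rnorm(1000)
  s_ident <- score_profile(ph, ph)
  expect_gt(s_ident$score, 100)
  s_const <- score_profile(rep(1, 1000), ph)
  expect_identical(s_const$score, 0)
  expect_identical(s_const$flag, "zero_variance")
  null_scores <- vapply(1:500, function(i)
    score_profile(rnorm(200), rnorm(200))$score, 0)
  expect_lt(abs(mean(null_scores > 2) - 0.01), 0.015)
})

test_that("averaging a planted module beats its single members", {
  wins <- vapply(1:40, function(s) {
    co <- generate_cohort(simulation_config(
      n_subjects = 600, n_metabolites = 6, n_snps = 5, n_rundays = 1,
      missing_rate = 0, runday_scale = 0,
      planted_modules = list(list(members = 1:4, rho = 0.5,
                                  phenotype = "fev1pp", effect = 0.15)),
      seed = 6800 + s))
    m <- transformed_abundance(co$abundance$values)
    rownames(m$values) <- rownames(co$abundance$values)
    ph <- pheno_residuals(co, "fev1pp", co$covariates[, 1:6])
    members <- paste0("M00", 1:4)
    avg <- rowMeans(m$values[names(ph), members])
    mod_score <- score_profile(avg, ph)$score
    single <- vapply(members, function(v)
      score_profile(m$values[names(ph), v], ph)$score, 0)
    mod_score > max(single)
  }, TRUE)
  expect_gte(mean(wins), 0.75)
})

test_that("the greedy search recovers a planted module and asserts its score rule", {
  co <- generate_cohort(simulation_config(
    n_subjects = 1000, n_metabolites = 25, n_snps = 5, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_modules = list(
      list(members = 1:3, rho = 0.6, phenotype = "fev1pp", effect = 0.15),
      list(members = 10:14, rho = 0.5, phenotype = "fev1_fvc", effect = 0)),
    seed = 69))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  net <- estimate_ggm(m)
  ph <- pheno_residuals(co, "fev1pp", co$covariates[, 1:6])
  mods <- greedy_module_search(net, m, ph, phenotype_name = "fev1pp")
  expect_gte(length(mods), 1)
  members <- unlist(lapply(mods, `[[`, "members"))
  expect_gte(sum(paste0("M00", 1:3) %in% members), 2)
  # every returned module's score strictly exceeds its best member score
  singles <- vapply(colnames(m$values), function(v)
    score_profile(m$values[names(ph), v], ph)$score, 0)
  for (mo in mods) {
    if (length(mo$members) > 1)
      expect_gt(mo$score, max(singles[mo$members]))
    expect_lt(mo$adjusted_p, 0.05)
    expect_true(all(mo$members %in%
                      igraph::V(net)$name[igraph::V(net)$type == "metabolite"]))
  }
  # no two returned modules overlap after merging
  if (length(mods) > 1) {
    for (i in seq_along(mods)) for (j in seq_along(mods)) {
      if (j > i)
        expect_length(intersect(mods[[i]]$members, mods[[j]]$members), 0)
    }
  }
})

test_that("module search is invariant to metabolite column order", {
  co <- generate_cohort(simulation_config(
    n_subjects = 600, n_metabolites = 15, n_snps = 5, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_modules = list(list(members = 1:3, rho = 0.6,
                                phenotype = "fev1pp", effect = 0.2)),
    seed = 70))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  net <- estimate_ggm(m)
  ph <- pheno_residuals(co, "fev1pp", co$covariates[, 1:6])
  mods1 <- greedy_module_search(net, m, ph)
  perm <- sample(ncol(m$values))
  m2 <- abundance_matrix(m$values[, perm], m$runday, stage = "transformed")
  mods2 <- greedy_module_search(net, m2, ph)
  sets1 <- lapply(mods1, `[[`, "members")
  sets2 <- lapply(mods2, `[[`, "members")
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("module variance decomposition attributes PC variance to shared SNPs", {
  co <- generate_cohort(simulation_config(
    n_subjects = 2000, n_metabolites = 8, n_snps = 10, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_qtls = data.frame(metabolite = c(1, 2), snp = c(4, 4),
                              eaf = c(0.4, 0.4), r2 = c(0.15, 0.15)),
    planted_modules = list(list(members = 1:2, rho = 0.3,
                                phenotype = "fev1pp", effect = 0)),
    seed = 71))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  links <- data.frame(snp = "rs00004", metabolite = c("M001", "M002"))
  vd <- module_variance_decomposition(c("M001", "M002"), m, co$dosage,
                                      links, co$covariates[, 1:6])
  expect_gt(sum(vd$snp_increments), 0.08)
  expect_lt(sum(vd$snp_increments), 0.25)
  # genetically null module
  vd0 <- module_variance_decomposition(c("M005", "M006"), m, co$dosage,
                                       data.frame(snp = character(),
                                                  metabolite = character()),
                                       co$covariates[, 1:6])
  expect_length(vd0$snp_increments, 0)
  expect_error(module_variance_decomposition("M001", m, co$dosage, links),
               "at least 2")
})
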