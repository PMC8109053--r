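test_that("MAF filter applies the >1% rule and is idempotent", {
  set.seed(41)
  n <- 2000
  eafs <- c(0.005, 0.5, 0.02, 0.995)
  G <- vapply(eafs, function(f) rbinom(n, 2, f), numeric(n))
  dimnames(G) <- list(sprintf("S%04d", 1:n), paste0("rs", 1:4))
  g <- dosage_matrix(G)
  filt <- maf_filter(g)
  expect_setequal(filt$info$snp, c("rs2", "rs3"))
  expect_identical(maf_filter(filt)$info$snp, filt$info$snp)
})

test_that("the residualization scan equals brute-force per-pair regression", {
  set.seed(42)
  n <- 50
  covs <- data.frame(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
                     PC1 = rnorm(n), PC2 = rnorm(n),
                     row.names = sprintf("S%03d", 1:n))
  G <- vapply(1:5, function(j) rbinom(n, 2, 0.4), numeric(n))
  dimnames(G) <- list(rownames(covs), paste0("rs", 1:5))
  Y <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(rownames(covs), paste0("M", 1:4)))
  Y[, 1] <- Y[, 1] + 0.5 * G[, 2]
  m <- abundance_matrix(Y, rep("D1", n), stage = "transformed")
  scan <- metqtl_scan(m, dosage_matrix(G), covs, cap = 5)
  for (i in seq_len(nrow(scan$records))) {
    rec <- scan$records[i, ]
    fit <- summary(stats::lm(Y[, rec$metabolite] ~ G[, rec$snp] + covs$age +
                               covs$sex + covs$PC1 + covs$PC2))
    cf <- fit$coefficients[2, ]
    expect_equal(rec$beta, cf[1], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(rec$se, cf[2], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(rec$p, cf[4], tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("permuted dosages produce no genome-wide hits", {
  co <- generate_cohort(simulation_config(
    n_subjects = 300, n_metabolites = 50, n_snps = 100, n_rundays = 1,
    missing_rate = 0, runday_scale = 0, seed = 43))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  G <- co$dosage$dosages
  set.seed(44)
  G <- G[sample(nrow(G)), ]
  rownames(G) <- rownames(co$dosage$dosages)
  scan <- metqtl_scan(m, dosage_matrix(G, co$dosage$info),
                      co$covariates, cap = 1)
  expect_identical(sum(scan$records$significant), 0L)
})

test_that("a planted QTL is detected with its variance fraction", {
  co <- generate_cohort(simulation_config(
    n_subjects = 1000, n_metabolites = 20, n_snps = 50, n_rundays = 2,
    missing_rate = 0, runday_scale = 0.1,
    planted_qtls = data.frame(metabolite = 7, snp = 11, eaf = 0.35,
                              r2 = 0.5),
    seed = 45))
  m <- qc_preprocess(co$abundance)$abundance
  scan <- metqtl_scan(m, co$dosage, co$covariates)
  hit <- scan$records[scan$records$metabolite == "M007" &
                        scan$records$snp == "rs00011", ]
  expect_true(hit$significant)
  expect_gt(hit$r2, 0.44)
  expect_lt(hit$r2, 0.56)
})

test_that("monomorphic SNPs are skipped and collinear covariates rejected", {
  set.seed(46)
  n <- 40
  G <- cbind(rs1 = rbinom(n, 2, 0.5), rs2 = rep(2, n))
  rownames(G) <- sprintf("S%03d", 1:n)
  Y <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(rownames(G), c("M1", "M2")))
  m <- abundance_matrix(Y, rep("D1", n), stage = "transformed")
  scan <- metqtl_scan(m, dosage_matrix(G))
  expect_identical(scan$skipped_snps, "rs2")
  covs <- data.frame(a = rnorm(n), b = rnorm(n), row.names = rownames(G))
  covs$b <- 2 * covs$a
  expect_error(metqtl_scan(m, dosage_matrix(G), covs), "collinear")
})

test_that("a single candidate is the sole independent met-QTL", {
  set.seed(47)
  n <- 200
  g <- dosage_matrix(matrix(rbinom(n, 2, 0.3), n, 1,
                            dimnames = list(sprintf("S%03d", 1:n), "rs1")))
  y <- stats::setNames(0.5 * g$dosages[, 1] + rnorm(n),
                       rownames(g$dosages))
  ind <- recursive_conditioning(y, g, data.frame(snp = "rs1", p = 1e-15))
  expect_identical(ind$snps$snp, "rs1")
  expect_identical(ind$snps$round, 0L)
})

test_that("perfect-LD duplicates yield exactly one admitted SNP", {
  set.seed(48)
  n <- 500
  d <- rbinom(n, 2, 0.4)
  G <- cbind(rs1 = d, rs2 = d)
  rownames(G) <- sprintf("S%03d", 1:n)
  info <- data.frame(snp = c("rs1", "rs2"), chrom = c(1, 1),
                     pos = c(100, 200))
  y <- stats::setNames(0.6 * d + rnorm(n), rownames(G))
  p1 <- summary(stats::lm(y ~ G[, 1]))$coefficients[2, 4]
  ind <- recursive_conditioning(y, dosage_matrix(G, info),
                                data.frame(snp = c("rs1", "rs2"),
                                           p = c(p1, p1)))
  expect_identical(nrow(ind$snps), 1L)
  expect_identical(ind$snps$snp, "rs1")   # tie broken by position
  expect_identical(ind$dropped, "rs2")
})

test_that("conditioning recovers planted causal SNPs among null LD correlates", {
  # two independent causal SNPs plus 8 correlates of them
  ld <- data.frame(snp1 = c(rep(1, 4), rep(2, 4)), snp2 = 3:10,
                   r = rep(0.9, 8))
  co <- generate_cohort(simulation_config(
    n_subjects = 1000, n_metabolites = 5, n_snps = 10, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_qtls = data.frame(metabolite = c(1, 1), snp = c(1, 2),
                              eaf = c(0.4, 0.3), r2 = c(0.15, 0.12)),
    ld_pairs = ld, seed = 49))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  y <- stats::setNames(m$values[, "M001"], rownames(m$values))
  scan <- metqtl_scan(m, co$dosage, co$covariates, cap = 10)
  cand <- scan$records[scan$records$metabolite == "M001" &
                         scan$records$p < 1e-8, c("snp", "p")]
  expect_gte(nrow(cand), 2)
  ind <- recursive_conditioning(y, co$dosage, cand, co$covariates,
                                metabolite = "M001")
  expect_setequal(ind$snps$snp, c("rs00001", "rs00002"))
})

test_that("variance decomposition recovers planted fractions", {
  co <- generate_cohort(simulation_config(
    n_subjects = 2000, n_metabolites = 5, n_snps = 10, n_rundays = 1,
    missing_rate = 0, runday_scale = 0,
    planted_qtls = data.frame(metabolite = c(1, 1, 2), snp = c(1, 2, 3),
                              eaf = c(0.4, 0.3, 0.5),
                              r2 = c(0.34, 0.25, 0.30)),
    seed = 50))
  m <- transformed_abundance(co$abundance$values)
  rownames(m$values) <- rownames(co$abundance$values)
  y1 <- stats::setNames(m$values[, "M001"], rownames(m$values))
  vd1 <- variance_explained(y1, co$dosage, c("rs00001", "rs00002"),
                            co$covariates[, 1:6])
  expect_length(vd1$snp_increments, 2)
  expect_true(all(vd1$snp_increments > 0))
  expect_lt(abs(sum(vd1$snp_increments) - 0.59), 0.05)
  # single planted SNP at 0.30; no covariate effects planted
  y2 <- stats::setNames(m$values[, "M002"], rownames(m$values))
  vd2 <- variance_explained(y2, co$dosage, "rs00003",
                            co$covariates[, 1:6])
  expect_gt(vd2$r2_top, 0.26)
  expect_lt(vd2$r2_top, 0.34)
  expect_lt(vd2$r2_covariates, 0.02)
  # SNP independent of the metabolite
  y3 <- stats::setNames(m$values[, "M003"], rownames(m$values))
  vd3 <- variance_explained(y3, co$dosage, "rs00007")
  expect_lt(vd3$r2_top, 2 / 2000 + 0.003)
  expect_error(variance_explained(numeric(0), co$dosage, "rs00007"),
               "empty profile")
})

test_that("planted-QTL detection power rises with the target variance fraction", {
  targets <- c(0.01, 0.05, 0.1, 0.3)
  reps <- 25
  detect <- vapply(seq_along(targets), function(ti) {
    hits <- vapply(seq_len(reps), function(r) {
      co <- generate_cohort(simulation_config(
        n_subjects = 1000, n_metabolites = 10, n_snps = 40, n_rundays = 1,
        missing_rate = 0, runday_scale = 0,
        planted_qtls = data.frame(metabolite = 3, snp = 5, eaf = 0.4,
                                  r2 = targets[ti]),
        seed = 5000 + 100 * ti + r))
      m <- transformed_abundance(co$abundance$values)
      rownames(m$values) <- rownames(co$abundance$values)
      scan <- metqtl_scan(m, co$dosage, cap = 1)
      rec <- scan$records[scan$records$metabolite == "M003" &
                            scan$records$snp == "rs00005", ]
      nrow(rec) > 0 && any(rec$significant)
    }, TRUE)
    mean(hits)
  }, 0)
  # non-decreasing within Monte-Carlo noise, and strictly more power at the
  # top than the bottom of the range
  expect_true(all(diff(detect) > -0.05))
  expect_gt(detect[4], detect[1])
  expect_equal(detect[4], 1)
})

test_that("scan-significance FWER under the global null is controlled", {
  fams <- vapply(1:40, function(s) {
    co <- generate_cohort(simulation_config(
      n_subjects = 200, n_metabolites = 25, n_snps = 60, n_rundays = 1,
      missing_rate = 0, runday_scale = 0, seed = 7000 + s))
    m <- transformed_abundance(co$abundance$values)
    rownames(m$values) <- rownames(co$abundance$values)
    scan <- metqtl_scan(m, co$dosage, cap = 1)
    any(scan$records$significant)
  }, TRUE)
  expect_lte(mean(fams), 0.10)
})
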