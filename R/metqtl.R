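#' Minor-allele-frequency filter
#'
#' Retains SNPs with `min(EAF, 1 - EAF) > min_maf`, frequencies computed
#' from the analysis sample. Idempotent.
#'
#' @param g a [dosage_matrix()].
#' @param min_maf minimum minor-allele frequency (exclusive), default 0.01.
#' @return a filtered `dosage_matrix`.
#' @export
maf_filter <- function(g, min_maf = 0.01) {
  stopifnot(inherits(g, "dosage_matrix"))
  eaf <- colMeans(g$dosages, na.rm = TRUE) / 2
  keep <- pmin(eaf, 1 - eaf) > min_maf
  dosage_matrix(g$dosages[, keep, drop = FALSE],
                g$info[keep, , drop = FALSE])
}

# residualize columns of a matrix on a design (QR-based); returns residuals
# and the rank of the design
residualize <- function(Y, design) {
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  list(resid = qr.resid(qrX, Y), rank = qrX$rank)
}

covariate_design <- function(covariates, ids) {
  if (is.null(covariates))
    return(matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)")))
  stats::model.matrix(~ ., data = covariates[ids, , drop = FALSE])
}

#' Metabolome-wide QTL scan
#'
#' Additive linear-model association of every (SNP, metabolite) pair,
#' adjusted for covariates (including ancestry PCs). Both the metabolite
#' and the dosage are residualized on the covariate design, and the
#' residual correlation is tested with `df = n - 1 - rank(design)`; this
#' reproduces the per-pair full regression exactly (Frisch-Waugh) at a
#' fraction of the cost. Missing dosages are mean-imputed per SNP;
#' monomorphic SNPs are skipped and logged.
#'
#' @param m an `abundance_matrix` at stage `transformed`.
#' @param g a MAF-filtered `dosage_matrix`.
#' @param covariates data frame of clinical covariates plus ancestry PCs
#'   (rownames = sample ids), or `NULL` for intercept-only.
#' @param alpha family-wise alpha; pairs with
#'   `p < alpha / (n_metabolites * n_snps)` are flagged significant.
#' @param cap per-metabolite number of sub-threshold records retained in
#'   addition to all significant ones, default 100.
#' @return object of class `metqtl_scan`: list with `records` (data frame:
#'   snp, metabolite, beta, se, p, r2, significant), `threshold`, `n`,
#'   `n_snps`, `n_metabolites`, `skipped_snps`.
#' @export
metqtl_scan <- function(m, g, covariates = NULL, alpha = 0.05, cap = 100) {
  assert_stage(m, "transformed", "metqtl_scan")
  stopifnot(inherits(g, "dosage_matrix"))
  ids <- intersect(sample_ids(m), rownames(g$dosages))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  if (!length(ids)) stop("no overlapping samples between inputs")
  Y <- m$values[ids, , drop = FALSE]
  G <- g$dosages[ids, , drop = FALSE]
  # mean-impute missing dosages per SNP
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  mono <- apply(G, 2, stats::sd) == 0
  skipped <- colnames(G)[mono]
  G <- G[, !mono, drop = FALSE]
  n <- length(ids)
  X <- covariate_design(covariates, ids)
  rz <- residualize(cbind(Y, G), X)
  df <- n - 1 - rz$rank
  if (df < 1) stop("not enough samples for the covariate design")
  Yr <- rz$resid[, seq_len(ncol(Y)), drop = FALSE]
  Gr <- rz$resid[, ncol(Y) + seq_len(ncol(G)), drop = FALSE]
  ynorm <- sqrt(colSums(Yr^2))
  gnorm <- sqrt(colSums(Gr^2))
  R <- crossprod(sweep(Gr, 2, gnorm, `/`), sweep(Yr, 2, ynorm, `/`))
  R <- pmin(pmax(R, -1), 1)
  tstat <- R * sqrt(df / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), df)
  beta <- R * rep(ynorm, each = nrow(R)) / gnorm
  SE <- beta / tstat
  thr <- alpha / (ncol(Y) * ncol(G))
  # marginal r2 (variance explained by the SNP alone)
  R2m <- stats::cor(G, Y)^2
  recs <- list()
  for (j in seq_len(ncol(Y))) {
    sig <- P[, j] < thr
    keep <- sig | rank(P[, j], ties.method = "first") <= cap
    recs[[j]] <- data.frame(
      snp = rownames(P)[keep], metabolite = colnames(Y)[j],
      beta = beta[keep, j], se = SE[keep, j], p = P[keep, j],
      r2 = R2m[keep, j], significant = sig[keep])
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records, threshold = thr, n = n,
                 n_snps = ncol(G), n_metabolites = ncol(Y),
                 skipped_snps = skipped),
            class = "metqtl_scan")
}

#' @export
print.metqtl_scan <- function(x, ...) {
  cat(sprintf(
    "metqtl_scan: %d SNPs x %d metabolites (n = %d)\n  threshold %.3g; %d significant pairs over %d metabolites\n",
    x$n_snps, x$n_metabolites, x$n,
    x$threshold, sum(x$records$significant),
    length(unique(x$records$metabolite[x$records$significant]))))
  invisible(x)
}

#' Recursive conditioning to independent met-QTL SNPs
#'
#' Given the K genome-wide-significant candidate SNPs for one metabolite,
#' admits the top (smallest marginal p) SNP, then iteratively refits
#' `metabolite ~ candidate + admitted SNPs + covariates` for every
#' remaining candidate and admits the smallest conditional p if it beats
#' `0.05 / T` where `T` is the number of remaining candidates; stops
#' otherwise. Candidates made collinear by already-admitted SNPs (perfect
#' LD) are dropped with a log entry. Ties in p are broken by
#' (chrom, pos, id) order, so reruns are identical.
#'
#' @param y named numeric metabolite profile (names = sample ids).
#' @param g `dosage_matrix` containing at least the candidate SNPs.
#' @param candidates data frame with columns `snp` and `p` (marginal scan
#'   p-values); all candidates are assumed to have passed the genome-wide
#'   threshold for this metabolite.
#' @param covariates covariate data frame or `NULL`.
#' @param alpha per-round numerator of the Bonferroni threshold, default
#'   0.05.
#' @return object of class `independent_set`: list with `snps` (data frame
#'   snp, p, round, threshold in admission order), `metabolite`, `dropped`
#'   (collinear candidates).
#' @export
recursive_conditioning <- function(y, g, candidates, covariates = NULL,
                                   alpha = 0.05, metabolite = NA_character_) {
  stopifnot(inherits(g, "dosage_matrix"),
            all(c("snp", "p") %in% names(candidates)))
  if (!nrow(candidates)) stop("need at least one candidate SNP")
  info <- g$info[match(candidates$snp, g$info$snp), ]
  chrom <- if (is.null(info$chrom)) rep(0L, nrow(info)) else info$chrom
  pos <- if (is.null(info$pos)) rep(0L, nrow(info)) else info$pos
  ord <- order(candidates$p, chrom, pos, candidates$snp)
  candidates <- candidates[ord, , drop = FALSE]
  ids <- intersect(names(y), rownames(g$dosages))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  X <- covariate_design(covariates, ids)
  G <- g$dosages[ids, candidates$snp, drop = FALSE]
  yv <- y[ids]
  cc <- stats::complete.cases(cbind(yv, G, X))
  yv <- yv[cc]; G <- G[cc, , drop = FALSE]; X <- X[cc, , drop = FALSE]

  admitted <- candidates$snp[1]
  admit_log <- data.frame(snp = admitted, p = candidates$p[1], round = 0L,
                          threshold = NA_real_)
  remaining <- setdiff(candidates$snp, admitted)
  dropped <- character(0)
  round_i <- 0L
  while (length(remaining)) {
    round_i <- round_i + 1L
    thr <- alpha / length(remaining)
    Z <- cbind(X, G[, admitted, drop = FALSE])
    cond_p <- vapply(remaining, function(s) {
      # candidate last: a perfect-LD duplicate aliases the candidate itself
      cand <- G[, s]
      fit <- stats::lm(yv ~ 0 + Z + cand)
      if (is.na(stats::coef(fit)["cand"])) return(NA_real_)
      summary(fit)$coefficients["cand", 4]
    }, 0)
    if (anyNA(cond_p)) {
      dropped <- c(dropped, remaining[is.na(cond_p)])
      remaining <- remaining[!is.na(cond_p)]
      cond_p <- cond_p[!is.na(cond_p)]
      if (!length(remaining)) break
      thr <- alpha / length(remaining)
    }
    inf2 <- g$info[match(remaining, g$info$snp), ]
    chrom2 <- if (is.null(inf2$chrom)) rep(0L, nrow(inf2)) else inf2$chrom
    pos2 <- if (is.null(inf2$pos)) rep(0L, nrow(inf2)) else inf2$pos
    ordr <- order(cond_p, chrom2, pos2, remaining)
    best <- ordr[1]
    if (cond_p[best] >= thr) break
    admitted <- c(admitted, remaining[best])
    admit_log <- rbind(admit_log,
                       data.frame(snp = remaining[best], p = cond_p[best],
                                  round = round_i, threshold = thr))
    remaining <- remaining[-best]
  }
  structure(list(snps = admit_log, metabolite = metabolite,
                 dropped = dropped),
            class = "independent_set")
}

#' Genetic-versus-clinical variance decomposition
#'
#' Computes the coefficient of determination of the metabolite on (a) the
#' clinical covariates alone, and (b) the admitted independent SNPs in
#' admission order, where each SNP's contribution is the incremental r-squared
#' of the nested genotype-only models (top SNP first). The unexplained
#' remainder is one minus the r-squared of the joint SNPs + covariates model.
#'
#' @param y named numeric metabolite (or module-PC) profile.
#' @param g `dosage_matrix`.
#' @param ind an `independent_set` (or character vector of SNP ids in
#'   admission order); may be empty.
#' @param covariates covariate data frame or `NULL`.
#' @return object of class `variance_decomposition`: list with
#'   `r2_covariates`, `snp_increments` (named, admission order), `r2_top`,
#'   `remainder`.
#' @export
variance_explained <- function(y, g, ind, covariates = NULL) {
  if (!length(y) || all(is.na(y))) stop("empty profile")
  snps <- if (inherits(ind, "independent_set")) ind$snps$snp
          else as.character(ind)
  ids <- intersect(names(y), rownames(g$dosages))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  yv <- y[ids]
  G <- g$dosages[ids, snps, drop = FALSE]
  X <- if (is.null(covariates)) NULL
       else stats::model.matrix(~ ., covariates[ids, , drop = FALSE])[, -1,
                                                            drop = FALSE]
  cc <- stats::complete.cases(cbind(yv, G, X))
  yv <- yv[cc]; G <- G[cc, , drop = FALSE]
  if (!is.null(X)) X <- X[cc, , drop = FALSE]
  r2_cov <- if (is.null(X)) 0
            else summary(stats::lm(yv ~ X))$r.squared
  incr <- numeric(0)
  if (length(snps)) {
    prev <- 0
    for (k in seq_along(snps)) {
      r2k <- summary(stats::lm(yv ~ G[, seq_len(k), drop = FALSE]))$r.squared
      incr <- c(incr, r2k - prev)
      prev <- r2k
    }
    names(incr) <- snps
  }
  full <- if (length(snps) && !is.null(X))
    summary(stats::lm(yv ~ G + X))$r.squared
  else if (length(snps)) sum(incr)
  else r2_cov
  structure(list(r2_covariates = r2_cov, snp_increments = incr,
                 r2_top = if (length(incr)) incr[[1]] else 0,
                 remainder = max(0, 1 - full)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("variance decomposition: covariates %.3f; SNPs %s; remainder %.3f\n",
              x$r2_covariates,
              if (length(x$snp_increments))
                paste(sprintf("%s=%.3f", names(x$snp_increments),
                              x$snp_increments), collapse = " + ")
              else "none", x$remainder))
  invisible(x)
}
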