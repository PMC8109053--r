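#' Gaussian graphical model of metabolite co-abundance
#'
#' Estimates full-order partial correlations between metabolites after
#' residualizing on confounders. Because the metabolite count can exceed
#' the sample count, the correlation matrix is regularized by analytic
#' shrinkage toward the identity (Schaefer-Strimmer estimator; the
#' data-driven intensity is recorded in the result) before inversion.
#' Edge rule: partial correlation strictly above `pcor_min` (negative
#' partial correlations are never edged, as they are typically spurious)
#' and Fisher-z p-value below `alpha / denominator`.
#'
#' Edge p-values use the Fisher z transform with effective df `n - 3`
#' (the conditioning count is not subtracted, since shrinkage invalidates
#' the classical df); this is an approximation, documented as such.
#'
#' @param m an `abundance_matrix` at stage `transformed`.
#' @param confounders data frame of confounders (age, sex, BMI, smoking,
#'   pack-years, center) or `NULL`.
#' @param alpha significance level before Bonferroni correction.
#' @param pcor_min minimum (positive) partial correlation for an edge.
#' @param denominator `"square"` (p^2 tests, the default convention) or
#'   `"pairs"` (p(p-1)/2).
#' @return an `igraph` graph: metabolite vertices (`type = "metabolite"`),
#'   edges carry `pcor`, `p` and `provenance = "ggm"`; graph attributes
#'   record the shrinkage intensity `lambda`, `n`, `alpha`, `pcor_min`
#'   and the Bonferroni `denominator`.
#' @export
estimate_ggm <- function(m, confounders = NULL, alpha = 0.05,
                         pcor_min = 0.2,
                         denominator = c("square", "pairs")) {
  assert_stage(m, "transformed", "estimate_ggm")
  denominator <- match.arg(denominator)
  Y <- m$values
  n <- nrow(Y)
  if (n < 30) stop("need at least 30 subjects for GGM estimation")
  if (!is.null(confounders)) {
    ids <- intersect(rownames(Y), rownames(confounders))
    Y <- Y[ids, , drop = FALSE]
    X <- stats::model.matrix(~ ., confounders[ids, , drop = FALSE])
    if (nrow(Y) <= ncol(X))
      stop("more confounder columns than subjects")
    Y <- residualize(Y, X)$resid
    n <- nrow(Y)
  }
  p <- ncol(Y)
  sh <- shrink_cor(Y)
  if (sh$lambda >= 1)
    warning("shrinkage intensity reached 1 (pure diagonal)")
  pc <- pcor_from_cor(sh$cor)
  z <- atanh(pmin(pmax(pc, -1 + 1e-12), 1 - 1e-12))
  pval <- 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
  denom <- if (denominator == "square") p^2 else p * (p - 1) / 2
  thr <- alpha / denom
  up <- upper.tri(pc)
  sel <- up & pc > max(pcor_min, 0) & pval < thr
  idx <- which(sel, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = colnames(Y))
  g <- igraph::set_vertex_attr(g, "type", value = "metabolite")
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]),
                           pcor = pc[sel], p = pval[sel],
                           provenance = "ggm")
  }
  g <- igraph::set_graph_attr(g, "lambda", sh$lambda)
  g <- igraph::set_graph_attr(g, "n", n)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g <- igraph::set_graph_attr(g, "pcor_min", pcor_min)
  g <- igraph::set_graph_attr(g, "denominator", denom)
  g
}

# Schaefer-Strimmer analytic shrinkage of the correlation matrix toward
# the identity: lambda* = sum var(r_ij) / sum r_ij^2 over off-diagonals.
shrink_cor <- function(Y) {
  n <- nrow(Y)
  Xs <- scale(Y)
  r <- crossprod(Xs) / (n - 1)
  W2 <- crossprod(Xs^2)            # sum_k w_kij^2 with w = x_ki x_kj
  S1 <- crossprod(Xs)              # sum_k w_kij
  var_r <- n / ((n - 1)^3) * (W2 - S1^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom <= 0) 1 else sum(var_r[off]) / denom
  lambda <- min(max(lambda, 0), 1)
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  list(cor = rs, lambda = lambda)
}

# full-order partial correlations from the inverse correlation matrix
pcor_from_cor <- function(R) {
  P <- solve(R)
  D <- 1 / sqrt(diag(P))
  pc <- -P * outer(D, D)
  diag(pc) <- 1
  pc
}

#' Attach SNP nodes from independent met-QTL results
#'
#' Adds one SNP vertex per independent met-QTL SNP and one
#' (SNP, metabolite) edge per admitted association, with edge provenance
#' `"metqtl"`. Metabolite-metabolite edges are untouched. Independent
#' SNPs whose metabolite is absent from the network are skipped with a
#' warning.
#'
#' @param net an `igraph` network from [estimate_ggm()].
#' @param ind a single `independent_set`, a list of them, or a data frame
#'   with columns `snp` and `metabolite`.
#' @return the augmented `igraph` network.
#' @export
add_snp_nodes <- function(net, ind) {
  links <- if (is.data.frame(ind)) ind
  else {
    if (inherits(ind, "independent_set")) ind <- list(ind)
    do.call(rbind, lapply(ind, function(s)
      if (nrow(s$snps)) data.frame(snp = s$snps$snp,
                                   metabolite = s$metabolite)
      else NULL))
  }
  if (is.null(links) || !nrow(links)) return(net)
  known <- igraph::V(net)$name[igraph::V(net)$type == "metabolite"]
  miss <- !(links$metabolite %in% known)
  if (any(miss)) {
    warning(sprintf("%d met-QTL link(s) to metabolites absent from the network skipped",
                    sum(miss)))
    links <- links[!miss, , drop = FALSE]
    if (!nrow(links)) return(net)
  }
  new_snps <- setdiff(unique(links$snp), igraph::V(net)$name)
  if (length(new_snps))
    net <- igraph::add_vertices(net, length(new_snps), name = new_snps,
                                type = "snp")
  net <- igraph::add_edges(net,
                           rbind(match(links$snp, igraph::V(net)$name),
                                 match(links$metabolite, igraph::V(net)$name)),
                           pcor = NA_real_, p = NA_real_,
                           provenance = "metqtl")
  net
}

#' Score a profile against a residualized phenotype
#'
#' Simple linear regression `profile ~ phenotype residual`; the score is
#' the negative base-10 logarithm of the slope p-value.
#'
#' @param profile per-sample numeric values (a metabolite or a module
#'   average).
#' @param pheno_resid phenotype residual (already adjusted for its
#'   covariates), same length/order.
#' @return list with `beta`, `p`, `score` and `flag` (`"zero_variance"`
#'   when the profile is constant, in which case the score is 0).
#' @export
score_profile <- function(profile, pheno_resid) {
  stopifnot(length(profile) == length(pheno_resid))
  ok <- stats::complete.cases(profile, pheno_resid)
  x <- pheno_resid[ok]; y <- profile[ok]
  n <- length(x)
  if (n < 3 || stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(beta = 0, p = 1, score = 0, flag = "zero_variance"))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- max(2 * stats::pt(-abs(tt), n - 2), .Machine$double.xmin)
  list(beta = r * stats::sd(y) / stats::sd(x), p = p,
       score = -log10(p), flag = NA_character_)
}

#' Greedy phenotype-driven module search
#'
#' Every metabolite node seeds a candidate module. At each step the
#' module's graph neighbors are tentatively averaged into the
#' representative profile; the best-scoring extension is admitted only if
#' its score strictly exceeds both the current module score and the score
#' of every single member (including the newcomer). After all seeds have
#' been expanded, modules significant after Bonferroni correction over
#' the number of seeds are kept; overlapping modules are merged (union)
#' when the merged module passes the same single-component rule,
#' otherwise the higher-scoring one is kept. SNP nodes are never used for
#' expansion.
#'
#' @param net an `igraph` network from [estimate_ggm()] (possibly with
#'   SNP nodes attached).
#' @param m an `abundance_matrix` at stage `transformed` sharing
#'   metabolite ids with `net`.
#' @param pheno_resid named numeric vector of phenotype residuals
#'   (names = sample ids).
#' @param alpha significance level on the Bonferroni-adjusted module
#'   p-value, default 0.05.
#' @param phenotype_name label stored on each module.
#' @return object of class `phenotype_modules`: list of modules, each
#'   with `members`, `beta`, `p`, `score`, `adjusted_p` (Bonferroni over
#'   seeds; the Table-style "adjusted score"), `seed` and
#'   `merged_from`. Convert with [as.data.frame()].
#' @export
greedy_module_search <- function(net, m, pheno_resid, alpha = 0.05,
                                 phenotype_name = "phenotype") {
  assert_stage(m, "transformed", "greedy_module_search")
  metab_v <- igraph::V(net)$name[igraph::V(net)$type == "metabolite"]
  metab_v <- intersect(metab_v, metabolite_ids(m))
  if (!length(metab_v))
    return(structure(list(), class = "phenotype_modules",
                     n_seeds = 0L, phenotype = phenotype_name))
  ids <- intersect(sample_ids(m), names(pheno_resid))
  Y <- m$values[ids, metab_v, drop = FALSE]
  ph <- pheno_resid[ids]
  singles <- vapply(metab_v, function(v)
    score_profile(Y[, v], ph)$score, 0)
  adj <- lapply(metab_v, function(v) {
    nb <- igraph::neighbors(net, v)
    intersect(nb$name[nb$type == "metabolite"], metab_v)
  })
  names(adj) <- metab_v
  n_seeds <- length(metab_v)

  expand_seed <- function(seed) {
    members <- seed
    cur <- singles[[seed]]
    repeat {
      nbrs <- setdiff(unique(unlist(adj[members])), members)
      if (!length(nbrs)) break
      cand_scores <- vapply(nbrs, function(v) {
        s <- score_profile(rowMeans(Y[, c(members, v), drop = FALSE]), ph)
        if (!is.finite(s$score)) -Inf else s$score
      }, 0)
      best <- which.max(cand_scores)   # first index wins ties
      best_v <- nbrs[best]
      if (cand_scores[best] > cur &&
          cand_scores[best] > max(singles[c(members, best_v)])) {
        members <- c(members, best_v)
        cur <- cand_scores[best]
      } else break
    }
    members
  }

  mods <- lapply(metab_v, function(seed) {
    members <- expand_seed(seed)
    s <- score_profile(rowMeans(Y[, members, drop = FALSE]), ph)
    list(members = sort(members), beta = s$beta, p = s$p, score = s$score,
         adjusted_p = min(s$p * n_seeds, 1), seed = seed,
         merged_from = character(0))
  })
  mods <- Filter(function(mo) mo$adjusted_p < alpha, mods)
  # deduplicate identical member sets
  keys <- vapply(mods, function(mo) paste(mo$members, collapse = "|"), "")
  mods <- mods[!duplicated(keys)]

  # merge overlapping modules
  repeat {
    merged_any <- FALSE
    if (length(mods) < 2) break
    for (i in seq_along(mods)) {
      for (j in seq_along(mods)) {
        if (j <= i) next
        if (!length(intersect(mods[[i]]$members, mods[[j]]$members))) next
        u <- sort(union(mods[[i]]$members, mods[[j]]$members))
        s <- score_profile(rowMeans(Y[, u, drop = FALSE]), ph)
        if (s$score > max(singles[u])) {
          merged <- list(members = u, beta = s$beta, p = s$p,
                         score = s$score,
                         adjusted_p = min(s$p * n_seeds, 1),
                         seed = mods[[i]]$seed,
                         merged_from = c(mods[[i]]$seed, mods[[j]]$seed,
                                         mods[[i]]$merged_from,
                                         mods[[j]]$merged_from))
          mods <- c(mods[-c(i, j)], list(merged))
        } else {
          drop_j <- mods[[i]]$score >= mods[[j]]$score
          mods <- mods[-if (drop_j) j else i]
        }
        merged_any <- TRUE
        break
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  mods <- Filter(function(mo) mo$adjusted_p < alpha, mods)
  structure(mods, class = "phenotype_modules", n_seeds = n_seeds,
            phenotype = phenotype_name)
}

#' @export
as.data.frame.phenotype_modules <- function(x, ...) {
  if (!length(x))
    return(data.frame(phenotype = character(), module_id = integer(),
                      members = character(), n_members = integer(),
                      beta = numeric(), p = numeric(), score = numeric(),
                      adjusted_score = numeric()))
  out <- do.call(rbind, lapply(seq_along(x), function(i) {
    mo <- x[[i]]
    data.frame(phenotype = attr(x, "phenotype"), module_id = i,
               members = paste(mo$members, collapse = ","),
               n_members = length(mo$members), beta = mo$beta, p = mo$p,
               score = mo$score, adjusted_score = mo$adjusted_p)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.phenotype_modules <- function(x, ...) {
  cat(sprintf("phenotype_modules (%s): %d significant module(s) from %d seeds\n",
              attr(x, "phenotype"), length(x), attr(x, "n_seeds")))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' Module-level variance decomposition
#'
#' Represents the module by the first principal component of its members'
#' transformed intensities (orientation fixed so the mean loading is
#' non-negative) and reports, side by side, the variance of that PC
#' explained by the members' independent met-QTL SNPs and by the clinical
#' covariates.
#'
#' @param members character vector of module member metabolite ids
#'   (>= 2).
#' @param m an `abundance_matrix` at stage `transformed`.
#' @param g a `dosage_matrix`.
#' @param ind list of `independent_set` objects (or data frame with
#'   columns `snp`, `metabolite`) giving each metabolite's independent
#'   met-QTL SNPs.
#' @param covariates covariate data frame or `NULL`.
#' @return a `variance_decomposition` with an extra `snps` field listing
#'   the member met-QTL SNPs used.
#' @export
module_variance_decomposition <- function(members, m, g, ind,
                                          covariates = NULL) {
  if (length(members) < 2) stop("module needs at least 2 members")
  assert_stage(m, "transformed", "module_variance_decomposition")
  links <- if (is.data.frame(ind)) ind
  else do.call(rbind, lapply(ind, function(s)
    if (nrow(s$snps)) data.frame(snp = s$snps$snp, metabolite = s$metabolite)
    else NULL))
  snps <- if (is.null(links)) character(0)
          else unique(links$snp[links$metabolite %in% members])
  Y <- m$values[, members, drop = FALSE]
  pc <- stats::prcomp(Y, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  sgn <- if (mean(load1) < 0) -1 else 1
  pc1 <- stats::setNames(sgn * pc$x[, 1], rownames(Y))
  vd <- variance_explained(pc1, g, snps, covariates)
  vd$snps <- snps
  vd
}
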