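#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests corrected for (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Per-metabolite phenotype regressions
#'
#' Tests every metabolite against one phenotype with a model family
#' matched to the phenotype's type. For continuous phenotypes the
#' metabolite is the response (`metabolite ~ phenotype + covariates`,
#' linear); for binary and count phenotypes the phenotype is the response
#' and the metabolite the predictor of interest (logistic /
#' negative-binomial with Poisson fallback). Rows with any missing value
#' are dropped (complete-case). Significance is flagged at
#' `bonferroni_threshold(alpha, n_metabolites)`.
#'
#' @param m an `abundance_matrix` at stage `transformed`.
#' @param phenotype named numeric vector (names = sample ids).
#' @param covariates data frame of adjustment covariates, rownames =
#'   sample ids. Default covariate set: age, sex, BMI, current smoking,
#'   pack-years, clinical center.
#' @param family `"linear"`, `"logistic"` or `"negbin"`.
#' @param phenotype_name label stored on each record.
#' @param alpha family-wise alpha for the Bonferroni flag, default 0.05.
#' @return data frame with one row per metabolite: `metabolite`,
#'   `phenotype`, `family`, `beta`, `se`, `p`, `significant`, `converged`,
#'   `n`; the threshold used is stored in attribute `threshold`.
#' @export
fit_metabolite_phenotype <- function(m, phenotype, covariates = NULL,
                                     family = c("linear", "logistic",
                                                "negbin"),
                                     phenotype_name = "phenotype",
                                     alpha = 0.05) {
  assert_stage(m, "transformed", "fit_metabolite_phenotype")
  family <- match.arg(family)
  ids <- intersect(sample_ids(m), names(phenotype))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  if (!length(ids)) stop("no overlapping samples")
  Y <- m$values[ids, , drop = FALSE]
  ph <- phenotype[ids]
  X <- if (is.null(covariates)) NULL else covariates[ids, , drop = FALSE]
  thr <- bonferroni_threshold(alpha, ncol(Y))
  recs <- lapply(seq_len(ncol(Y)), function(j) {
    df <- data.frame(.metab = Y[, j], .pheno = ph)
    if (!is.null(X)) df <- cbind(df, X)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    n_used <- nrow(df)
    res <- tryCatch({
      if (family == "linear") {
        fit <- stats::lm(.metab ~ ., data = df)
        cf <- summary(fit)$coefficients[".pheno", ]
        list(beta = cf[1], se = cf[2], p = cf[4], conv = TRUE)
      } else if (family == "logistic") {
        fit <- stats::glm(.pheno ~ ., data = df, family = stats::binomial())
        if (!fit$converged) stop("glm did not converge")
        cf <- summary(fit)$coefficients[".metab", ]
        list(beta = cf[1], se = cf[2], p = cf[4], conv = TRUE)
      } else {
        fit <- tryCatch(
          suppressWarnings(MASS::glm.nb(.pheno ~ ., data = df)),
          error = function(e)
            stats::glm(.pheno ~ ., data = df, family = stats::poisson()))
        cf <- summary(fit)$coefficients[".metab", ]
        list(beta = cf[1], se = cf[2], p = cf[4], conv = TRUE)
      }
    }, error = function(e) list(beta = NA_real_, se = NA_real_,
                                p = NA_real_, conv = FALSE))
    data.frame(metabolite = colnames(Y)[j], phenotype = phenotype_name,
               family = family, beta = unname(res$beta),
               se = unname(res$se), p = unname(res$p),
               significant = !is.na(res$p) && res$p < thr,
               converged = res$conv, n = n_used)
  })
  out <- do.call(rbind, recs)
  attr(out, "threshold") <- thr
  out
}

#' Univariate demographic screen
#'
#' Simple linear regression of each (transformed) metabolite on each
#' demographic variable separately, with Bonferroni significance over the
#' number of metabolites within each variable. Numeric and binary
#' variables use the exact t-test of the regression slope; factors use a
#' one-way ANOVA F test.
#'
#' @param m an `abundance_matrix` at stage `transformed`.
#' @param demographics data frame (rownames = sample ids) of variables to
#'   screen.
#' @param alpha family-wise alpha within each variable, default 0.05.
#' @return data frame with one row per (metabolite, variable).
#' @export
demographic_screen <- function(m, demographics, alpha = 0.05) {
  assert_stage(m, "transformed", "demographic_screen")
  ids <- intersect(sample_ids(m), rownames(demographics))
  Y <- m$values[ids, , drop = FALSE]
  thr <- bonferroni_threshold(alpha, ncol(Y))
  out <- list()
  for (v in names(demographics)) {
    x <- demographics[ids, v]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      if (nlevels(x) < 2) { warning("constant demographic '", v,
                                    "' skipped"); next }
      p <- apply(Y, 2, function(y)
        stats::anova(stats::lm(y ~ x))[["Pr(>F)"]][1])
      beta <- rep(NA_real_, ncol(Y))
    } else {
      x <- as.numeric(x)
      if (stats::sd(x, na.rm = TRUE) == 0) {
        warning("constant demographic '", v, "' skipped"); next
      }
      ok <- !is.na(x)
      n <- sum(ok)
      r <- suppressWarnings(stats::cor(x[ok], Y[ok, , drop = FALSE]))
      tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tt), n - 2)
      beta <- as.numeric(r) * apply(Y[ok, , drop = FALSE], 2, stats::sd) /
        stats::sd(x[ok])
      p <- as.numeric(p)
    }
    out[[v]] <- data.frame(metabolite = colnames(Y), variable = v,
                           beta = beta, p = p, significant = p < thr)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(metabolite = character(), variable = character(),
                         beta = numeric(), p = numeric(),
                         significant = logical())
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Group-comparison tests from cohort-table summaries
#'
#' Reproduces cohort demographics-table tests: binary traits are compared
#' across groups with a Pearson chi-square test of independence on the
#' groups x (yes, no) table (no continuity correction); continuous traits
#' with a one-way ANOVA F test reconstructed exactly from per-group n,
#' mean and SD.
#'
#' @param gs a list describing one trait: either
#'   `list(type = "binary", n = <per-group n>, count = <per-group yes>)`
#'   or `list(type = "continuous", n = , mean = , sd = )`.
#' @return the test p-value; the statistic is attached as attribute
#'   `statistic`.
#' @export
cohort_table_tests <- function(gs) {
  stopifnot(is.list(gs), gs$type %in% c("binary", "continuous"))
  if (length(gs$n) < 2) stop("need at least two groups")
  if (gs$type == "binary") {
    if (any(gs$count > gs$n)) stop("counts exceed group sizes")
    tab <- cbind(yes = gs$count, no = gs$n - gs$count)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p <- ht$p.value
    attr(p, "statistic") <- unname(ht$statistic)
    return(p)
  }
  if (any(gs$n < 2)) stop("ANOVA from summaries needs n >= 2 per group")
  if (any(gs$sd < 0)) stop("negative SD")
  n <- gs$n; mu <- gs$mean; s <- gs$sd
  N <- sum(n); k <- length(n)
  grand <- sum(n * mu) / N
  ssb <- sum(n * (mu - grand)^2)
  ssw <- sum((n - 1) * s^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  attr(p, "statistic") <- f
  p
}
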