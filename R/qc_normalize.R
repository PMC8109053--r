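#' Run-day median normalization
#'
#' Corrects multiplicative batch variation from instrument inter-day tuning:
#' each intensity is divided by its metabolite's run-day median and
#' multiplied by the metabolite's overall median, using non-missing cells
#' only. Missing cells stay missing.
#'
#' @param m an [abundance_matrix()] at stage `raw`.
#' @return an `abundance_matrix` at stage `normalized`, with attribute
#'   `qc_flags` listing (metabolite, day) blocks that were entirely missing.
#' @export
runday_normalize <- function(m) {
  assert_stage(m, "raw", "runday_normalize")
  if (anyNA(m$runday)) stop("every sample needs a run-day label")
  x <- m$values
  days <- levels(m$runday)
  flags <- list()
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    overall <- stats::median(xj, na.rm = TRUE)
    for (d in days) {
      idx <- which(m$runday == d)
      dm <- stats::median(xj[idx], na.rm = TRUE)
      if (is.na(dm)) {
        # whole (metabolite, day) block missing: leave missing, flag it
        flags[[length(flags) + 1L]] <-
          data.frame(metabolite = colnames(x)[j], runday = d)
        next
      }
      if (dm == 0)
        stop(sprintf("zero run-day median for metabolite '%s' on day '%s'",
                     colnames(x)[j], d))
      x[idx, j] <- xj[idx] * overall / dm
    }
  }
  out <- m
  out$values <- x
  out <- set_stage(out, "normalized")
  attr(out, "qc_flags") <- if (length(flags)) do.call(rbind, flags) else NULL
  out
}

#' Missingness filter
#'
#' Removes metabolites whose fraction of missing samples strictly exceeds
#' `max_missing` (a metabolite missing exactly 20% of samples is kept under
#' the default).
#'
#' @param m an `abundance_matrix` at stage `normalized`.
#' @param max_missing maximum tolerated missing fraction, default 0.20.
#' @return list with elements `abundance` (stage `filtered`) and `report`
#'   (data frame of removed metabolites and their missing fractions).
#' @export
filter_missingness <- function(m, max_missing = 0.20) {
  assert_stage(m, "normalized", "filter_missingness")
  frac <- colMeans(is.na(m$values))
  drop <- frac > max_missing
  if (all(drop))
    stop("all metabolites exceed the missingness threshold; empty result")
  report <- data.frame(metabolite = colnames(m$values)[drop],
                       missing_fraction = unname(frac[drop]))
  out <- m
  out$values <- m$values[, !drop, drop = FALSE]
  out <- set_stage(out, "filtered")
  list(abundance = out, report = report)
}

#' k-nearest-neighbor imputation across metabolites
#'
#' Each missing cell (sample i, metabolite j) is replaced by the unweighted
#' mean, over the k metabolites nearest to j, of their observed values at
#' sample i. Distance between two metabolites is the Euclidean distance over
#' samples where both are observed, scaled by the number of shared samples
#' (root mean squared difference), so metabolite pairs with different
#' overlap are comparable. If none of the k neighbors is observed at sample
#' i the metabolite's own mean is used, and the fallback is logged.
#'
#' @param m an `abundance_matrix` at stage `filtered`.
#' @param k number of neighbors, default 10.
#' @return an `abundance_matrix` at stage `imputed` with no missing cells;
#'   attribute `impute_fallbacks` records column-mean fallbacks.
#' @export
knn_impute <- function(m, k = 10) {
  assert_stage(m, "filtered", "knn_impute")
  x <- m$values
  p <- ncol(x)
  if (p < k + 1) stop("need at least k + 1 metabolites for kNN imputation")
  if (!anyNA(x)) return(set_stage(m, "imputed"))
  obs <- !is.na(x)
  # pairwise root-mean-square distance over shared observed samples
  xz <- x; xz[!obs] <- 0
  sq <- xz^2
  n_shared <- crossprod(obs)                       # shared sample counts
  cross <- crossprod(xz)
  ssq_i <- crossprod(sq, obs)                      # sum x_i^2 over shared
  d2 <- ssq_i + t(ssq_i) - 2 * cross
  dist <- sqrt(pmax(d2, 0) / pmax(n_shared, 1))
  dist[n_shared == 0] <- Inf
  diag(dist) <- Inf
  colmeans <- colMeans(x, na.rm = TRUE)
  fallbacks <- list()
  for (j in which(colSums(!obs) > 0)) {
    nb <- order(dist[, j])[seq_len(k)]
    miss_i <- which(!obs[, j])
    nbvals <- x[miss_i, nb, drop = FALSE]
    est <- rowMeans(nbvals, na.rm = TRUE)
    bad <- !is.finite(est)
    if (any(bad)) {
      est[bad] <- colmeans[j]
      fallbacks[[length(fallbacks) + 1L]] <- data.frame(
        metabolite = colnames(x)[j],
        sample = rownames(x)[miss_i[bad]])
    }
    x[miss_i, j] <- est
  }
  out <- m
  out$values <- x
  out <- set_stage(out, "imputed")
  attr(out, "impute_fallbacks") <-
    if (length(fallbacks)) do.call(rbind, fallbacks) else NULL
  out
}

#' Subject-level outlier removal
#'
#' For each metabolite, values are z-scored across subjects; each subject's
#' aggregate is the median of its metabolite z-scores; these medians are
#' standardized across subjects, and subjects whose standardized median
#' exceeds `z_cut` (two-sided by default) are removed. With fewer than three
#' subjects the standardization is degenerate and nothing is removed.
#'
#' @param m an `abundance_matrix` at stage `imputed`.
#' @param z_cut removal threshold on the standardized subject median,
#'   default 3.5.
#' @param two_sided remove on `|z| > z_cut` (default) or only high-side.
#' @return list with `abundance` (stage `imputed`; the step is repeatable)
#'   and `report` (removed subject ids and their standardized medians).
#' @export
remove_outlier_subjects <- function(m, z_cut = 3.5, two_sided = TRUE) {
  assert_stage(m, "imputed", "remove_outlier_subjects")
  x <- m$values
  n <- nrow(x)
  empty <- data.frame(sample = character(), median_z = numeric())
  if (n < 3) return(list(abundance = m, report = empty))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance metabolite(s); z-scores set to 0",
                    sum(sds == 0)))
  }
  z <- scale(x)
  z[, sds == 0] <- 0
  med <- apply(z, 1, stats::median)
  s <- stats::sd(med)
  if (!is.finite(s) || s == 0) return(list(abundance = m, report = empty))
  std <- (med - mean(med)) / s
  out_idx <- if (two_sided) abs(std) > z_cut else std > z_cut
  report <- data.frame(sample = rownames(x)[out_idx],
                       median_z = unname(std[out_idx]))
  out <- m
  out$values <- x[!out_idx, , drop = FALSE]
  out$runday <- factor(m$runday[!out_idx])
  list(abundance = out, report = report)
}

#' Rank-based inverse normal transformation
#'
#' Replaces each metabolite column by Blom scores
#' `qnorm((rank - c) / (n - 2c + 1))` with offset `c = 3/8`; ties receive
#' their average rank. Ranks (hence all rank statistics) are preserved.
#' Constant columns become all zeros with a warning.
#'
#' @param m an `abundance_matrix` at stage `imputed` with no missing cells.
#' @param offset Blom offset constant, default 3/8.
#' @return an `abundance_matrix` at stage `transformed`.
#' @export
inverse_normal_transform <- function(m, offset = 3 / 8) {
  assert_stage(m, "imputed", "inverse_normal_transform")
  x <- m$values
  if (anyNA(x)) stop("no missing cells allowed; run knn_impute first")
  n <- nrow(x)
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning(sprintf("%d constant metabolite(s) transformed to all zeros",
                    sum(const)))
  out <- apply(x, 2, function(v)
    stats::qnorm((rank(v, ties.method = "average") - offset) /
                   (n - 2 * offset + 1)))
  out[, const] <- 0
  dimnames(out) <- dimnames(x)
  res <- m
  res$values <- out
  set_stage(res, "transformed")
}

#' Full pre-analysis chain
#'
#' Convenience wrapper running run-day normalization, missingness
#' filtering, kNN imputation, outlier removal and the inverse normal
#' transformation in the required order.
#'
#' @param m an `abundance_matrix` at stage `raw`.
#' @param max_missing,k,z_cut stage parameters, see the individual steps.
#' @return list with `abundance` (stage `transformed`) and `report`, a list
#'   holding the missingness and outlier reports plus per-run-day median
#'   shifts.
#' @export
qc_preprocess <- function(m, max_missing = 0.20, k = 10, z_cut = 3.5) {
  pre_med <- tapply(rowMeans(m$values, na.rm = TRUE), m$runday, stats::median)
  norm <- runday_normalize(m)
  post_med <- tapply(rowMeans(norm$values, na.rm = TRUE), norm$runday,
                     stats::median)
  filt <- filter_missingness(norm, max_missing = max_missing)
  imp <- knn_impute(filt$abundance, k = k)
  outl <- remove_outlier_subjects(imp, z_cut = z_cut)
  trans <- inverse_normal_transform(outl$abundance)
  list(abundance = trans,
       report = list(
         metabolites_removed = filt$report,
         subjects_removed = outl$report,
         runday_median_shift = data.frame(
           runday = names(pre_med),
           median_before = as.numeric(pre_med),
           median_after = as.numeric(post_med))))
}
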