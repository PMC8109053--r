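#' One-tailed Fisher enrichment of hits within annotation groups
#'
#' For every group in `grouping`, tests over-representation of `hits`
#' against the whole `universe` with the upper-tail hypergeometric
#' (one-tailed Fisher's exact) test, then adjusts across groups with
#' Benjamini-Hochberg. Universe ids without a group are pooled into an
#' `"unannotated"` group; groups of size < 2 are kept but flagged as
#' underpowered.
#'
#' @param hits character vector of significant feature ids (subset of
#'   `universe`).
#' @param universe character vector of all tested feature ids.
#' @param grouping named character vector mapping feature id to group
#'   label (e.g. metabolite subpathway or SNP consequence class).
#' @return data frame sorted by p with columns `group`, `a` (hits in
#'   group), `b` (hits outside), `c` (non-hits in group), `d` (non-hits
#'   outside), `odds_ratio`, `p`, `q`, `significant` (q < 0.05),
#'   `underpowered`.
#' @export
fisher_enrichment <- function(hits, universe, grouping) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  hits <- unique(as.character(hits))
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  grp <- as.character(grouping[universe])
  grp[is.na(grp)] <- "unannotated"
  N <- length(universe)
  nh <- length(hits)
  is_hit <- universe %in% hits
  out <- do.call(rbind, lapply(unique(grp), function(gl) {
    ing <- grp == gl
    K <- sum(ing)
    a <- sum(ing & is_hit)
    b <- nh - a
    c_ <- K - a
    d <- N - K - b
    p <- stats::phyper(a - 1, K, N - K, nh, lower.tail = FALSE)
    orat <- (a * d) / max(b * c_, .Machine$double.eps)
    data.frame(group = gl, a = a, b = b, c = c_, d = d,
               odds_ratio = if (b * c_ == 0 && a * d > 0) Inf else orat,
               p = p, underpowered = K < 2)
  }))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < 0.05
  out <- out[order(out$p, out$group), ]
  rownames(out) <- NULL
  out[, c("group", "a", "b", "c", "d", "odds_ratio", "p", "q",
          "significant", "underpowered")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; the i-th sorted q-value is
#' `min over j >= i of p_j * m / j`, clipped at 1, returned in the
#' original order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
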