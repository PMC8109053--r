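#' Abundance matrix container
#'
#' A sample-by-metabolite grid of non-negative intensities together with the
#' per-sample run-day (batch) label and a processing-stage tag. The stage tag
#' enforces the pre-analysis order: `raw` -> `normalized` -> `filtered` ->
#' `imputed` -> `transformed`. Missing intensities are `NA`.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns;
#'   both dimensions must carry unique names.
#' @param runday character or factor of length `nrow(values)` giving the
#'   mass-spectrometry run day of each sample.
#' @param stage processing stage of `values`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, runday,
                             stage = c("raw", "normalized", "filtered",
                                       "imputed", "transformed")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and metabolite column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite ids")
  if (length(runday) != nrow(values))
    stop("`runday` must have one label per sample")
  if (stage != "transformed" && any(values < 0, na.rm = TRUE))
    stop("negative intensities are not allowed before the transformed stage")
  structure(
    list(values = values, runday = factor(runday), stage = stage),
    class = "abundance_matrix")
}

stage_order <- c("raw", "normalized", "filtered", "imputed", "transformed")

assert_stage <- function(m, required, op) {
  if (!inherits(m, "abundance_matrix"))
    stop(op, " expects an abundance_matrix")
  if (!m$stage %in% required)
    stop(sprintf("%s requires stage %s but got '%s': pipeline order is %s",
                 op, paste(sQuote(required), collapse = " or "), m$stage,
                 paste(stage_order, collapse = " -> ")))
  invisible(m)
}

set_stage <- function(m, stage) {
  m$stage <- stage
  m
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d metabolites (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  run days: %d; missing cells: %d (%.1f%%)\n",
              nlevels(x$runday), sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

sample_ids <- function(m) rownames(m$values)
metabolite_ids <- function(m) colnames(m$values)

#' Dosage matrix container
#'
#' Sample-by-SNP additive allele dosages in \[0, 2\] with per-SNP metadata
#' (chromosome, position, alleles, effect-allele frequency, consequence
#' class, nearest-gene label).
#'
#' @param dosages numeric matrix in \[0, 2\], samples in rows, SNPs in
#'   columns, both dimensions named.
#' @param info data frame with one row per SNP; must contain a `snp` column
#'   matching `colnames(dosages)`. Recognised optional columns: `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `consequence`, `gene`.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, info = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("`dosages` must have sample row names and SNP column names")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 2 + 1e-8)
    stop("dosages must lie in [0, 2]")
  if (is.null(info)) {
    info <- data.frame(snp = colnames(dosages), stringsAsFactors = FALSE)
  }
  if (!"snp" %in% names(info)) stop("`info` needs a 'snp' column")
  info <- info[match(colnames(dosages), info$snp), , drop = FALSE]
  if (anyNA(info$snp))
    stop("`info` is missing metadata rows for some SNPs")
  if (is.null(info$eaf)) info$eaf <- colMeans(dosages, na.rm = TRUE) / 2
  rownames(info) <- NULL
  structure(list(dosages = dosages, info = info), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)
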