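#' @name io
#' @title File formats
#' @description
#' All tabular files are tab-separated with `#`-prefixed metadata header
#' lines. The abundance table has samples in rows: first column
#' `sample_id`, a reserved `runday` column, then one column per
#' metabolite; missing cells are empty or `NA`. Genotypes are either a
#' TSV dosage matrix (samples x SNPs, values in \[0, 2\], SNP metadata in
#' a sidecar TSV) or a VCF whose `DS` field (fallback: `GT` allele count)
#' supplies dosages. Networks export to GraphML and SIF for Cytoscape.
NULL

tsv_header <- function(what, extra = character()) {
  c(sprintf("# mqtlnet %s", what),
    sprintf("# generated %s", format(Sys.time(), "%Y-%m-%d")),
    extra)
}

write_tsv <- function(df, path, what, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(what, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = c("NA", ""),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read an abundance table
#'
#' @param m an `abundance_matrix`.
#' @param path file path.
#' @return `read_abundance` returns an `abundance_matrix` at the stage
#'   recorded in the file header (default `raw`).
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(sample_id = sample_ids(m), runday = as.character(m$runday),
                   m$values, check.names = FALSE)
  write_tsv(df, path, "abundance", sprintf("# stage %s", m$stage))
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  hdr <- readLines(path, n = 10)
  stage_line <- grep("^# stage ", hdr, value = TRUE)
  stage <- if (length(stage_line)) sub("^# stage ", "", stage_line[1])
           else "raw"
  df <- read_tsv(path)
  if (!all(c("sample_id", "runday") %in% names(df)))
    stop("abundance table needs 'sample_id' and 'runday' columns")
  met <- setdiff(names(df), c("sample_id", "runday"))
  if (anyDuplicated(met)) stop("duplicate metabolite ids in ", path)
  vals <- as.matrix(df[met])
  rownames(vals) <- df$sample_id
  abundance_matrix(vals, df$runday, stage = stage)
}

#' Write / read genotype dosages
#'
#' TSV route: dosage matrix with first column `sample_id` plus a sidecar
#' metadata table. VCF route: dosages from the `DS` FORMAT field, or the
#' `GT` allele count when `DS` is absent.
#'
#' @param g a `dosage_matrix`.
#' @param path dosage TSV path (or VCF for [read_genotypes()]).
#' @param info_path sidecar SNP metadata TSV path (optional).
#' @return `read_genotypes` returns a `dosage_matrix`.
#' @export
write_dosages <- function(g, path, info_path = NULL) {
  df <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE)
  write_tsv(df, path, "dosages")
  if (!is.null(info_path)) write_tsv(g$info, info_path, "snp metadata")
  invisible(path)
}

#' @rdname write_dosages
#' @export
read_genotypes <- function(path, info_path = NULL) {
  info <- if (!is.null(info_path)) read_tsv(info_path) else NULL
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    d <- read_vcf_dosages(path)
    if (!is.null(info)) {
      merged <- merge(d$info["snp"], info, by = "snp", all.x = TRUE,
                      sort = FALSE)
      for (cl in setdiff(names(d$info), "snp"))
        if (!cl %in% names(merged)) merged[[cl]] <- d$info[[cl]]
      info <- merged
    } else info <- d$info
    return(dosage_matrix(d$dosages, info))
  }
  df <- read_tsv(path)
  if (!"sample_id" %in% names(df)) stop("dosage table needs 'sample_id'")
  vals <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(vals) <- df$sample_id
  dosage_matrix(vals, info)
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(x) {
        if (is.na(x)) return(NA_real_)
        sum(as.numeric(strsplit(x, "[/|]")[[1]]) > 0)
      }, 0)
    })
  } else stop("VCF has neither DS nor GT FORMAT fields")
  rownames(ds) <- ids
  info <- data.frame(snp = ids, chrom = fix$CHROM,
                     pos = suppressWarnings(as.integer(fix$POS)),
                     effect_allele = fix$ALT, other_allele = fix$REF,
                     stringsAsFactors = FALSE)
  list(dosages = t(ds), info = info)
}

#' Write a minimal dosage VCF
#'
#' Emits VCFv4.2 with a `DS` FORMAT field carrying the additive dosages;
#' the effect allele is written as ALT.
#'
#' @param g a `dosage_matrix` whose `info` carries `chrom`, `pos` and
#'   alleles.
#' @param path output path (plain text).
#' @export
write_vcf <- function(g, path) {
  info <- g$info
  stopifnot(all(c("chrom", "pos") %in% names(info)))
  samples <- rownames(g$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  ref <- if (is.null(info$other_allele)) rep("A", nrow(info))
         else info$other_allele
  alt <- if (is.null(info$effect_allele)) rep("G", nrow(info))
         else info$effect_allele
  for (j in seq_len(nrow(info))) {
    ds <- formatC(g$dosages[, j], format = "g", digits = 6)
    ds[is.na(g$dosages[, j])] <- "."
    writeLines(paste(c(info$chrom[j], info$pos[j], info$snp[j], ref[j],
                       alt[j], ".", "PASS", ".", "DS", ds),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Splits a sample-keyed TSV into the phenotype columns (`fev1pp`,
#' `fev1_fvc`, `pct_emphysema`, `exacerbation_count`,
#' `chronic_bronchitis`, `gold_group`) and everything else as covariates.
#'
#' @param path TSV path with a `sample_id` column.
#' @return list with data frames `phenotypes` and `covariates`, both
#'   rownamed by sample id.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv(path)
  if (!"sample_id" %in% names(df)) stop("phenotype table needs 'sample_id'")
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  ph_cols <- intersect(c(phenotype_names, "gold_group"), names(df))
  if ("center" %in% names(df)) df$center <- factor(df$center)
  list(phenotypes = df[, ph_cols, drop = FALSE],
       covariates = df[, setdiff(names(df), ph_cols), drop = FALSE])
}

#' Write a synthetic cohort to pipeline input files
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param genotype_format `"tsv"` or `"vcf"`.
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             snp_info = file.path(dir, "snp_info.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_abundance(cohort$abundance, paths["abundance"])
  pheno <- data.frame(sample_id = rownames(cohort$phenotypes),
                      cohort$phenotypes,
                      cohort$covariates[rownames(cohort$phenotypes), ,
                                        drop = FALSE],
                      check.names = FALSE)
  write_tsv(pheno, paths["phenotypes"], "phenotypes+covariates",
            sprintf("# seed %d", cohort$truth$seed))
  write_tsv(cohort$annotation, paths["annotation"], "metabolite annotation")
  write_tsv(cohort$truth |> truth_report(), paths["truth"], "planted truth",
            sprintf("# seed %d", cohort$truth$seed))
  if (genotype_format == "vcf") {
    paths["genotypes"] <- file.path(dir, "genotypes.vcf")
    write_vcf(cohort$dosage, paths["genotypes"])
    write_tsv(cohort$dosage$info, paths["snp_info"], "snp metadata")
  } else {
    paths["genotypes"] <- file.path(dir, "genotypes.tsv")
    write_dosages(cohort$dosage, paths["genotypes"], paths["snp_info"])
  }
  paths
}

#' Export a network for Cytoscape
#'
#' @param net an `igraph` network (metabolite/SNP nodes).
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(net, path) {
  el <- igraph::as_edgelist(net)
  prov <- igraph::E(net)$provenance
  if (is.null(prov)) prov <- rep("ggm", nrow(el))
  writeLines(paste(el[, 1], prov, el[, 2], sep = "\t"), path)
  invisible(path)
}
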