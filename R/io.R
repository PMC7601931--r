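#' Read a long-format genotype table
#'
#' Expects a tab-separated file with a header and one row per
#' (sample, SNP): columns `sample_id`, `snp_id`, `genotype`. The genotype
#' is a two-character allele string such as `"GA"`; allele order is
#' irrelevant (`"AG"` parses to the same stored genotype). Missing calls
#' are coded `"NA"` or `"./."` and are kept as missing entries — the
#' sample itself is retained.
#'
#' @param path file path.
#' @param snp_defs list of [snp_def()]s declaring every SNP in the file.
#' @param samples optional samples data.frame (`sample_id`, `status`,
#'   `stage`); when omitted, all samples are provisionally labelled
#'   `"control"` and the caller is expected to attach real labels.
#' @return A [cohort()] holding the genotype calls.
#' @export
read_genotype_table <- function(path, snp_defs, samples = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "snp_id", "genotype")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  if (is.list(snp_defs) && inherits(snp_defs, "snp_def"))
    snp_defs <- list(snp_defs)
  ids <- vapply(snp_defs, `[[`, character(1), "snp_id")
  unknown <- which(!tab$snp_id %in% ids)
  if (length(unknown))
    stop("row ", unknown[1L], ": unknown snp_id '", tab$snp_id[unknown[1L]], "'")
  missing_code <- tab$genotype %in% c("NA", "./.", ".", "")
  a1 <- ifelse(missing_code, NA_character_, substr(tab$genotype, 1L, 1L))
  a2 <- ifelse(missing_code, NA_character_, substr(tab$genotype, 2L, 2L))
  if (any(!missing_code & nchar(tab$genotype) != 2L))
    stop("malformed genotype string: '",
         tab$genotype[!missing_code & nchar(tab$genotype) != 2L][1L], "'")
  gt <- data.frame(sample_id = tab$sample_id, snp_id = tab$snp_id,
                   a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- data.frame(sample_id = unique(tab$sample_id),
                          status = "control", stringsAsFactors = FALSE)
  cohort(samples, snp_defs, genotypes = gt)
}

#' Write a long-format genotype table
#'
#' Inverse of [read_genotype_table()]: one row per (sample, SNP) with the
#' canonical genotype string; missing calls written as `"NA"`.
#'
#' @param cohort a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path) {
  gt <- cohort$genotypes
  out <- data.frame(sample_id = gt$sample_id, snp_id = gt$snp_id,
                    genotype = ifelse(is.na(gt$a1), "NA",
                                      paste0(gt$a1, gt$a2)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Supports the subset of VCF v4.x this pipeline consumes: biallelic SNP
#' records with a GT field. `0/0`, `0/1`, `1/1` (and their phased `|`
#' forms) map to ref-hom / het / alt-hom; `./.` maps to missing.
#' Multi-allelic records are skipped with a warning; records without GT
#' are an error.
#'
#' @param path VCF file path.
#' @param samples optional samples data.frame as in
#'   [read_genotype_table()].
#' @return A [cohort()]; SNP definitions are built from ID/REF/ALT with
#'   the ALT allele provisionally taken as the minor allele.
#' @export
read_vcf_subset <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  if (any(multi))
    warning(sum(multi), " multi-allelic/non-SNP record(s) skipped",
            call. = FALSE)
  if (all(multi)) stop("no usable biallelic SNP records in ", path)
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("GT field absent from VCF record")
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  gt_mat <- gt_mat[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  snp_ids <- fix[, "ID"]
  snp_defs <- lapply(seq_along(snp_ids), function(i)
    snp_def(snp_ids[i], gene = NA_character_,
            ref_allele = fix[i, "REF"], alt_allele = fix[i, "ALT"]))
  rows <- list()
  for (i in seq_along(snp_ids)) {
    g <- gsub("|", "/", gt_mat[i, ], fixed = TRUE)
    a1 <- a2 <- rep(NA_character_, length(g))
    known <- !is.na(g) & g != "./."
    code <- g[known]
    if (!all(code %in% c("0/0", "0/1", "1/0", "1/1")))
      stop("unsupported GT code '", setdiff(code, c("0/0","0/1","1/0","1/1"))[1L],
           "' at ", snp_ids[i])
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    a1[known] <- ifelse(substr(code, 1, 1) == "0", ref, alt)
    a2[known] <- ifelse(substr(code, 3, 3) == "0", ref, alt)
    rows[[i]] <- data.frame(sample_id = unname(colnames(gt_mat)),
                            snp_id = unname(snp_ids[i]),
                            a1 = unname(a1), a2 = unname(a2),
                            stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, rows)
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(gt_mat),
                          status = "control", stringsAsFactors = FALSE)
  cohort(samples, snp_defs, genotypes = gt)
}

#' Read a samples table
#'
#' Tab-separated, header required: `sample_id`, `status`
#' (`case`/`control`) and optionally `stage` (0-4, blank/NA allowed).
#'
#' @param path file path.
#' @return data.frame suitable for the `samples` argument of [cohort()].
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab)))
    stop("samples table must have columns sample_id, status")
  tab$sample_id <- as.character(tab$sample_id)
  if (!is.null(tab$stage)) tab$stage <- as.integer(tab$stage)
  tab
}

#' Read a phenotype table
#'
#' Tab-separated, header required: `sample_id`, `phenotype_id`, `value`,
#' `units`.
#'
#' @param path file path.
#' @return data.frame suitable for the `phenotypes` argument of
#'   [cohort()].
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype_id", "value", "units")
  if (!all(need %in% names(tab)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  tab$value <- as.numeric(tab$value)
  tab
}

#' Read a copy-number table
#'
#' Tab-separated, header required: `sample_id`, `gene_id`, `copy_number`.
#'
#' @param path file path.
#' @return data.frame suitable for the `copy_numbers` argument of
#'   [cohort()].
#' @export
read_cnv_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "copy_number")
  if (!all(need %in% names(tab)))
    stop("CNV table must have columns: ", paste(need, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  tab$copy_number <- as.integer(tab$copy_number)
  tab
}

#' Write all cohort tables to a directory
#'
#' Emits `samples.tsv`, `genotypes.tsv`, `cnv.tsv` and `phenotypes.tsv`
#' in the formats the corresponding readers expect, so a generated cohort
#' round-trips losslessly.
#'
#' @param cohort a [cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  utils::write.table(cohort$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_genotype_table(cohort, paths["genotypes"])
  utils::write.table(cohort$copy_numbers, paths["cnv"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir directory containing the four TSVs.
#' @param snp_defs list of [snp_def()]s.
#' @return A [cohort()].
#' @export
read_cohort <- function(dir, snp_defs) {
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  co <- read_genotype_table(file.path(dir, "genotypes.tsv"), snp_defs,
                            samples = samples)
  cnv_path <- file.path(dir, "cnv.tsv")
  phe_path <- file.path(dir, "phenotypes.tsv")
  cn <- if (file.exists(cnv_path)) read_cnv_table(cnv_path) else NULL
  ph <- if (file.exists(phe_path)) read_phenotype_table(phe_path) else NULL
  cohort(samples, co$snp_defs, genotypes = co$genotypes,
         copy_numbers = cn, phenotypes = ph)
}
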