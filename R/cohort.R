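#' Define a SNP
#'
#' A SNP definition carries the rsID, the gene it belongs to, its two
#' alleles and which of them is the minor allele in the pooled cohort.
#' The minor allele is the one whose homozygote frequency enters the
#' Hardy-Weinberg departure coefficient (see [hwe_f()]), matching the
#' convention of reporting genotypes major-allele-first.
#'
#' @param snp_id rsID string, e.g. `"rs3803800"`.
#' @param gene gene symbol, e.g. `"TNFSF13"`.
#' @param ref_allele,alt_allele single-character nucleotide codes.
#' @param minor_allele the minor allele; must be one of `ref_allele`,
#'   `alt_allele`. Defaults to `alt_allele`.
#' @return An object of class `snp_def`.
#' @examples
#' snp_def("rs3803800", "TNFSF13", "G", "A")
#' @export
snp_def <- function(snp_id, gene, ref_allele, alt_allele,
                    minor_allele = alt_allele) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L,
            nchar(ref_allele) == 1L, nchar(alt_allele) == 1L)
  if (ref_allele == alt_allele)
    stop("ref and alt allele must differ for ", snp_id)
  if (!minor_allele %in% c(ref_allele, alt_allele))
    stop("minor allele '", minor_allele, "' is not an allele of ", snp_id)
  structure(list(snp_id = snp_id, gene = gene,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 minor_allele = minor_allele),
            class = "snp_def")
}

#' @export
print.snp_def <- function(x, ...) {
  cat(sprintf("<snp_def> %s (%s) %s>%s, minor = %s\n", x$snp_id, x$gene,
              x$ref_allele, x$alt_allele, x$minor_allele))
  invisible(x)
}

#' Assemble a cohort
#'
#' A cohort bundles the per-sample tables every analysis stage consumes:
#' sample status (case/control) and optional ordinal clinical stage,
#' long-format genotype calls, gene copy-number calls and quantitative
#' phenotypes. Genotypes are stored canonically (reference allele first)
#' so `"GA"` and `"AG"` compare equal.
#'
#' @param samples data.frame with columns `sample_id`, `status`
#'   (`"case"`/`"control"`) and optionally `stage` (integer 0-4 or NA).
#' @param snp_defs list of [snp_def()] objects.
#' @param genotypes data.frame with columns `sample_id`, `snp_id`, `a1`,
#'   `a2` (missing calls as NA alleles). Defaults to empty.
#' @param copy_numbers data.frame with columns `sample_id`, `gene_id`,
#'   `copy_number`. Defaults to empty.
#' @param phenotypes data.frame with columns `sample_id`, `phenotype_id`,
#'   `value`, `units`. Percent-scaled phenotypes (units `"%"`) must lie in
#'   `[0, 100]`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(samples, snp_defs, genotypes = NULL,
                   copy_numbers = NULL, phenotypes = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "status") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in cohort")
  if (!all(samples$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (is.null(samples$stage)) samples$stage <- NA_integer_
  st <- samples$stage[!is.na(samples$stage)]
  if (length(st) && !all(st %in% 0:4))
    stop("stage must be an integer in 0..4")

  if (is.list(snp_defs) && inherits(snp_defs, "snp_def"))
    snp_defs <- list(snp_defs)
  stopifnot(all(vapply(snp_defs, inherits, logical(1), "snp_def")))
  names(snp_defs) <- vapply(snp_defs, `[[`, character(1), "snp_id")

  empty_gt <- data.frame(sample_id = character(), snp_id = character(),
                         a1 = character(), a2 = character(),
                         stringsAsFactors = FALSE)
  if (is.null(genotypes)) genotypes <- empty_gt
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (nrow(genotypes)) {
    unknown <- setdiff(unique(genotypes$snp_id), names(snp_defs))
    if (length(unknown))
      stop("genotypes reference undeclared SNP(s): ",
           paste(unknown, collapse = ", "))
    for (id in unique(genotypes$snp_id)) {
      snp <- snp_defs[[id]]
      sel <- which(genotypes$snp_id == id)
      a1 <- genotypes$a1[sel]; a2 <- genotypes$a2[sel]
      known <- !is.na(a1) & !is.na(a2)
      bad <- c(setdiff(a1[known], c(snp$ref_allele, snp$alt_allele)),
               setdiff(a2[known], c(snp$ref_allele, snp$alt_allele)))
      if (length(bad))
        stop("allele '", bad[1L], "' is not an allele of ", id,
             " (", snp$ref_allele, "/", snp$alt_allele, ")")
      # canonical order: reference allele first
      flip <- known & a1 != a2 & a1 != snp$ref_allele
      tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
      genotypes$a1[sel] <- a1; genotypes$a2[sel] <- a2
    }
  }

  if (is.null(copy_numbers))
    copy_numbers <- data.frame(sample_id = character(),
                               gene_id = character(),
                               copy_number = integer(),
                               stringsAsFactors = FALSE)
  if (is.null(phenotypes))
    phenotypes <- data.frame(sample_id = character(),
                             phenotype_id = character(),
                             value = numeric(), units = character(),
                             stringsAsFactors = FALSE)
  if (nrow(phenotypes)) {
    pct <- phenotypes$units == "%" & !is.na(phenotypes$value)
    if (any(pct & (phenotypes$value < 0 | phenotypes$value > 100)))
      stop("percent phenotypes must lie in [0, 100]")
  }

  structure(list(samples = samples, snp_defs = snp_defs,
                 genotypes = genotypes, copy_numbers = copy_numbers,
                 phenotypes = phenotypes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d cases / %d controls), %d SNPs\n",
              nrow(x$samples), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), length(x$snp_defs)))
  invisible(x)
}

#' Genotype counts at one SNP
#'
#' The three-cell tally that drives the Hardy-Weinberg and association
#' machinery. `n_alt_hom` counts homozygotes of the SNP's *minor* allele
#' (the allele whose homozygote frequency enters the departure
#' coefficient); `n_ref_hom` counts homozygotes of the major allele.
#'
#' @param n_ref_hom,n_het,n_alt_hom non-negative integer counts; total
#'   must be positive.
#' @param snp_id optional rsID label.
#' @return Object of class `genotype_counts`.
#' @examples
#' genotype_counts(261, 142, 36, "rs3803800")
#' @export
genotype_counts <- function(n_ref_hom, n_het, n_alt_hom, snp_id = NA_character_) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  stopifnot(length(counts) == 3L, all(counts >= 0),
            all(counts == round(counts)))
  if (sum(counts) <= 0) stop("empty tally")
  structure(list(n_ref_hom = as.integer(n_ref_hom),
                 n_het = as.integer(n_het),
                 n_alt_hom = as.integer(n_alt_hom),
                 n = as.integer(sum(counts)), snp_id = snp_id),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s: ref-hom %d, het %d, alt-hom %d (n = %d)\n",
              ifelse(is.na(x$snp_id), "?", x$snp_id),
              x$n_ref_hom, x$n_het, x$n_alt_hom, x$n))
  invisible(x)
}

#' Tally genotypes for one SNP and study arm
#'
#' Counts genotypes over samples of the given status, orienting the tally
#' to the SNP's declared minor allele: `n_alt_hom` is the minor-allele
#' homozygote count. Samples missing a call at this SNP are excluded from
#' this SNP's tally only (no sample-wide dropping, no imputation).
#'
#' @param cohort a [cohort()], QC already applied.
#' @param snp_id rsID of a declared SNP.
#' @param status `"case"` or `"control"`.
#' @return A [genotype_counts()] with attribute `n_missing`.
#' @export
tally_genotypes <- function(cohort, snp_id, status = c("case", "control")) {
  status <- match.arg(status)
  snp <- cohort$snp_defs[[snp_id]]
  if (is.null(snp)) stop("unknown SNP: ", snp_id)
  ids <- cohort$samples$sample_id[cohort$samples$status == status]
  gt <- cohort$genotypes[cohort$genotypes$snp_id == snp_id &
                         cohort$genotypes$sample_id %in% ids, , drop = FALSE]
  miss <- is.na(gt$a1) | is.na(gt$a2)
  # samples with no genotype row at all count as missing too
  n_missing <- sum(miss) + sum(!ids %in% gt$sample_id)
  gt <- gt[!miss, , drop = FALSE]
  if (!nrow(gt)) stop("empty tally for ", snp_id, " (", status, ")")
  minor <- snp$minor_allele
  n_minor <- (gt$a1 == minor) + (gt$a2 == minor)
  out <- genotype_counts(sum(n_minor == 0L), sum(n_minor == 1L),
                         sum(n_minor == 2L), snp_id)
  attr(out, "n_missing") <- n_missing
  out
}

#' Exclude samples carrying a single gene copy
#'
#' The study genes sit on chromosome 17p, a region recurrently deleted in
#' CLL; a hemizygous deletion leaves only one allele, so genotype calls
#' there do not represent a diploid genotype. Any sample whose copy number
#' is below `threshold` for *any* listed gene is removed from all
#' downstream analyses. Samples without a copy-number call for a listed
#' gene are retained with a warning: absence of the assay is a data
#' defect, not evidence of deletion.
#'
#' @param cohort a [cohort()].
#' @param genes character vector of gene ids to screen.
#' @param threshold minimum retained copy number (default 2).
#' @return The filtered cohort, with attribute `exclusion_report`: a list
#'   with `removed` (sample ids) and `single_copy_fraction` (per gene,
#'   over samples with a call).
#' @export
apply_cnv_exclusion <- function(cohort, genes, threshold = 2L) {
  cn <- cohort$copy_numbers
  cn <- cn[cn$gene_id %in% genes, , drop = FALSE]
  removed <- character(0)
  frac <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    cng <- cn[cn$gene_id == g, , drop = FALSE]
    uncalled <- setdiff(cohort$samples$sample_id, cng$sample_id)
    if (length(uncalled))
      warning(length(uncalled), " sample(s) lack a copy-number call for ",
              g, "; retained", call. = FALSE)
    low <- cng$sample_id[cng$copy_number < threshold]
    frac[g] <- if (nrow(cng)) length(low) / nrow(cng) else 0
    removed <- union(removed, low)
  }
  removed <- intersect(cohort$samples$sample_id, removed)
  keep <- !cohort$samples$sample_id %in% removed
  out <- cohort
  out$samples <- cohort$samples[keep, , drop = FALSE]
  kept_ids <- out$samples$sample_id
  out$genotypes <- cohort$genotypes[cohort$genotypes$sample_id %in% kept_ids, ,
                                    drop = FALSE]
  out$copy_numbers <- cohort$copy_numbers[
    cohort$copy_numbers$sample_id %in% kept_ids, , drop = FALSE]
  out$phenotypes <- cohort$phenotypes[
    cohort$phenotypes$sample_id %in% kept_ids, , drop = FALSE]
  attr(out, "exclusion_report") <- list(removed = removed,
                                        single_copy_fraction = frac,
                                        threshold = threshold,
                                        genes = genes)
  out
}

# Genotype display string: canonical order, ref allele first (e.g. "GA").
genotype_label <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), NA_character_, paste0(a1, a2))
}
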