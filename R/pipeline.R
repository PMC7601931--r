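#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates QC (CNV exclusion), Hardy-Weinberg and association
#' reporting, and the quantitative genotype-/stage-phenotype analyses
#' from a single configuration, writing CSV tables and a run log to an
#' output directory. Given identical inputs and seed, the outputs are
#' byte-identical across reruns.
#'
#' The configuration is a named list (or path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{snps}{list of SNP declarations: `snp_id`, `gene`, `ref`,
#'     `alt`, optional `minor` (default `alt`).}
#'   \item{samples,genotypes}{paths to the samples and genotype TSVs
#'     (see [read_sample_table()], [read_genotype_table()]); `vcf` may
#'     replace `genotypes`.}
#'   \item{cnv,phenotypes}{optional paths to the CNV and phenotype TSVs.}
#'   \item{cnv_genes}{genes screened by the single-copy exclusion
#'     (default: all genes in the CNV table).}
#'   \item{contrasts}{optional list of quantitative analyses, each with
#'     `phenotype_id`, `group_by` (an rsID, or `"stage"`), optional
#'     `weights` (default: centered linear trend), and optional flags
#'     `boxcox`, `bootstrap`.}
#'   \item{flags}{optional list: `correction` (default
#'     `"haldane_anscombe"`), `alpha` (default 0.05), `bh` (default
#'     FALSE), `B` (default 10000), `seed` (mandatory when any bootstrap
#'     is enabled).}
#' }
#'
#' @param config named list or YAML path as above.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the result objects (`cohort`,
#'   `association`, `quant_tests`, `quant_summaries`, `exclusions`) and
#'   the written `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  flags <- config$flags
  if (is.null(flags)) flags <- list()
  correction <- if (is.null(flags$correction)) "haldane_anscombe" else
    flags$correction
  alpha <- if (is.null(flags$alpha)) 0.05 else flags$alpha
  bh <- isTRUE(flags$bh)
  B <- if (is.null(flags$B)) 10000L else as.integer(flags$B)
  seed <- flags$seed
  any_boot <- any(vapply(config$contrasts, function(cs)
    isTRUE(cs$bootstrap), logical(1)))
  if (any_boot && is.null(seed))
    stop("[config] seed is mandatory when bootstrap is enabled")

  # --- stage: load -------------------------------------------------------
  snp_defs <- tryCatch(
    lapply(config$snps, function(s)
      snp_def(s$snp_id, s$gene, s$ref, s$alt,
              minor_allele = if (is.null(s$minor)) s$alt else s$minor)),
    error = function(e) stop("[load] ", conditionMessage(e)))
  co <- tryCatch({
    samples <- read_sample_table(config$samples)
    base <- if (!is.null(config$vcf)) {
      v <- read_vcf_subset(config$vcf, samples = samples)
      cohort(samples, snp_defs, genotypes = v$genotypes)
    } else {
      read_genotype_table(config$genotypes, snp_defs, samples = samples)
    }
    cn <- if (!is.null(config$cnv)) read_cnv_table(config$cnv) else NULL
    ph <- if (!is.null(config$phenotypes) && file.exists(config$phenotypes))
      read_phenotype_table(config$phenotypes) else NULL
    cohort(samples, snp_defs, genotypes = base$genotypes,
           copy_numbers = cn, phenotypes = ph)
  }, error = function(e) stop("[load] ", conditionMessage(e)))
  say("loaded %d samples (%d cases, %d controls), %d SNPs",
      nrow(co$samples), sum(co$samples$status == "case"),
      sum(co$samples$status == "control"), length(co$snp_defs))

  # --- stage: QC ---------------------------------------------------------
  exclusions <- data.frame(sample_id = character(), stringsAsFactors = FALSE)
  if (nrow(co$copy_numbers)) {
    genes <- if (is.null(config$cnv_genes))
      unique(co$copy_numbers$gene_id) else config$cnv_genes
    co <- tryCatch(apply_cnv_exclusion(co, genes),
                   error = function(e) stop("[qc] ", conditionMessage(e)))
    rep_ <- attr(co, "exclusion_report")
    exclusions <- data.frame(sample_id = rep_$removed,
                             stringsAsFactors = FALSE)
    say("CNV exclusion (%s): removed %d sample(s); single-copy fractions: %s",
        paste(genes, collapse = ", "), length(rep_$removed),
        paste(sprintf("%s = %.2f%%", names(rep_$single_copy_fraction),
                      100 * rep_$single_copy_fraction), collapse = ", "))
  } else {
    say("no copy-number data; CNV exclusion skipped")
  }

  # --- stage: association ------------------------------------------------
  assoc <- tryCatch(
    association_report(co, correction = correction, bh = bh),
    error = function(e) stop("[association] ", conditionMessage(e)))
  for (snp in unique(assoc$snp)) {
    r <- assoc[assoc$snp == snp, ][1L, ]
    say("%s: chi2(df = %d) = %.2f, p = %.4f; HWE f case/ctrl = %.2f/%.2f",
        snp, r$df, r$chisq, r$p, r$f_case, r$f_ctrl)
  }

  # --- stage: quantitative ----------------------------------------------
  quant_tests <- list()
  quant_summaries <- list()
  if (length(config$contrasts) && !nrow(co$phenotypes)) {
    warning("[quant] no phenotype data; quantitative stage skipped",
            call. = FALSE)
    say("quantitative stage skipped: no phenotype data")
  } else if (length(config$contrasts)) {
    for (ci in seq_along(config$contrasts)) {
      cs <- config$contrasts[[ci]]
      res <- tryCatch(
        quant_analysis(co, cs$phenotype_id, cs$group_by,
                       weights = cs$weights,
                       boxcox = isTRUE(cs$boxcox),
                       bootstrap = isTRUE(cs$bootstrap),
                       B = B,
                       seed = if (is.null(seed)) NULL else seed + ci,
                       alpha = alpha),
        error = function(e) stop("[quant] ", conditionMessage(e)))
      quant_tests[[ci]] <- res$tests
      quant_summaries[[ci]] <- res$summary
      say("%s by %s: F(%d, %d) = %.3f, p = %.4f, LSD: %s",
          cs$phenotype_id, cs$group_by, res$anova$df_between,
          res$anova$df_within, res$anova$F, res$anova$p_parametric,
          res$lsd$notation)
      if (!is.na(res$anova$advisory))
        say("advisory [%s by %s]: %s", cs$phenotype_id, cs$group_by,
            res$anova$advisory)
    }
  }

  # --- stage: write ------------------------------------------------------
  paths <- c(association = file.path(out_dir, "association_report.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             quant_tests = file.path(out_dir, "quant_tests.csv"),
             quant_summary = file.path(out_dir, "quant_summary.csv"),
             log = file.path(out_dir, "run.log"))
  utils::write.csv(assoc, paths["association"], row.names = FALSE)
  utils::write.csv(exclusions, paths["exclusions"], row.names = FALSE)
  if (length(quant_tests)) {
    utils::write.csv(do.call(rbind, quant_tests), paths["quant_tests"],
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, quant_summaries),
                     paths["quant_summary"], row.names = FALSE)
  } else {
    paths <- paths[setdiff(names(paths), c("quant_tests", "quant_summary"))]
  }
  writeLines(log_lines, paths["log"])
  invisible(list(cohort = co, association = assoc,
                 quant_tests = if (length(quant_tests))
                   do.call(rbind, quant_tests) else NULL,
                 quant_summaries = if (length(quant_summaries))
                   do.call(rbind, quant_summaries) else NULL,
                 exclusions = exclusions, paths = paths))
}

#' One quantitative genotype- or stage-phenotype analysis
#'
#' Groups one phenotype of the case arm by genotype at a SNP (group order
#' = minor-allele dose 0, 1, 2) or by Rai stage, then runs the one-way
#' ANOVA (with optional Box-Cox and bootstrap p), the planned linear
#' contrast (default: centered equally spaced trend weights), Fisher's
#' LSD, and the descriptive summary.
#'
#' @param cohort a [cohort()].
#' @param phenotype_id which phenotype to analyse.
#' @param group_by an rsID, or `"stage"`.
#' @param weights optional contrast weights (default: linear trend over
#'   the group order).
#' @param boxcox,bootstrap,B,seed analysis flags (see [anova_oneway()]).
#' @param alpha LSD significance level.
#' @return List with `groups`, `anova`, `contrast`, `lsd`, `summary`
#'   (data.frame) and `tests` (one-row data.frame of all statistics).
#' @export
quant_analysis <- function(cohort, phenotype_id, group_by, weights = NULL,
                           boxcox = FALSE, bootstrap = FALSE, B = 10000,
                           seed = NULL, alpha = 0.05) {
  ph <- cohort$phenotypes[cohort$phenotypes$phenotype_id == phenotype_id, ,
                          drop = FALSE]
  if (!nrow(ph)) stop("no values for phenotype ", phenotype_id)
  if (group_by == "stage") {
    sam <- cohort$samples[!is.na(cohort$samples$stage), ,
                          drop = FALSE]
    m <- merge(ph, sam[, c("sample_id", "stage")], by = "sample_id")
    grp <- factor(m$stage, levels = sort(unique(sam$stage)))
  } else {
    snp <- cohort$snp_defs[[group_by]]
    if (is.null(snp)) stop("unknown grouping: ", group_by)
    gt <- cohort$genotypes[cohort$genotypes$snp_id == group_by, ,
                           drop = FALSE]
    gt <- gt[!is.na(gt$a1), , drop = FALSE]
    m <- merge(ph, gt, by = "sample_id")
    dose <- (m$a1 == snp$minor_allele) + (m$a2 == snp$minor_allele)
    labs <- genotype_label(m$a1, m$a2)
    order_labs <- unique(labs[order(dose)])
    grp <- factor(labs, levels = order_labs)
  }
  groups <- quant_groups(m$value, grp, units = ph$units[1L])
  an <- anova_oneway(groups, transform = if (boxcox) "boxcox" else "none",
                     bootstrap = bootstrap, B = B, seed = seed)
  if (is.null(weights)) {
    k <- length(groups$labels)
    weights <- (seq_len(k) - 1) - mean(seq_len(k) - 1)
  }
  ct <- linear_contrast(groups, weights, bootstrap = bootstrap, B = B,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  lsd <- fisher_lsd(groups, alpha = alpha)
  summ <- group_summary(groups)
  summ <- cbind(phenotype = phenotype_id, group_by = group_by, summ,
                stringsAsFactors = FALSE)
  tests <- data.frame(phenotype = phenotype_id, group_by = group_by,
                      F = an$F, df_between = an$df_between,
                      df_within = an$df_within,
                      p_param = an$p_parametric, p_boot = an$p_bootstrap,
                      fligner_p = an$variance_homogeneity_p,
                      lambda = an$boxcox_lambda,
                      lsd_notation = lsd$notation,
                      contrast_estimate = ct$estimate,
                      F_contrast = ct$F_contrast,
                      p_contrast = ct$p_parametric,
                      p_contrast_boot = ct$p_bootstrap,
                      r_alerting = ct$r_alerting,
                      r_effect_size = ct$r_effect_size,
                      stringsAsFactors = FALSE)
  list(groups = groups, anova = an, contrast = ct, lsd = lsd,
       summary = summ, tests = tests)
}
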