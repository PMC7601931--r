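#' Pair case and control genotype tallies for one SNP
#'
#' @param case_counts,control_counts [genotype_counts()] for the two study
#'   arms, in the same allele orientation.
#' @param snp_id rsID label; defaults to the label carried by the counts.
#' @return Object of class `case_control_table`.
#' @examples
#' case_control_table(genotype_counts(261, 142, 36),
#'                    genotype_counts(279, 179, 19), "rs3803800")
#' @export
case_control_table <- function(case_counts, control_counts,
                               snp_id = case_counts$snp_id) {
  stopifnot(inherits(case_counts, "genotype_counts"),
            inherits(control_counts, "genotype_counts"))
  structure(list(case = case_counts, control = control_counts,
                 snp_id = snp_id),
            class = "case_control_table")
}

#' @export
print.case_control_table <- function(x, ...) {
  cat(sprintf("<case_control_table> %s\n  cases:    %d / %d / %d\n  controls: %d / %d / %d\n",
              ifelse(is.na(x$snp_id), "?", x$snp_id),
              x$case$n_ref_hom, x$case$n_het, x$case$n_alt_hom,
              x$control$n_ref_hom, x$control$n_het, x$control$n_alt_hom))
  invisible(x)
}

#' Chi-squared test of genotype distribution between arms
#'
#' Pearson chi-squared on the 3-by-2 genotype-by-status table, no
#' continuity correction, df = 2. A genotype class empty in both arms is
#' dropped (with a warning) and the degrees of freedom reduced.
#'
#' @param table a [case_control_table()].
#' @return Object of class `chisq_result`: `statistic`, `df`, `p`.
#' @examples
#' tab <- case_control_table(genotype_counts(261, 142, 36),
#'                           genotype_counts(279, 179, 19))
#' genotype_chisq(tab)   # 8.56, df 2
#' @export
genotype_chisq <- function(table) {
  stopifnot(inherits(table, "case_control_table"))
  m <- cbind(case = c(table$case$n_ref_hom, table$case$n_het,
                      table$case$n_alt_hom),
             control = c(table$control$n_ref_hom, table$control$n_het,
                         table$control$n_alt_hom))
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning(sum(empty), " genotype class(es) empty in both arms dropped",
            call. = FALSE)
    m <- m[!empty, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("fewer than two genotype classes with data")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> X2(df = %d) = %.4g, p = %.4g\n",
              x$df, x$statistic, x$p))
  invisible(x)
}

#' Odds ratio for a 2-by-2 exposure-by-status table
#'
#' Computes the cross-product odds ratio with a Woolf (log-scale Wald)
#' confidence interval. With `correction = "haldane_anscombe"` (the
#' default used throughout the association report) 0.5 is added to all
#' four cells unconditionally before both the point estimate and the
#' interval, which keeps every reported OR finite even with zero cells
#' and stabilises the log-variance.
#'
#' @param n_exposed_case,n_ref_case counts in the case arm.
#' @param n_exposed_ctrl,n_ref_ctrl counts in the control arm.
#' @param correction `"haldane_anscombe"` (default) or `"none"`.
#' @param z normal quantile for the interval (default 1.959964, i.e. 95%).
#' @param comparison free-text description of the exposed vs reference
#'   genotype sets, carried into reports.
#' @return Object of class `or_result`: `or_point`, `ci_low`, `ci_high`,
#'   `log_or`, `se_log_or`, `correction`, `comparison`.
#' @examples
#' odds_ratio_2x2(36, 261, 19, 279)   # OR 2.00, CI (1.13, 3.56)
#' @export
odds_ratio_2x2 <- function(n_exposed_case, n_ref_case,
                           n_exposed_ctrl, n_ref_ctrl,
                           correction = c("haldane_anscombe", "none"),
                           z = 1.959964, comparison = "") {
  correction <- match.arg(correction)
  cells <- c(a = unname(n_exposed_case), b = unname(n_exposed_ctrl),
             c = unname(n_ref_case), d = unname(n_ref_ctrl))
  stopifnot(all(cells >= 0))
  if (n_exposed_case + n_ref_case == 0 || n_exposed_ctrl + n_ref_ctrl == 0)
    stop("an arm has no observations")
  if (correction == "haldane_anscombe") cells <- cells + 0.5
  if (any(cells == 0))
    stop("zero cell without continuity correction; OR not estimable")
  log_or <- log(cells["a"]) + log(cells["d"]) -
    log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  structure(list(or_point = unname(exp(log_or)),
                 ci_low = unname(exp(log_or - z * se)),
                 ci_high = unname(exp(log_or + z * se)),
                 log_or = unname(log_or), se_log_or = unname(se),
                 correction = correction, comparison = comparison),
            class = "or_result")
}

#' @export
print.or_result <- function(x, digits = 2, ...) {
  cat(sprintf("<or_result> %sOR = %.*f, CI95%% = (%.*f, %.*f) [%s]\n",
              if (nzchar(x$comparison)) paste0(x$comparison, ": ") else "",
              digits, x$or_point, digits, x$ci_low, digits, x$ci_high,
              x$correction))
  invisible(x)
}

# Collapse a case_control_table to a 2x2 (exposed, reference) per arm for a
# genetic model of the given effect allele. Counts are minor-allele
# oriented: alt-hom = minor homozygote.
collapse_counts <- function(counts, model, effect_is_minor) {
  rr <- counts$n_ref_hom; het <- counts$n_het; aa <- counts$n_alt_hom
  if (!effect_is_minor) { tmp <- rr; rr <- aa; aa <- tmp }
  switch(model,
         dominant  = c(exposed = het + aa, reference = rr),
         recessive = c(exposed = aa, reference = rr + het),
         allelic   = c(exposed = 2L * aa + het, reference = 2L * rr + het))
}

#' Collapsed-model odds ratio
#'
#' Collapses the 3-by-2 genotype table under a genetic model for the
#' chosen effect allele, then computes the corrected odds ratio:
#' * `dominant`: carriers (het + effect-allele homozygote) vs the other
#'   homozygote;
#' * `recessive`: effect-allele homozygote vs the rest;
#' * `allelic`: allele counts (each sample contributes two alleles).
#'
#' A 1-df Pearson chi-squared p (no continuity correction) and a Fisher
#' exact p on the collapsed table are attached; both conventions are in
#' use for collapsed tables, so both are reported.
#'
#' @param table a [case_control_table()] (minor-allele oriented counts).
#' @param model `"recessive"`, `"dominant"` or `"allelic"`.
#' @param effect_allele `"minor"` (default) or `"major"`: which allele is
#'   collapsed over.
#' @param correction,z passed to [odds_ratio_2x2()].
#' @return An `or_result` with extra fields `model`, `p_chisq`,
#'   `p_fisher` and `collapsed` (the 2-by-2 cells).
#' @examples
#' tab <- case_control_table(genotype_counts(261, 142, 36),
#'                           genotype_counts(279, 179, 19))
#' model_odds_ratio(tab, "recessive")   # OR 2.13, CI (1.21, 3.75)
#' @export
model_odds_ratio <- function(table, model = c("recessive", "dominant",
                                              "allelic"),
                             effect_allele = c("minor", "major"),
                             correction = c("haldane_anscombe", "none"),
                             z = 1.959964) {
  stopifnot(inherits(table, "case_control_table"))
  model <- match.arg(model)
  effect_allele <- match.arg(effect_allele)
  correction <- match.arg(correction)
  ca <- collapse_counts(table$case, model, effect_allele == "minor")
  co <- collapse_counts(table$control, model, effect_allele == "minor")
  res <- odds_ratio_2x2(ca["exposed"], ca["reference"],
                        co["exposed"], co["reference"],
                        correction = correction, z = z,
                        comparison = paste0(model, " (", effect_allele,
                                            " allele)"))
  m <- rbind(case = ca, control = co)
  res$model <- model
  res$p_chisq <- suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$p.value)
  res$p_fisher <- stats::fisher.test(m)$p.value
  res$collapsed <- m
  res
}

#' Per-SNP association report
#'
#' For every declared SNP, tallies both arms, tests the genotype
#' distribution (2-df chi-squared), reports per-genotype odds ratios
#' against the most frequent homozygote (the reference group, whose OR is
#' 1 by construction and therefore omitted), the dominant and recessive
#' collapsed-model odds ratios for the minor allele, and the
#' Hardy-Weinberg departure per arm (f, CI, exact-test p). One row per
#' genotype plus one row per collapsed model; SNP-level statistics are
#' repeated on each row of their SNP so the table is flat CSV.
#'
#' @param cohort a [cohort()] with QC already applied.
#' @param correction,z passed to the odds-ratio machinery.
#' @param bh if `TRUE`, append Benjamini-Hochberg-adjusted chi-squared
#'   p-values across SNPs (exploratory use; hypotheses here are planned,
#'   so the default is off).
#' @return data.frame with columns `snp`, `genotype`, `n_case`,
#'   `pct_case`, `n_ctrl`, `pct_ctrl`, `or`, `ci_low`, `ci_high`,
#'   `chisq`, `df`, `p`, `f_case`, `f_case_lo`, `f_case_hi`,
#'   `p_hwe_case`, `f_ctrl`, `f_ctrl_lo`, `f_ctrl_hi`, `p_hwe_ctrl`
#'   (full precision; round at display).
#' @export
association_report <- function(cohort, correction = "haldane_anscombe",
                               z = 1.959964, bh = FALSE) {
  rows <- list()
  chisq_ps <- c()
  for (snp in cohort$snp_defs) {
    ca <- tally_genotypes(cohort, snp$snp_id, "case")
    co <- tally_genotypes(cohort, snp$snp_id, "control")
    tab <- case_control_table(ca, co, snp$snp_id)
    chi <- genotype_chisq(tab)
    chisq_ps[snp$snp_id] <- chi$p
    hw_ca <- hwe_f(ca)
    hw_co <- hwe_f(co)
    major <- if (snp$minor_allele == snp$alt_allele) snp$ref_allele else
      snp$alt_allele
    labels <- c(paste0(major, major),
                paste0(major, snp$minor_allele),
                paste0(snp$minor_allele, snp$minor_allele))
    n_ca <- c(ca$n_ref_hom, ca$n_het, ca$n_alt_hom)
    n_co <- c(co$n_ref_hom, co$n_het, co$n_alt_hom)
    ors <- list(NULL,
                odds_ratio_2x2(n_ca[2], n_ca[1], n_co[2], n_co[1],
                               correction = correction, z = z),
                odds_ratio_2x2(n_ca[3], n_ca[1], n_co[3], n_co[1],
                               correction = correction, z = z))
    geno_rows <- lapply(1:3, function(i) {
      data.frame(snp = snp$snp_id, genotype = labels[i],
                 n_case = n_ca[i], pct_case = 100 * n_ca[i] / ca$n,
                 n_ctrl = n_co[i], pct_ctrl = 100 * n_co[i] / co$n,
                 or = if (i == 1) NA_real_ else ors[[i]]$or_point,
                 ci_low = if (i == 1) NA_real_ else ors[[i]]$ci_low,
                 ci_high = if (i == 1) NA_real_ else ors[[i]]$ci_high,
                 stringsAsFactors = FALSE)
    })
    model_rows <- lapply(c("dominant", "recessive"), function(mod) {
      mo <- model_odds_ratio(tab, mod, "minor", correction = correction,
                             z = z)
      data.frame(snp = snp$snp_id,
                 genotype = paste0(mod, "_", snp$minor_allele),
                 n_case = mo$collapsed["case", "exposed"],
                 pct_case = 100 * mo$collapsed["case", "exposed"] / ca$n,
                 n_ctrl = mo$collapsed["control", "exposed"],
                 pct_ctrl = 100 * mo$collapsed["control", "exposed"] / co$n,
                 or = mo$or_point, ci_low = mo$ci_low, ci_high = mo$ci_high,
                 stringsAsFactors = FALSE)
    })
    snp_rows <- do.call(rbind, c(geno_rows, model_rows))
    snp_rows$chisq <- chi$statistic
    snp_rows$df <- chi$df
    snp_rows$p <- chi$p
    snp_rows$f_case <- hw_ca$f
    snp_rows$f_case_lo <- hw_ca$ci_low
    snp_rows$f_case_hi <- hw_ca$ci_high
    snp_rows$p_hwe_case <- hw_ca$p_hwe
    snp_rows$f_ctrl <- hw_co$f
    snp_rows$f_ctrl_lo <- hw_co$ci_low
    snp_rows$f_ctrl_hi <- hw_co$ci_high
    snp_rows$p_hwe_ctrl <- hw_co$p_hwe
    rows[[snp$snp_id]] <- snp_rows
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh) {
    adj <- stats::p.adjust(chisq_ps, method = "BH")
    out$p_bh <- adj[out$snp]
  }
  out
}
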