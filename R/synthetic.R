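# Derived substream seeds: one PRNG stream per cohort, fixed offsets per
# component, so adding a phenotype never perturbs the genotype draws.
substream_seed <- function(seed, kind, index) {
  base <- switch(kind, snp = 7919L, cnv = 104729L, stage = 31337L,
                 phenotype = 424243L, missing = 611953L,
                 stop("unknown substream kind"))
  (as.integer(seed) + base + 97L * as.integer(index)) %% 2147483629L
}

#' Specify a synthetic cohort
#'
#' Full parameterisation of the generator: arm sizes, per-SNP genotype
#' model (control minor-allele frequency `q`, Hardy-Weinberg departure
#' `f_ctrl`/`f_case`, per-genotype odds ratios with the major homozygote
#' as reference, missing rate), genotype-conditional phenotype models
#' (normal or lognormal), an ordinal stage model with a linear mean shift
#' for flagged phenotypes, and per-gene single-copy fractions.
#'
#' Case genotype probabilities are the (q, f_case) probabilities
#' reweighted multiplicatively by the per-genotype odds ratios and
#' renormalised — the exact genotype-level logistic-model correspondence,
#' so the case-control genotype odds ratio of genotype j versus the
#' reference homozygote equals `or_j` analytically.
#'
#' @param n_case,n_ctrl arm sizes.
#' @param snps list of per-SNP specs; each a list with `def` (a
#'   [snp_def()]), `q`, `f_ctrl` (default 0), `f_case` (default
#'   `f_ctrl`), `or_het` (default 1), `or_hom` (default 1),
#'   `missing_rate` (default 0).
#' @param phenotypes list of phenotype specs; each a list with
#'   `phenotype_id`, `units`, `by_snp` (rsID driving the genotype effect),
#'   `family` (`"normal"` or `"lognormal"`), `location` (length 3, per
#'   genotype: ref-hom, het, alt-hom; log-scale for lognormal), `scale`
#'   (length 1 or 3, positive), `stage_slope` (default 0: additive mean
#'   shift per stage unit, cases only), `arm` (default `"case"`: which
#'   samples get values; `"both"` for all).
#' @param stage_probs probabilities of Rai stages 0-4 for cases (length
#'   5, summing to 1); `NULL` leaves stage unassigned.
#' @param single_copy_fraction named numeric vector, per-gene fraction of
#'   samples carrying a single copy (in \[0, 1)).
#' @param seed integer master seed; all substreams derive from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case, n_ctrl, snps, phenotypes = list(),
                        stage_probs = NULL,
                        single_copy_fraction = numeric(), seed = 1L) {
  stopifnot(n_case >= 1, n_ctrl >= 1, length(snps) >= 1)
  snps <- lapply(snps, function(s) {
    stopifnot(inherits(s$def, "snp_def"), s$q >= 0, s$q <= 1)
    s$f_ctrl <- if (is.null(s$f_ctrl)) 0 else s$f_ctrl
    s$f_case <- if (is.null(s$f_case)) s$f_ctrl else s$f_case
    s$or_het <- if (is.null(s$or_het)) 1 else s$or_het
    s$or_hom <- if (is.null(s$or_hom)) 1 else s$or_hom
    s$missing_rate <- if (is.null(s$missing_rate)) 0 else s$missing_rate
    stopifnot(s$or_het > 0, s$or_hom > 0,
              s$missing_rate >= 0, s$missing_rate < 1)
    genotype_probs(s$q, s$f_ctrl)   # validate both parameterisations
    genotype_probs(s$q, s$f_case)
    s
  })
  names(snps) <- vapply(snps, function(s) s$def$snp_id, character(1))
  phenotypes <- lapply(phenotypes, function(p) {
    stopifnot(!is.null(p$phenotype_id), !is.null(p$by_snp),
              p$by_snp %in% names(snps))
    p$units <- if (is.null(p$units)) "" else p$units
    p$family <- if (is.null(p$family)) "normal" else p$family
    stopifnot(p$family %in% c("normal", "lognormal"),
              length(p$location) == 3)
    if (length(p$scale) == 1) p$scale <- rep(p$scale, 3)
    stopifnot(length(p$scale) == 3)
    if (any(p$scale < 0)) stop("negative scale for ", p$phenotype_id)
    p$stage_slope <- if (is.null(p$stage_slope)) 0 else p$stage_slope
    p$arm <- if (is.null(p$arm)) "case" else p$arm
    stopifnot(p$arm %in% c("case", "both"))
    p
  })
  if (!is.null(stage_probs)) {
    stopifnot(length(stage_probs) == 5, all(stage_probs >= 0),
              abs(sum(stage_probs) - 1) < 1e-8)
  }
  if (length(single_copy_fraction)) {
    stopifnot(!is.null(names(single_copy_fraction)),
              all(single_copy_fraction >= 0), all(single_copy_fraction < 1))
  }
  structure(list(n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                 snps = snps, phenotypes = phenotypes,
                 stage_probs = stage_probs,
                 single_copy_fraction = single_copy_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw genotypes at a single locus
#'
#' I.i.d. draws from the three-genotype distribution implied by minor
#' allele frequency `q` and departure `f` (see [genotype_probs()]).
#'
#' @param n number of samples.
#' @param q minor-allele frequency.
#' @param f Hardy-Weinberg departure coefficient.
#' @param seed optional integer seed.
#' @return Integer vector of minor-allele doses (0, 1, 2).
#' @export
simulate_genotypes <- function(n, q, f, seed = NULL) {
  probs <- genotype_probs(q, f)
  if (!is.null(seed)) set.seed(seed)
  sample.int(3L, n, replace = TRUE, prob = probs) - 1L
}

# Dose vector (0/1/2 of the minor allele) -> canonical allele columns.
dose_to_alleles <- function(dose, snp) {
  major <- if (snp$minor_allele == snp$alt_allele) snp$ref_allele else
    snp$alt_allele
  a1 <- ifelse(is.na(dose), NA_character_,
               ifelse(dose == 2L, snp$minor_allele, major))
  a2 <- ifelse(is.na(dose), NA_character_,
               ifelse(dose >= 1L, snp$minor_allele, major))
  # canonical display order: ref allele first
  flip <- !is.na(dose) & a1 != a2 & a1 != snp$ref_allele
  tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
  list(a1 = a1, a2 = a2)
}

#' Simulate a case-control cohort
#'
#' Controls are drawn at `(q, f_ctrl)` per SNP; cases at the
#' odds-ratio-reweighted `(q, f_case)` probabilities (see
#' [cohort_spec()]). Single-copy CNV flags are assigned independently at
#' the specified per-gene fractions, genotype calls are masked at the
#' per-SNP missing rate, and cases receive Rai stages from the stage
#' model. Fully deterministic given the spec (which includes the seed).
#'
#' @param spec a [cohort_spec()].
#' @return A [cohort()] (QC not yet applied).
#' @export
simulate_case_control <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("CASE%05d", seq_len(spec$n_case)),
           sprintf("CTRL%05d", seq_len(spec$n_ctrl)))
  status <- rep(c("case", "control"), c(spec$n_case, spec$n_ctrl))
  stage <- rep(NA_integer_, length(ids))
  if (!is.null(spec$stage_probs)) {
    set.seed(substream_seed(spec$seed, "stage", 0L))
    stage[status == "case"] <- sample(0:4, spec$n_case, replace = TRUE,
                                      prob = spec$stage_probs)
  }
  samples <- data.frame(sample_id = ids, status = status, stage = stage,
                        stringsAsFactors = FALSE)

  gt_rows <- vector("list", length(spec$snps))
  for (k in seq_along(spec$snps)) {
    s <- spec$snps[[k]]
    p_ctrl <- genotype_probs(s$q, s$f_ctrl)
    p_case <- genotype_probs(s$q, s$f_case) * c(1, s$or_het, s$or_hom)
    p_case <- p_case / sum(p_case)
    set.seed(substream_seed(spec$seed, "snp", k))
    dose <- integer(length(ids))
    dose[status == "case"] <- sample.int(3L, spec$n_case, replace = TRUE,
                                         prob = p_case) - 1L
    dose[status == "control"] <- sample.int(3L, spec$n_ctrl, replace = TRUE,
                                            prob = p_ctrl) - 1L
    if (s$missing_rate > 0) {
      set.seed(substream_seed(spec$seed, "missing", k))
      dose[stats::runif(length(ids)) < s$missing_rate] <- NA_integer_
    }
    al <- dose_to_alleles(dose, s$def)
    gt_rows[[k]] <- data.frame(sample_id = ids, snp_id = s$def$snp_id,
                               a1 = al$a1, a2 = al$a2,
                               stringsAsFactors = FALSE)
  }

  cn_rows <- list()
  genes <- names(spec$single_copy_fraction)
  for (j in seq_along(genes)) {
    set.seed(substream_seed(spec$seed, "cnv", j))
    single <- stats::runif(length(ids)) < spec$single_copy_fraction[j]
    cn_rows[[j]] <- data.frame(sample_id = ids, gene_id = genes[j],
                               copy_number = ifelse(single, 1L, 2L),
                               stringsAsFactors = FALSE)
  }

  co <- cohort(samples,
               lapply(spec$snps, `[[`, "def"),
               genotypes = do.call(rbind, gt_rows),
               copy_numbers = if (length(cn_rows)) do.call(rbind, cn_rows)
                              else NULL)
  if (length(spec$phenotypes)) co <- simulate_phenotypes(co, spec)
  co
}

#' Attach genotype-conditional phenotypes to a cohort
#'
#' Each phenotype is drawn per sample from its genotype-conditional
#' family — normal(location, scale) or lognormal(meanlog = location,
#' sdlog = scale) — with the stage-linear mean shift added on the
#' observation scale for samples with a stage. Samples missing the
#' driving genotype get no value. Percent-scale phenotypes are clamped to
#' \[0, 100\].
#'
#' @param cohort a [cohort()] with genotypes present.
#' @param spec the [cohort_spec()] carrying the phenotype models and
#'   master seed.
#' @return The cohort with phenotype rows appended.
#' @export
simulate_phenotypes <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "cohort_spec"))
  ph_rows <- list()
  for (m in seq_along(spec$phenotypes)) {
    p <- spec$phenotypes[[m]]
    snp <- cohort$snp_defs[[p$by_snp]]
    if (is.null(snp)) stop("phenotype ", p$phenotype_id,
                           " references unknown SNP ", p$by_snp)
    gt <- cohort$genotypes[cohort$genotypes$snp_id == p$by_snp, ,
                           drop = FALSE]
    sam <- merge(cohort$samples, gt, by = "sample_id", sort = TRUE)
    if (p$arm == "case") sam <- sam[sam$status == "case", , drop = FALSE]
    sam <- sam[!is.na(sam$a1), , drop = FALSE]
    sam <- sam[order(sam$sample_id), , drop = FALSE]
    dose <- (sam$a1 == snp$minor_allele) + (sam$a2 == snp$minor_allele)
    set.seed(substream_seed(spec$seed, "phenotype", m))
    value <- if (p$family == "normal") {
      stats::rnorm(nrow(sam), p$location[dose + 1L], p$scale[dose + 1L])
    } else {
      stats::rlnorm(nrow(sam), p$location[dose + 1L], p$scale[dose + 1L])
    }
    if (p$stage_slope != 0) {
      shift <- ifelse(is.na(sam$stage), 0, sam$stage * p$stage_slope)
      value <- value + shift
    }
    if (p$units == "%") value <- pmin(pmax(value, 0), 100)
    ph_rows[[m]] <- data.frame(sample_id = sam$sample_id,
                               phenotype_id = p$phenotype_id,
                               value = value, units = p$units,
                               stringsAsFactors = FALSE)
  }
  out <- cohort
  out$phenotypes <- rbind(cohort$phenotypes, do.call(rbind, ph_rows))
  out
}

#' Expand printed genotype counts into an explicit cohort
#'
#' Published genotype tables report only the three-cell tallies per arm.
#' This expander materialises them as per-sample rows (deterministically:
#' the first `n_ref_hom` samples are reference homozygotes, and so on) so
#' a printed table can be fed through the full pipeline without
#' special-casing. With several SNPs, genotypes are assigned
#' independently per SNP — marginal tallies are exact, joint structure is
#' arbitrary, which is all a per-SNP analysis consumes.
#'
#' @param tables named list (by rsID) of [case_control_table()]s; all
#'   must agree on arm sizes.
#' @param snp_defs list of [snp_def()]s covering every table.
#' @return A [cohort()] whose [tally_genotypes()] reproduce the input
#'   counts exactly.
#' @examples
#' tab <- case_control_table(genotype_counts(261, 142, 36),
#'                           genotype_counts(279, 179, 19), "rs3803800")
#' co <- counts_to_cohort(list(rs3803800 = tab),
#'                        list(snp_def("rs3803800", "TNFSF13", "G", "A")))
#' @export
counts_to_cohort <- function(tables, snp_defs) {
  stopifnot(length(tables) >= 1)
  if (is.list(snp_defs) && inherits(snp_defs, "snp_def"))
    snp_defs <- list(snp_defs)
  names(snp_defs) <- vapply(snp_defs, `[[`, character(1), "snp_id")
  n_case <- unique(vapply(tables, function(t) t$case$n, integer(1)))
  n_ctrl <- unique(vapply(tables, function(t) t$control$n, integer(1)))
  if (length(n_case) != 1 || length(n_ctrl) != 1)
    stop("all tables must have the same per-arm totals")
  ids <- c(sprintf("CASE%05d", seq_len(n_case)),
           sprintf("CTRL%05d", seq_len(n_ctrl)))
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  samples <- data.frame(sample_id = ids, status = status,
                        stringsAsFactors = FALSE)
  gt_rows <- lapply(names(tables), function(id) {
    tab <- tables[[id]]
    snp <- snp_defs[[id]]
    if (is.null(snp)) stop("no snp_def for ", id)
    dose <- c(rep(0:2, c(tab$case$n_ref_hom, tab$case$n_het,
                         tab$case$n_alt_hom)),
              rep(0:2, c(tab$control$n_ref_hom, tab$control$n_het,
                         tab$control$n_alt_hom)))
    al <- dose_to_alleles(dose, snp)
    data.frame(sample_id = ids, snp_id = id, a1 = al$a1, a2 = al$a2,
               stringsAsFactors = FALSE)
  })
  cohort(samples, snp_defs[names(tables)],
         genotypes = do.call(rbind, gt_rows))
}
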