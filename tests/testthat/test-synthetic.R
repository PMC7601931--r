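test_that("generated cohorts are fully deterministic and round-trip losslessly", {
  spec <- cohort_spec(80, 90,
                      snps = list(list(def = snp_rs3803800(), q = 0.25,
                                       f_ctrl = 0.05, or_hom = 1.5,
                                       missing_rate = 0.05)),
                      phenotypes = list(list(phenotype_id = "IgA",
                                             units = "g/L",
                                             by_snp = "rs3803800",
                                             family = "lognormal",
                                             location = log(c(1.14, 1.36, 1.89)),
                                             scale = 0.4)),
                      stage_probs = c(0.3, 0.3, 0.2, 0.1, 0.1),
                      single_copy_fraction = c(TNFSF13 = 0.047),
                      seed = 123)
  co1 <- simulate_case_control(spec)
  co2 <- simulate_case_control(spec)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in c("samples.tsv", "genotypes.tsv", "cnv.tsv", "phenotypes.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)

  back <- read_cohort(d1, list(snp_rs3803800()))
  expect_equal(back$samples, co1$samples, ignore_attr = "row.names")
  ord <- function(g) {
    g <- g[order(g$sample_id, g$snp_id), ]
    rownames(g) <- NULL
    g
  }
  expect_equal(ord(back$genotypes), ord(co1$genotypes))
  expect_equal(back$phenotypes$value, co1$phenotypes$value)
  expect_equal(back$copy_numbers$copy_number, co1$copy_numbers$copy_number)
})

test_that("adding a phenotype never perturbs the genotype draws", {
  base <- tiny_spec(seed = 9)
  with_ph <- cohort_spec(150, 200,
                         snps = list(list(def = snp_rs3803800(), q = 0.25)),
                         phenotypes = list(list(phenotype_id = "MFI",
                                                units = "MFI",
                                                by_snp = "rs3803800",
                                                family = "normal",
                                                location = c(35, 43, 42),
                                                scale = 6)),
                         seed = 9)
  co_a <- simulate_case_control(base)
  co_b <- simulate_case_control(with_ph)
  expect_identical(co_a$genotypes, co_b$genotypes)
  expect_gt(nrow(co_b$phenotypes), 0)
})

test_that("degenerate and null settings behave as specified", {
  # q = 0: every sample is a reference homozygote
  g <- simulate_genotypes(200, q = 0, f = 0, seed = 4)
  expect_true(all(g == 0L))

  # all ORs 1 and f_case = f_ctrl: arms share the genotype distribution
  spec <- cohort_spec(15000, 15000,
                      snps = list(list(def = snp_rs3803800(), q = 0.3,
                                       f_ctrl = 0.05)),
                      seed = 31)
  co <- simulate_case_control(spec)
  chi <- genotype_chisq(case_control_table(
    tally_genotypes(co, "rs3803800", "case"),
    tally_genotypes(co, "rs3803800", "control")))
  expect_gt(chi$p, 1e-3)

  # invalid (q, f) rejected by the spec constructor
  expect_error(tiny_spec(f_ctrl = -0.9), "alt_hom")
  expect_error(tiny_spec(or_hom = -2), "or_hom")
})

test_that("single-copy fractions propagate to the CNV filter", {
  spec <- cohort_spec(4000, 4000,
                      snps = list(list(def = snp_rs3803800(), q = 0.25)),
                      single_copy_fraction = c(TNFSF13 = 0.047,
                                               TNFRSF13B = 0.0297),
                      seed = 12)
  co <- simulate_case_control(spec)
  out <- apply_cnv_exclusion(co, c("TNFSF13", "TNFRSF13B"))
  rep_ <- attr(out, "exclusion_report")
  expect_equal(unname(rep_$single_copy_fraction["TNFSF13"]), 0.047,
               tolerance = 0.25)
  expect_equal(nrow(out$samples) + length(rep_$removed), 8000)
  # removed fraction ~ 1 - (1-p1)(1-p2)
  expect_equal(length(rep_$removed) / 8000, 1 - (1 - 0.047) * (1 - 0.0297),
               tolerance = 0.2)
})

test_that("genotype and departure parameters are recovered at large n", {
  g <- simulate_genotypes(50000, q = 0.25, f = 0.12, seed = 77)
  counts <- genotype_counts(sum(g == 0), sum(g == 1), sum(g == 2))
  h <- hwe_f(counts)
  expect_gt(h$f, 0.10); expect_lt(h$f, 0.14)
  expect_equal(h$allele_freq, 0.25, tolerance = 0.02)
})

test_that("recessive OR confidence intervals cover the generating value across seeds", {
  # study-scale arms (439/477) with a genotype relative risk of 2.1
  or_true <- 2.1
  hits <- 0L
  for (s in 1:100) {
    spec <- cohort_spec(439, 477,
                        snps = list(list(def = snp_rs3803800(), q = 0.2275,
                                         or_hom = or_true)),
                        seed = 8000 + s)
    co <- simulate_case_control(spec)
    tab <- case_control_table(tally_genotypes(co, "rs3803800", "case"),
                              tally_genotypes(co, "rs3803800", "control"))
    mo <- model_odds_ratio(tab, "recessive")
    hits <- hits + (mo$ci_low <= or_true && or_true <= mo$ci_high)
  }
  expect_gte(hits, 93)
})

test_that("stage trend and genotype effects propagate into the phenotypes", {
  spec <- cohort_spec(600, 50,
                      snps = list(list(def = snp_rs4985726(), q = 0.4)),
                      phenotypes = list(list(phenotype_id = "TACIpct",
                                             units = "%",
                                             by_snp = "rs4985726",
                                             family = "normal",
                                             location = c(10, 10, 10),
                                             scale = 1,
                                             stage_slope = 2)),
                      stage_probs = rep(0.2, 5),
                      seed = 19)
  co <- simulate_case_control(spec)
  ph <- co$phenotypes
  m <- merge(ph, co$samples, by = "sample_id")
  m <- m[!is.na(m$stage), ]
  g <- quant_groups(m$value, factor(m$stage, levels = 0:4), units = "%")
  tr <- trend_by_ordinal(g)
  expect_gt(tr$r_alerting, 0.95)
  expect_lt(tr$p_parametric, 1e-6)

  # negative scale rejected
  expect_error(cohort_spec(10, 10,
                           snps = list(list(def = snp_rs4985726(), q = 0.4)),
                           phenotypes = list(list(phenotype_id = "x",
                                                  by_snp = "rs4985726",
                                                  location = c(1, 2, 3),
                                                  scale = -1)),
                           seed = 1),
               "negative scale")
})

test_that("expanding printed counts reproduces the tallies exactly", {
  co <- published_cohort()
  for (nm in c("rs3803800", "rs4985726")) {
    ca <- tally_genotypes(co, nm, "case")
    ct <- tally_genotypes(co, nm, "control")
    ref <- if (nm == "rs3803800") list(c(261L, 142L, 36L), c(279L, 179L, 19L))
           else list(c(353L, 78L, 8L), c(353L, 117L, 7L))
    expect_equal(c(ca$n_ref_hom, ca$n_het, ca$n_alt_hom), ref[[1]])
    expect_equal(c(ct$n_ref_hom, ct$n_het, ct$n_alt_hom), ref[[2]])
  }
  expect_error(counts_to_cohort(list(rs3803800 = table_rs3803800(),
                                     rs4985726 = case_control_table(
                                       genotype_counts(1, 1, 1),
                                       genotype_counts(2, 2, 2))),
                                list(snp_rs3803800(), snp_rs4985726())),
               "same per-arm totals")
})
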