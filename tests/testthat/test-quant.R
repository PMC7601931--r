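test_that("Sn double-median matches its worked examples and brute force", {
  expect_equal(sn_scale(rep(3.2, 9))$sn, 0)          # constant vector
  expect_equal(sn_scale(c(1, 2, 3))$sn, 1)
  expect_equal(sn_scale(c(0, 0, 10))$sn, 0)          # outer median of 0,0,10
  set.seed(101)
  for (i in 1:60) {
    x <- stats::rnorm(sample(1:50, 1), sd = sample(c(0.1, 1, 50), 1))
    expect_equal(sn_scale(x, "eq2_literal")$sn, sn_bruteforce(x, "eq2_literal"))
    expect_equal(sn_scale(x, "rousseeuw_croux")$sn,
                 sn_bruteforce(x, "rousseeuw_croux"))
  }
})

test_that("Sn is scale-equivariant and zero iff pairwise differences vanish", {
  set.seed(7)
  x <- stats::rcauchy(31)
  for (cc in c(-3, 0.25, 10))
    expect_equal(sn_scale(cc * x)$sn, abs(cc) * sn_scale(x)$sn)
  expect_error(sn_scale(numeric(0)), "empty")
  # more than half the points identical forces Sn to 0
  expect_equal(sn_scale(c(rep(5, 6), 1, 2, 3, 4))$sn, 0)
})

test_that("one-way ANOVA handles identity, transforms and degeneracies", {
  g <- groups_with_means(c(10, 10, 10), sds = 2, ns = c(12, 15, 9))
  an <- anova_oneway(g)
  expect_equal(an$F, 0)
  expect_equal(an$p_parametric, 1)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 33)
  expect_true(an$variance_homogeneity_p > 0 &&
                an$variance_homogeneity_p <= 1)

  # zero spread everywhere: F undefined
  flat <- quant_groups(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5))
  expect_error(anova_oneway(flat), "F undefined")

  # Box-Cox on data with non-positive values instructs a shift
  neg <- quant_groups(c(-1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_error(anova_oneway(neg, transform = "boxcox"), "shift")
})

test_that("Box-Cox recovers the log transform for lognormal groups", {
  set.seed(21)
  vals <- c(stats::rlnorm(500, 1.0, 0.6), stats::rlnorm(500, 1.4, 0.6),
            stats::rlnorm(500, 1.8, 0.6))
  g <- quant_groups(vals, rep(c("a", "b", "c"), each = 500))
  an <- anova_oneway(g, transform = "boxcox")
  expect_lt(abs(an$boxcox_lambda), 0.2)
})

test_that("Box-Cox at lambda = 1 is affine: all statistics unchanged", {
  set.seed(31)
  g <- quant_groups(stats::rlnorm(60, 2, 0.5),
                    rep(c("a", "b", "c"), each = 20))
  raw <- anova_oneway(g)
  aff <- anova_oneway(g, transform = "boxcox", lambda = 1)
  expect_equal(aff$F, raw$F)
  expect_equal(aff$p_parametric, raw$p_parametric)
  w <- c(-1, 0, 1)
  g1 <- g
  g1$data <- lapply(g$data, function(x) x - 1)   # the lambda = 1 transform
  expect_equal(linear_contrast(g1, w)$F_contrast,
               linear_contrast(g, w)$F_contrast)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(99)
  n_rej <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    g <- quant_groups(stats::rnorm(60), rep(c("a", "b", "c"), each = 20))
    n_rej <- n_rej + (anova_oneway(g)$p_parametric < 0.05)
  }
  expect_lt(abs(n_rej / n_sim - 0.05), 0.03)
})

test_that("planned contrast reproduces the hand-computed example", {
  g <- quant_groups(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                    factor(rep(c("a", "b", "c"), each = 3),
                           levels = c("a", "b", "c")))
  ct <- linear_contrast(g, c(-1, 0, 1))
  expect_equal(ct$estimate, 2)
  expect_equal(ct$F_contrast, 6)
  expect_equal(ct$df_within, 6)
  expect_equal(ct$r_alerting, 1)
  expect_equal(ct$r_effect_size, sqrt(0.5), tolerance = 1e-12)

  # equal means: zero contrast, zero effect size
  g0 <- groups_with_means(c(5, 5, 5), sds = 1, ns = c(10, 10, 10))
  ct0 <- linear_contrast(g0, c(-1, 0, 1))
  expect_equal(ct0$F_contrast, 0, tolerance = 1e-12)
  expect_equal(ct0$r_effect_size, 0, tolerance = 1e-10)

  # weight validation
  expect_error(linear_contrast(g, c(1, 1, 1)), "sum to 0")
  expect_error(linear_contrast(g, c(0, 0, 0)), "all zero")
  expect_error(linear_contrast(g, c(-1, 1)), "one weight per group")
})

test_that("effect-size correlation satisfies its defining identity", {
  # the magnitude relation |r| = sqrt(F / (F + df)) holds exactly,
  # e.g. F = 4.2475 on 212 within df gives |r| = 0.140
  expect_equal(round(sqrt(4.2475 / (4.2475 + 212)), 3), 0.140)
  set.seed(55)
  for (i in 1:20) {
    g <- quant_groups(stats::rnorm(45, rep(c(0, 0.5, 1.5), each = 15)),
                      rep(c("a", "b", "c"), each = 15))
    ct <- linear_contrast(g, c(-1, 0, 1))
    expect_equal(abs(ct$r_effect_size),
                 sqrt(ct$F_contrast / (ct$F_contrast + ct$df_within)),
                 tolerance = 1e-12)
    expect_equal(sign(ct$r_effect_size), sign(ct$estimate))
  }
})

test_that("two-group contrast F equals the squared pooled t statistic", {
  set.seed(13)
  x <- stats::rnorm(14, 0); y <- stats::rnorm(11, 1)
  g <- quant_groups(c(x, y), rep(c("a", "b"), c(14, 11)))
  ct <- linear_contrast(g, c(-1, 1))
  tt <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(ct$F_contrast, unname(tt$statistic)^2)
  expect_equal(ct$p_parametric, tt$p.value)
})

test_that("orthogonal contrasts decompose the omnibus sum of squares on balanced designs", {
  set.seed(17)
  g <- quant_groups(stats::rnorm(36, rep(c(1, 3, 2), each = 12)),
                    rep(c("a", "b", "c"), each = 12))
  an <- anova_oneway(g)
  f1 <- linear_contrast(g, c(-1, 0, 1))$F_contrast
  f2 <- linear_contrast(g, c(1, -2, 1))$F_contrast
  expect_equal(f1 + f2, an$df_between * an$F, tolerance = 1e-10)
})

test_that("bootstrap F p-value is seeded, label-invariant and degenerate-safe", {
  set.seed(3)
  g <- quant_groups(stats::rnorm(45, rep(c(0, 0.4, 0.9), each = 15)),
                    rep(c("a", "b", "c"), each = 15))
  p1 <- bootstrap_f_pvalue(g, "omnibus_F", B = 500, seed = 77)
  p2 <- bootstrap_f_pvalue(g, "omnibus_F", B = 500, seed = 77)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)

  # relabeling groups (same order, new names) leaves the p unchanged
  g2 <- g; names(g2$data) <- g2$labels <- c("x", "y", "z")
  expect_identical(bootstrap_f_pvalue(g2, "omnibus_F", B = 500, seed = 77),
                   p1)

  # contrast variant is seeded too
  pc <- bootstrap_f_pvalue(g, "contrast_F", weights = c(-1, 0, 1),
                           B = 500, seed = 78)
  expect_identical(pc, bootstrap_f_pvalue(g, "contrast_F",
                                          weights = c(-1, 0, 1),
                                          B = 500, seed = 78))

  # all residuals zero: p = 1
  flat <- quant_groups(rep(c(4, 9), each = 6), rep(c("a", "b"), each = 6))
  expect_equal(bootstrap_f_pvalue(flat, "omnibus_F", B = 200, seed = 1), 1)
})

test_that("LSD notation marks homogeneous cliques like the published table", {
  # means and ns from the published MFI rows; SD chosen so that only the
  # first-group contrasts separate
  g <- groups_with_means(c(34.72, 43.40, 41.90), sds = 9,
                         ns = c(58, 65, 22), labels = c("AA", "AG", "GG"),
                         seed = 5)
  lsd <- fisher_lsd(g)
  expect_equal(lsd$notation, "AA (AG.GG)")
  expect_true(lsd$p_matrix["AA", "AG"] < 0.05)
  expect_true(lsd$p_matrix["AG", "GG"] >= 0.05)

  # indistinguishable groups: one clique
  g0 <- groups_with_means(c(5, 5.01, 5.02), sds = 3, ns = c(20, 20, 20),
                          labels = c("A", "B", "C"), seed = 6)
  expect_equal(fisher_lsd(g0)$notation, "(A.B.C)")

  # well-separated groups: all singletons
  g1 <- groups_with_means(c(0, 10, 20), sds = 1, ns = c(15, 15, 15),
                          labels = c("A", "B", "C"), seed = 7)
  expect_equal(fisher_lsd(g1)$notation, "A B C")

  # all-singleton groups carry no pooled error
  solo <- quant_groups(c(1, 2, 3), c("a", "b", "c"))
  expect_error(fisher_lsd(solo), "singleton")
})

test_that("ordinal trend recovers linearity and decouples the two correlations", {
  # group means exactly linear in stage
  g <- groups_with_means(c(10, 12, 14, 16, 18), sds = 1,
                         ns = rep(12, 5), labels = as.character(0:4))
  tr <- trend_by_ordinal(g)
  expect_equal(tr$r_alerting, 1, tolerance = 1e-12)
  expect_true(tr$r_effect_size > 0.8)

  # strong linear pattern in the means but huge within-group spread:
  # r_alerting stays near 1 while r_effect_size collapses
  gn <- groups_with_means(c(10, 10.2, 10.4, 10.6, 10.8), sds = 25,
                          ns = rep(30, 5), labels = as.character(0:4),
                          seed = 8)
  trn <- trend_by_ordinal(gn)
  expect_gt(abs(trn$r_alerting), 0.95)
  expect_lt(abs(trn$r_effect_size), 0.2)

  expect_error(trend_by_ordinal(quant_groups(1:10, rep(c("a", "b"), 5))),
               "3 ordered groups")
})

test_that("group summaries report the descriptive convention", {
  g <- quant_groups(c(1, 2, 3, 4, 10, 20, 30, 40), rep(c("a", "b"), each = 4),
                    units = "g/L")
  s <- group_summary(g)
  expect_equal(s$median[s$group == "a"], 2.5)
  expect_equal(s$q1[s$group == "b"], 17.5)
  expect_equal(s$min, c(1, 10))
  expect_equal(s$max, c(4, 40))
  expect_equal(s$n, c(4L, 4L))
})
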