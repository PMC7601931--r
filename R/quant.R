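#' Group quantitative phenotype values
#'
#' Container for a one-way layout: an ordered set of group labels (e.g.
#' genotypes, or Rai stages) and the phenotype observations in each.
#' Group order matters — it fixes the sign convention of trend contrasts
#' and the order of LSD notation.
#'
#' @param values numeric vector of observations.
#' @param groups vector of group labels parallel to `values`; a factor's
#'   level order is respected, otherwise first-appearance order is used.
#' @param units free-text units string (e.g. `"MFI"`, `"%"`, `"g/L"`).
#' @return Object of class `quant_groups`: list with `labels`, `data`
#'   (named list of numeric vectors) and `units`.
#' @export
quant_groups <- function(values, groups, units = "") {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  labels <- if (is.factor(groups)) levels(droplevels(groups)) else
    unique(as.character(groups))
  groups <- as.character(groups)
  if (length(labels) < 2) stop("need at least 2 groups")
  data <- lapply(labels, function(l) values[groups == l])
  names(data) <- labels
  if (any(lengths(data) == 0)) stop("every group must be nonempty")
  structure(list(labels = labels, data = data, units = units),
            class = "quant_groups")
}

#' @export
print.quant_groups <- function(x, ...) {
  cat(sprintf("<quant_groups> %d groups (%s), n = %s%s\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              paste(lengths(x$data), collapse = "/"),
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

# Flatten to (values, group index) in supplied group order.
qg_flat <- function(groups) {
  list(y = unlist(groups$data, use.names = FALSE),
       g = rep(seq_along(groups$data), lengths(groups$data)))
}

# One-way sums of squares; returns list(ss_between, ss_within, means, n_j).
oneway_ss <- function(y, g, k) {
  n_j <- tabulate(g, k)
  sums <- vapply(seq_len(k), function(j) sum(y[g == j]), numeric(1))
  means <- sums / n_j
  grand <- sum(y) / length(y)
  ss_b <- sum(n_j * (means - grand)^2)
  ss_w <- sum((y - means[g])^2)
  list(ss_between = ss_b, ss_within = ss_w, means = means, n_j = n_j)
}

#' Sn robust scale estimator
#'
#' A double-median scale statistic: for each observation take the median
#' absolute difference to all observations, then take the median of those
#' per-point medians. It estimates the typical difference between two
#' randomly sampled observations and tolerates up to half the data being
#' outlying.
#'
#' Two conventions are provided. `"eq2_literal"` (the default used in the
#' summaries) takes the inner median over all j = 1..n including j = i,
#' with plain midpoint medians. `"rousseeuw_croux"` is the classical
#' estimator: inner high median over j != i, outer low median, times the
#' consistency factor 1.1926.
#'
#' @param x numeric vector, length >= 1.
#' @param mode `"eq2_literal"` or `"rousseeuw_croux"`.
#' @return Object of class `sn_result`: list with `sn` and `mode`.
#' @examples
#' sn_scale(c(1, 2, 3))$sn     # 1
#' sn_scale(c(0, 0, 10))$sn    # 0
#' @export
sn_scale <- function(x, mode = c("eq2_literal", "rousseeuw_croux")) {
  mode <- match.arg(mode)
  if (!length(x)) stop("empty vector")
  x <- as.numeric(x)
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  sn <- if (mode == "eq2_literal") {
    inner <- apply(d, 1L, stats::median)
    stats::median(inner)
  } else {
    if (n == 1L) 0 else {
      # high median of the n-1 off-diagonal diffs per row
      inner <- vapply(seq_len(n), function(i) {
        di <- sort(d[i, -i])
        di[(n - 1L) %/% 2L + 1L]
      }, numeric(1))
      # low median over the n per-point values
      1.1926 * sort(inner)[(n + 1L) %/% 2L]
    }
  }
  structure(list(sn = sn, mode = mode), class = "sn_result")
}

# Box-Cox power transform at fixed lambda.
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0))
    stop("Box-Cox requires positive values; shift the data first")
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

# ML lambda over [-5, 5] for the one-way layout y ~ group.
boxcox_lambda_ml <- function(y, g) {
  if (any(y <= 0))
    stop("Box-Cox requires positive values; shift the data first")
  fit <- stats::lm(y ~ factor(g), y = TRUE, qr = TRUE)
  bc <- MASS::boxcox(fit, lambda = seq(-5, 5, by = 0.01), plotit = FALSE)
  bc$x[which.max(bc$y)]
}

# Pooled skewness of residuals from group means (advisory trigger).
pooled_skewness <- function(y, g, k) {
  ss <- oneway_ss(y, g, k)
  r <- y - ss$means[g]
  m2 <- mean(r^2); m3 <- mean(r^3)
  if (m2 <= 0) return(0)
  m3 / m2^1.5
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition with the Fligner-Killeen variance
#' homogeneity p-value attached. With `transform = "boxcox"` the
#' observations are power-transformed before the decomposition, using the
#' maximum-likelihood lambda over \[-5, 5\] from the one-way layout
#' (or a user-fixed `lambda`). When Fligner-Killeen p < 0.05 or the
#' pooled residual skewness exceeds 1, an advisory is recorded in the
#' result (`advisory`) suggesting the transform and/or the bootstrap p —
#' both remain explicit opt-ins.
#'
#' @param groups a [quant_groups()].
#' @param transform `"none"` (default) or `"boxcox"`.
#' @param lambda optional fixed Box-Cox exponent; `NULL` estimates it.
#' @param bootstrap if `TRUE`, attach a bootstrap p-value for the omnibus
#'   F (see [bootstrap_f_pvalue()]); requires `seed`.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `anova_result`: `F`, `df_between`,
#'   `df_within`, `p_parametric`, `p_bootstrap` (or NA),
#'   `variance_homogeneity_p`, `boxcox_lambda` (or NA), `advisory`,
#'   `means`, `n_j`.
#' @export
anova_oneway <- function(groups, transform = c("none", "boxcox"),
                         lambda = NULL, bootstrap = FALSE, B = 10000,
                         seed = NULL) {
  stopifnot(inherits(groups, "quant_groups"))
  transform <- match.arg(transform)
  fl <- qg_flat(groups)
  y <- fl$y; g <- fl$g
  k <- length(groups$labels)
  if (length(y) <= k) stop("need more observations than groups")
  bc_lambda <- NA_real_
  if (transform == "boxcox") {
    bc_lambda <- if (is.null(lambda)) boxcox_lambda_ml(y, g) else lambda
    y <- boxcox_transform(y, bc_lambda)
  }
  ss <- oneway_ss(y, g, k)
  df_b <- k - 1L
  df_w <- length(y) - k
  if (ss$ss_within <= 0)
    stop("zero within-group variance everywhere; F undefined")
  F_stat <- (ss$ss_between / df_b) / (ss$ss_within / df_w)
  p_par <- stats::pf(F_stat, df_b, df_w, lower.tail = FALSE)
  flig <- stats::fligner.test(y, factor(g))$p.value
  skew <- pooled_skewness(y, g, k)
  advisory <- if (flig < 0.05 || abs(skew) > 1)
    sprintf(paste0("variance heterogeneity or skew detected ",
                   "(Fligner-Killeen p = %.3g, pooled skewness = %.2f); ",
                   "consider transform = 'boxcox' and/or bootstrap = TRUE"),
            flig, skew) else NA_character_
  tg <- groups
  if (transform == "boxcox")
    tg$data <- split(y, g)[as.character(seq_len(k))]
  p_boot <- if (bootstrap) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    names(tg$data) <- groups$labels
    bootstrap_f_pvalue(tg, statistic = "omnibus_F", B = B, seed = seed)
  } else NA_real_
  structure(list(F = F_stat, df_between = df_b, df_within = df_w,
                 p_parametric = p_par, p_bootstrap = p_boot,
                 variance_homogeneity_p = flig, boxcox_lambda = bc_lambda,
                 advisory = advisory,
                 means = stats::setNames(ss$means, groups$labels),
                 n_j = stats::setNames(ss$n_j, groups$labels)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g (Fligner p = %.3g)\n",
              x$df_between, x$df_within, x$F, x$p_parametric,
              x$variance_homogeneity_p))
  if (!is.na(x$p_bootstrap))
    cat(sprintf("  bootstrap p = %.4g\n", x$p_bootstrap))
  if (!is.na(x$advisory)) cat("  advisory:", x$advisory, "\n")
  invisible(x)
}

#' Planned linear contrast with effect-size correlations
#'
#' Tests a single a-priori weighted combination of group means,
#' \eqn{L = \sum_j \lambda_j \bar y_j} with \eqn{\sum_j \lambda_j = 0}.
#' The contrast F statistic is
#' \eqn{F = L^2 / (MSE \sum_j \lambda_j^2 / n_j)} with 1 numerator df and
#' the pooled within-group df. Two complementary correlations are
#' reported: `r_alerting`, the Pearson correlation between the group
#' means and the weights (how well the means follow the predicted
#' pattern, ignoring within-group noise), and `r_effect_size`,
#' \eqn{\sqrt{F / (F + df_{within})}} signed by L (the noise-adjusted
#' correlation between the contrast and the observations). The two
#' deliberately decouple: means can track the weights almost perfectly
#' (r_alerting near 1) while huge within-group spread keeps
#' r_effect_size near 0.
#'
#' @param groups a [quant_groups()].
#' @param weights numeric contrast weights, one per group, summing to 0.
#' @param bootstrap if `TRUE`, attach a bootstrap p for the contrast F.
#' @param B,seed bootstrap controls, as in [anova_oneway()].
#' @return Object of class `contrast_result`: `estimate`, `F_contrast`,
#'   `df_within`, `p_parametric`, `p_bootstrap`, `r_alerting`,
#'   `r_effect_size`, `weights`, `means`.
#' @examples
#' g <- quant_groups(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                   rep(c("a", "b", "c"), each = 3))
#' linear_contrast(g, c(-1, 0, 1))   # F = 6, r_effect_size = 0.707
#' @export
linear_contrast <- function(groups, weights, bootstrap = FALSE, B = 10000,
                            seed = NULL) {
  stopifnot(inherits(groups, "quant_groups"))
  k <- length(groups$labels)
  if (k < 2) stop("need at least 2 groups")
  if (length(weights) != k)
    stop("need one weight per group (", k, ")")
  if (abs(sum(weights)) > 1e-8) stop("contrast weights must sum to 0")
  if (all(weights == 0)) stop("contrast weights must not be all zero")
  fl <- qg_flat(groups)
  ss <- oneway_ss(fl$y, fl$g, k)
  df_w <- length(fl$y) - k
  if (ss$ss_within <= 0) stop("zero within-group variance; F undefined")
  mse <- ss$ss_within / df_w
  L <- sum(weights * ss$means)
  F_c <- L^2 / (mse * sum(weights^2 / ss$n_j))
  p_par <- stats::pf(F_c, 1, df_w, lower.tail = FALSE)
  r_alert <- if (stats::sd(ss$means) == 0 || stats::sd(weights) == 0)
    NA_real_ else stats::cor(ss$means, weights)
  r_eff <- sign(L) * sqrt(F_c / (F_c + df_w))
  p_boot <- if (bootstrap) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    bootstrap_f_pvalue(groups, statistic = "contrast_F", weights = weights,
                       B = B, seed = seed)
  } else NA_real_
  structure(list(estimate = L, F_contrast = F_c, df_within = df_w,
                 p_parametric = p_par, p_bootstrap = p_boot,
                 r_alerting = r_alert, r_effect_size = r_eff,
                 weights = weights,
                 means = stats::setNames(ss$means, groups$labels)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(paste0("<contrast_result> L = %.4g, F(1, %d) = %.4g, ",
                     "p = %.4g\n  r_alerting = %.3f, r_effect_size = %.3f\n"),
              x$estimate, x$df_within, x$F_contrast, x$p_parametric,
              x$r_alerting, x$r_effect_size))
  if (!is.na(x$p_bootstrap))
    cat(sprintf("  bootstrap p = %.4g\n", x$p_bootstrap))
  invisible(x)
}

#' Bootstrap p-value for the omnibus or contrast F
#'
#' Imposes the null by centering each group at its own mean, pools the
#' residuals, resamples them with replacement into the original group
#' sizes B times and recomputes the statistic. The p-value is
#' \eqn{(1 + \#\{F^* \ge F_{obs}\}) / (B + 1)}, which is never zero.
#' Deterministic for a fixed seed.
#'
#' @param groups a [quant_groups()].
#' @param statistic `"omnibus_F"` or `"contrast_F"`.
#' @param weights contrast weights, required for `"contrast_F"`.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed (mandatory: results must be reproducible).
#' @return Bootstrap p-value in (0, 1].
#' @export
bootstrap_f_pvalue <- function(groups, statistic = c("omnibus_F",
                                                     "contrast_F"),
                               weights = NULL, B = 10000, seed) {
  stopifnot(inherits(groups, "quant_groups"), B >= 100)
  statistic <- match.arg(statistic)
  if (statistic == "contrast_F" && is.null(weights))
    stop("contrast_F needs contrast weights")
  fl <- qg_flat(groups)
  y <- fl$y; g <- fl$g
  k <- length(groups$labels)
  N <- length(y)
  df_w <- N - k
  ss <- oneway_ss(y, g, k)
  if (ss$ss_within <= 0) return(1)   # degenerate: no residual variation
  f_of <- function(yy) {
    s <- oneway_ss(yy, g, k)
    if (statistic == "omnibus_F") {
      (s$ss_between / (k - 1)) / (s$ss_within / df_w)
    } else {
      L <- sum(weights * s$means)
      L^2 / ((s$ss_within / df_w) * sum(weights^2 / s$n_j))
    }
  }
  F_obs <- f_of(y)
  resid <- y - ss$means[g]
  set.seed(seed)
  n_ge <- 0L
  # chunk the B resamples to bound memory at ~8 MB per block
  block <- max(1L, min(B, floor(1e6 / N)))
  done <- 0L
  while (done < B) {
    b <- min(block, B - done)
    m <- matrix(sample(resid, N * b, replace = TRUE), nrow = N)
    gm <- rowsum(m, g) / ss$n_j                     # k x b group means
    grand <- colSums(m) / N
    ssb <- colSums(gm^2 * ss$n_j) - N * grand^2
    sst <- colSums(m^2) - N * grand^2
    ssw <- sst - ssb
    Fb <- if (statistic == "omnibus_F") {
      (ssb / (k - 1)) / (ssw / df_w)
    } else {
      Lb <- colSums(gm * weights)
      Lb^2 / ((ssw / df_w) * sum(weights^2 / ss$n_j))
    }
    n_ge <- n_ge + sum(Fb >= F_obs)
    done <- done + b
  }
  (1 + n_ge) / (B + 1)
}

# Maximal cliques of an undirected "not significantly different" graph on
# 1..k, by subset enumeration (k is small). Returns list of index vectors
# ordered by first member.
maximal_cliques <- function(adj) {
  k <- nrow(adj)
  subsets <- list()
  for (size in k:1) {
    for (comb in utils::combn(k, size, simplify = FALSE)) {
      if (size == 1L || all(adj[comb, comb][upper.tri(diag(size))])) {
        dominated <- any(vapply(subsets, function(s) all(comb %in% s),
                                logical(1)))
        if (!dominated) subsets[[length(subsets) + 1L]] <- comb
      }
    }
  }
  key <- vapply(subsets, function(s)
    paste(sprintf("%04d", s), collapse = ""), character(1))
  subsets[order(key)]   # lexicographic by member indices
}

#' Fisher's LSD pairwise comparisons with homogeneous-group notation
#'
#' All pairwise t tests using the pooled within-group mean square and its
#' degrees of freedom, unadjusted and two-sided (the classical LSD,
#' unprotected). The notation string lists maximal cliques of groups with
#' no significant internal pair: `"AA (AG.GG)"` means AA differs from
#' both AG and GG, which do not differ from each other; `"(A.B.C)"` means
#' nothing separates; `"A B C"` means every pair separates.
#'
#' @param groups a [quant_groups()].
#' @param alpha significance level (default 0.05, two-sided).
#' @return Object of class `lsd_result`: `p_matrix` (pairwise p-values),
#'   `alpha`, `notation`, `cliques`.
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  stopifnot(inherits(groups, "quant_groups"))
  fl <- qg_flat(groups)
  k <- length(groups$labels)
  ss <- oneway_ss(fl$y, fl$g, k)
  df_w <- length(fl$y) - k
  if (df_w <= 0) stop("all groups are singletons; no pooled error")
  mse <- ss$ss_within / df_w
  pm <- matrix(NA_real_, k, k, dimnames = list(groups$labels, groups$labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse * (1 / ss$n_j[i] + 1 / ss$n_j[j]))
    t_ij <- (ss$means[i] - ss$means[j]) / se
    pm[i, j] <- pm[j, i] <- 2 * stats::pt(abs(t_ij), df_w,
                                          lower.tail = FALSE)
  }
  adj <- pm >= alpha
  diag(adj) <- TRUE
  cliques <- maximal_cliques(adj)
  fmt <- vapply(cliques, function(cl) {
    if (length(cl) == 1L) groups$labels[cl] else
      paste0("(", paste(groups$labels[cl], collapse = "."), ")")
  }, character(1))
  structure(list(p_matrix = pm, alpha = alpha,
                 notation = paste(fmt, collapse = " "),
                 cliques = lapply(cliques, function(cl) groups$labels[cl])),
            class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("<lsd_result> alpha = %.3g: %s\n", x$alpha, x$notation))
  invisible(x)
}

#' Linear trend of a phenotype over an ordered grouping
#'
#' Runs [linear_contrast()] with centered, equally spaced weights over
#' the supplied group order — the planned contrast for a monotone trend
#' over an ordinal scale such as Rai stage 0-4 or allele dose. Reports
#' both r_alerting (fidelity of the group means to the linear pattern)
#' and r_effect_size (the same association after within-group noise).
#'
#' @param groups a [quant_groups()] whose label order is the ordinal
#'   order; at least 3 groups.
#' @param scores optional numeric scores, one per group (default
#'   `0:(k-1)`); they are centered to form the weights.
#' @param ... passed to [linear_contrast()] (e.g. bootstrap controls).
#' @return A `contrast_result`.
#' @export
trend_by_ordinal <- function(groups, scores = NULL, ...) {
  stopifnot(inherits(groups, "quant_groups"))
  k <- length(groups$labels)
  if (k < 3) stop("need at least 3 ordered groups for a trend")
  if (is.null(scores)) scores <- seq_len(k) - 1
  stopifnot(length(scores) == k)
  linear_contrast(groups, scores - mean(scores), ...)
}

#' Per-group descriptive summary
#'
#' The descriptive convention used throughout the reports: mean, median,
#' Sn scale, quartiles and range per group.
#'
#' @param groups a [quant_groups()].
#' @param sn_mode passed to [sn_scale()].
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sn`,
#'   `median`, `q1`, `q3`, `min`, `max`.
#' @export
group_summary <- function(groups, sn_mode = "eq2_literal") {
  stopifnot(inherits(groups, "quant_groups"))
  rows <- lapply(groups$labels, function(l) {
    x <- groups$data[[l]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = l, n = length(x), mean = mean(x),
               sn = sn_scale(x, sn_mode)$sn, median = q[2],
               q1 = q[1], q3 = q[3], min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Box-and-whisker plot (mean, quartiles, min-max convention)
#'
#' Draws one box per group with the *mean* as the central point, the box
#' spanning the first to third quartile, and whiskers to the minimum and
#' maximum — the convention used for the phenotype figures.
#'
#' @param groups a [quant_groups()].
#' @param main plot title.
#' @param ylab y-axis label; defaults to the units string.
#' @return Invisibly, the [group_summary()] backing the plot.
#' @export
box_whiskers <- function(groups, main = "", ylab = groups$units) {
  s <- group_summary(groups)
  k <- nrow(s)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = range(s$min, s$max),
                 xaxt = "n", xlab = "", ylab = ylab, main = main)
  graphics::axis(1, at = seq_len(k), labels = s$group)
  w <- 0.25
  for (i in seq_len(k)) {
    graphics::rect(i - w, s$q1[i], i + w, s$q3[i])
    graphics::segments(i, s$min[i], i, s$q1[i])
    graphics::segments(i, s$q3[i], i, s$max[i])
    graphics::segments(i - w / 2, s$min[i], i + w / 2, s$min[i])
    graphics::segments(i - w / 2, s$max[i], i + w / 2, s$max[i])
    graphics::points(i, s$mean[i], pch = 19)
  }
  invisible(s)
}
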