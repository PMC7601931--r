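#' Hardy-Weinberg departure coefficient with confidence interval
#'
#' Estimates the inbreeding-type departure coefficient
#' \deqn{f = \frac{p_{cc} - p_c^2}{p_c (1 - p_c)}}
#' where \eqn{p_c} is the frequency of the minor allele and \eqn{p_{cc}}
#' the frequency of its homozygote. \eqn{f > 0} indicates a deficiency of
#' heterozygotes, \eqn{f < 0} a deficiency of homozygotes, and \eqn{f = 0}
#' exact equilibrium. The 95% interval is a Wald interval built on the
#' asymptotic variance
#' \deqn{\widehat{Var}(\hat f) = \frac{(1-f)^2 (1-2f) +
#'   f(1-f)(2-f) / (2 p_c (1-p_c))}{n},}
#' the large-sample variance of the genotype-frequency estimator of f.
#' All intermediate quantities are carried at full precision; rounding is
#' a display concern only.
#'
#' @param counts a [genotype_counts()] oriented so `n_alt_hom` counts the
#'   minor-allele homozygotes (as produced by [tally_genotypes()]).
#' @param conf_level confidence level (default 0.95).
#' @param p_method which HWE test feeds the `p_hwe` slot: `"exact"`
#'   (default, see [hwe_exact_p()]) or `"chisq"` (see [hwe_chisq_p()]).
#' @return Object of class `hwe_result`: list with `f`, `se_f`, `ci_low`,
#'   `ci_high`, `p_hwe`, `allele_freq` (minor-allele frequency), `n`.
#' @examples
#' hwe_f(genotype_counts(261, 142, 36))   # f = 0.12, CI (0.02, 0.22)
#' @export
hwe_f <- function(counts, conf_level = 0.95,
                  p_method = c("exact", "chisq")) {
  stopifnot(inherits(counts, "genotype_counts"))
  p_method <- match.arg(p_method)
  n <- counts$n
  p <- (2 * counts$n_alt_hom + counts$n_het) / (2 * n)
  if (p <= 0 || p >= 1)
    stop("f undefined for monomorphic locus")
  pcc <- counts$n_alt_hom / n
  f <- (pcc - p^2) / (p * (1 - p))
  v <- ((1 - f)^2 * (1 - 2 * f) +
          f * (1 - f) * (2 - f) / (2 * p * (1 - p))) / n
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_hwe <- switch(p_method, exact = hwe_exact_p(counts),
                  chisq = hwe_chisq_p(counts))
  structure(list(f = f, se_f = se, ci_low = f - z * se, ci_high = f + z * se,
                 p_hwe = p_hwe, p_method = p_method, allele_freq = p, n = n,
                 snp_id = counts$snp_id),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, digits = 2, ...) {
  cat(sprintf("<hwe_result> f = %.*f, CI95%% = (%.*f, %.*f), p(%s) = %.3g, n = %d\n",
              digits, x$f, digits, x$ci_low, digits, x$ci_high,
              x$p_method, x$p_hwe, x$n))
  invisible(x)
}

#' Exact conditional test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE follows a hypergeometric-type distribution free of the
#' allele frequency. The p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count (ties included, no mid-p).
#'
#' @param counts a [genotype_counts()].
#' @return p-value in (0, 1]; exactly 1 for a monomorphic tally.
#' @export
hwe_exact_p <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n
  n_minor <- 2L * counts$n_alt_hom + counts$n_het
  if (n_minor == 0L || n_minor == 2L * n) return(1)
  # feasible heterozygote counts share the parity of the allele count
  h_max <- min(n_minor, 2L * n - n_minor)
  h <- seq.int(n_minor %% 2L, h_max, by = 2L)
  hom_minor <- (n_minor - h) %/% 2L
  hom_major <- n - h - hom_minor
  logw <- h * log(2) - lfactorial(hom_major) - lfactorial(h) -
    lfactorial(hom_minor)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(counts$n_het, h)]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

#' Pearson chi-squared test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against the HWE expectation at the estimated allele frequency,
#' without continuity correction. Provided alongside the exact test so
#' both conventions are available.
#'
#' @param counts a [genotype_counts()].
#' @return p-value in (0, 1].
#' @export
hwe_chisq_p <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n
  p <- (2 * counts$n_alt_hom + counts$n_het) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  observed <- c(counts$n_ref_hom, counts$n_het, counts$n_alt_hom)
  stat <- sum((observed - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genotype probabilities implied by (allele frequency, f)
#'
#' Inverts the departure coefficient: given minor-allele frequency `q`
#' and departure `f`, the genotype probabilities are
#' \eqn{P(\mathrm{alt\text{-}hom}) = q^2 + f q (1-q)},
#' \eqn{P(\mathrm{het}) = 2 q (1-q)(1-f)},
#' \eqn{P(\mathrm{ref\text{-}hom}) = (1-q)^2 + f q (1-q)}.
#'
#' @param q minor-allele frequency in \[0, 1\].
#' @param f departure coefficient in (-1, 1).
#' @return Numeric vector `c(ref_hom, het, alt_hom)` summing to 1.
#' @export
genotype_probs <- function(q, f) {
  stopifnot(q >= 0, q <= 1, f > -1, f < 1)
  probs <- c(ref_hom = (1 - q)^2 + f * q * (1 - q),
             het = 2 * q * (1 - q) * (1 - f),
             alt_hom = q^2 + f * q * (1 - q))
  bad <- names(probs)[probs < -1e-12 | probs > 1 + 1e-12]
  if (length(bad))
    stop("invalid (q, f) combination: P(", bad[1L],
         ") outside [0, 1] at q = ", q, ", f = ", f)
  pmin(pmax(probs, 0), 1)
}
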