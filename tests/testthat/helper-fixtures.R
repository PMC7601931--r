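# Shared fixtures: the two published genotype tables and small builders.

snp_rs3803800 <- function() snp_def("rs3803800", "TNFSF13", "G", "A")
snp_rs4985726 <- function() snp_def("rs4985726", "TNFRSF13B", "C", "G")

table_rs3803800 <- function() {
  case_control_table(genotype_counts(261, 142, 36, "rs3803800"),
                     genotype_counts(279, 179, 19, "rs3803800"),
                     "rs3803800")
}

table_rs4985726 <- function() {
  case_control_table(genotype_counts(353, 78, 8, "rs4985726"),
                     genotype_counts(353, 117, 7, "rs4985726"),
                     "rs4985726")
}

published_cohort <- function() {
  counts_to_cohort(list(rs3803800 = table_rs3803800(),
                        rs4985726 = table_rs4985726()),
                   list(snp_rs3803800(), snp_rs4985726()))
}

# Independent O(n^2) double-median oracle for the Sn scale, loop-based with
# hand-rolled midpoint and high/low medians (no calls into the implementation).
sn_bruteforce <- function(x, mode = "eq2_literal") {
  n <- length(x)
  mid_median <- function(v) {
    v <- sort(v)
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  if (mode == "eq2_literal") {
    inner <- numeric(n)
    for (i in seq_len(n)) {
      d <- numeric(n)
      for (j in seq_len(n)) d[j] <- abs(x[i] - x[j])
      inner[i] <- mid_median(d)
    }
    return(mid_median(inner))
  }
  if (n == 1) return(0)
  inner <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i) d <- c(d, abs(x[i] - x[j]))
    d <- sort(d)
    inner[i] <- d[floor(length(d) / 2) + 1]        # high median
  }
  inner <- sort(inner)
  1.1926 * inner[floor((n + 1) / 2)]               # low median
}

# Independent full-enumeration oracle for the exact conditional HWE test:
# enumerate every genotype table with n samples, keep those sharing the
# observed minor-allele count, weight by the unconditional HWE multinomial
# probability at an arbitrary valid allele frequency, and normalise. The
# conditional distribution is free of the frequency, so any p in (0,1) works.
hwe_exact_bruteforce <- function(rr, het, aa, p = 0.37) {
  n <- rr + het + aa
  n_minor <- 2 * aa + het
  if (n_minor == 0 || n_minor == 2 * n) return(1)
  probs_hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  tabs <- list(); w <- numeric(0)
  for (a in 0:n) for (h in 0:(n - a)) {
    r <- n - a - h
    if (2 * a + h == n_minor) {
      tabs[[length(tabs) + 1]] <- c(r, h, a)
      w <- c(w, stats::dmultinom(c(r, h, a), prob = probs_hwe))
    }
  }
  w <- w / sum(w)
  obs <- which(vapply(tabs, function(t) all(t == c(rr, het, aa)),
                      logical(1)))
  sum(w[w <= w[obs] * (1 + 1e-9)])
}

# Build a quant_groups whose groups have exactly the requested means and a
# common SD, from seeded normal draws recentred and rescaled per group.
groups_with_means <- function(means, sds, ns, labels = NULL, seed = 1) {
  if (length(sds) == 1) sds <- rep(sds, length(means))
  if (is.null(labels)) labels <- paste0("g", seq_along(means))
  set.seed(seed)
  vals <- list()
  for (i in seq_along(means)) {
    x <- stats::rnorm(ns[i])
    x <- (x - mean(x)) / stats::sd(x) * sds[i] + means[i]
    vals[[i]] <- x
  }
  quant_groups(unlist(vals), factor(rep(labels, ns), levels = labels))
}

# Minimal one-SNP generator spec used across tests.
tiny_spec <- function(seed = 1, n_case = 150, n_ctrl = 200, ...) {
  cohort_spec(n_case, n_ctrl,
              snps = list(list(def = snp_rs3803800(), q = 0.25, ...)),
              seed = seed)
}
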