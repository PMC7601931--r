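---
title: "Case-control SNP association and genotype-phenotype analysis for CLL cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control SNP association and genotype-phenotype analysis for CLL cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllassoc)
```

## Scope and design

`cllassoc` implements the statistical core of a candidate-gene
case-control study of chronic lymphocytic leukaemia (CLL): biallelic SNPs
in the *TNFSF13* (APRIL) / *TNFRSF13B* (TACI) axis genotyped in a patient
and a control arm, with flow-cytometry, ELISA and immunoglobulin
phenotypes measured on subsets of the patients. The pipeline covers four
stages, each usable on its own:

1. **Cohort handling and QC** — long-format genotype/phenotype/CNV
   tables, a VCF subset reader, and the 17p single-copy exclusion.
2. **Hardy-Weinberg machinery** — the departure coefficient *f* with an
   asymptotic confidence interval, plus exact and chi-squared tests.
3. **Case-control association** — genotype-distribution chi-squared
   tests and continuity-corrected odds ratios under codominant,
   dominant, recessive and allelic models.
4. **Quantitative genotype-phenotype statistics** — one-way ANOVA with
   planned linear contrasts, a bootstrap F null, the Sn robust scale,
   Box-Cox support, Fligner-Killeen homogeneity checks, Fisher's LSD
   with homogeneous-group notation, and the alerting / effect-size
   correlations.

A synthetic-cohort generator reproduces exactly the statistical
structure the pipeline assumes, so every stage is validated end to end
against known ground truth without any external data.

## Sample-level QC: the single-copy exclusion

Both genes sit on the short arm of chromosome 17, a region recurrently
deleted in CLL. A sample carrying a single copy of either gene is
hemizygous there: its "genotype" at any SNP in the deleted interval is a
one-allele artifact, not a diploid call. `apply_cnv_exclusion()`
therefore removes any sample whose copy number falls below 2 for *any*
screened gene, from **all** downstream analyses, and reports the removed
ids and per-gene single-copy fractions. A sample lacking a copy-number
call is retained with a warning: the screen is assumed complete, so a
missing call is a data defect, not evidence of deletion. Missing
*genotypes*, by contrast, are excluded per SNP only — each SNP keeps its
own usable N, and nothing is imputed.

## Hardy-Weinberg departure

For a SNP with minor-allele frequency $p_c$ and minor-homozygote
frequency $p_{cc}$ the departure coefficient is

$$f = \frac{p_{cc} - p_c^2}{p_c\,(1 - p_c)},$$

positive when heterozygotes are deficient, negative when homozygotes
are, zero at equilibrium. The inverse map
$P(\text{alt-hom}) = q^2 + fq(1-q)$,
$P(\text{het}) = 2q(1-q)(1-f)$,
$P(\text{ref-hom}) = (1-q)^2 + fq(1-q)$ reproduces the observed genotype
frequencies exactly (a property the test suite checks), and is also what
the cohort generator samples from.

The 95% interval on $\hat f$ is a Wald interval with the large-sample
variance

$$\widehat{\mathrm{Var}}(\hat f) = \frac{(1-f)^2(1-2f) +
  f(1-f)(2-f)\,/\,(2\,p_c(1-p_c))}{n}.$$

$f$ and $p_c$ are carried at full precision throughout; rounding to two
decimals is a display decision applied only in reports.

Two HWE tests are exposed. `hwe_exact_p()` is the exact conditional
test: given the observed allele counts, the heterozygote count follows a
hypergeometric-type null distribution that is free of the allele
frequency, and the p-value sums the probabilities of all outcomes no
more probable than the observed one (ties included, no mid-p — the
standard convention). `hwe_chisq_p()` is the 1-df Pearson
goodness-of-fit variant. The exact test is the default `p_hwe` because
it is well calibrated at the rare-homozygote counts typical of these
loci, where the chi-squared approximation is at its weakest; both
remain available since the two conventions coexist in this literature.
The exact implementation is validated against full enumeration of the
conditional sample space for every table with up to 25 samples, and its
type-I error at study scale (n = 477, minor-allele frequency 0.2275) is
checked to sit at the nominal 5% level over 1000 null simulations.

## Case-control association

`genotype_chisq()` tests the 3-by-2 genotype-by-status table with
Pearson's statistic, no continuity correction, df = 2; a genotype class
empty in both arms is dropped with a warning and the df reduced.

All reported odds ratios use the Haldane-Anscombe correction: 0.5 is
added to **all four** cells unconditionally, then the cross-product
ratio and the Woolf (log-scale Wald) interval
$\exp(\ln \mathrm{OR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$ with
$z = 1.959964$ are computed on the corrected cells. The unconditional
form (rather than correcting only zero-cell tables) keeps the estimator
continuous in the counts, guarantees finiteness, and is the convention
under which the package's desk-scale reproduction of published
genotype tables agrees at two-decimal rounding; `correction = "none"`
is available and converges to the corrected value as counts grow (also
a tested property). Collapsed models follow the field's definitions —
dominant: carriers vs the other homozygote; recessive: effect-allele
homozygote vs the rest; allelic: 2n allele counts — with the reference
genotype in per-genotype reports being the homozygote of the more
frequent allele (its OR is 1 by construction and is omitted).

P-values for collapsed tables are reported both as 1-df chi-squared and
Fisher exact, since either may be wanted. No multiplicity adjustment is
applied by default — the analyses this package reproduces are planned,
a-priori hypotheses — but `bh = TRUE` appends Benjamini-Hochberg
adjusted p-values for exploratory scans.

## Quantitative statistics

### The Sn scale

The descriptive spread statistic is a double median of absolute
pairwise differences. The default mode takes, for each observation, the
plain (midpoint) median of $|x_i - x_j|$ over **all** $j = 1 \dots n$
including $j = i$, then the plain median over $i$. This literal form is
the package's primary definition; the classical Rousseeuw-Croux
variant (inner high median over $j \neq i$, outer low median,
consistency factor 1.1926) is available as
`mode = "rousseeuw_croux"`. The two differ on small samples — e.g. the
literal form gives 0 whenever more than half the per-point medians
vanish — so the mode is always explicit in the result object. Both are
validated against an independent brute-force double-median oracle on
hundreds of random vectors.

### ANOVA, Box-Cox and the advisory

`anova_oneway()` performs the standard one-way decomposition and always
attaches the Fligner-Killeen variance-homogeneity p-value. Box-Cox
transformation is an explicit opt-in: the exponent is estimated by
profile maximum likelihood over $\lambda \in [-5, 5]$ (step 0.01) on
the one-way layout, or fixed by the caller. "Transform if necessary" is
operationalised as an *advisory*, not an automatism: when
Fligner-Killeen p < 0.05 or the pooled residual skewness exceeds 1, the
result carries a message recommending the transform and/or the
bootstrap p, and the caller decides. At $\lambda = 1$ the transform is
an affine shift and every statistic is unchanged (tested); on lognormal
groups the estimated $\lambda$ lands near 0 (tested at 500 per group).
Non-positive values are a hard error instructing a shift rather than a
silent offset.

### Planned contrasts and the two correlations

For weights $\lambda_j$ with $\sum_j \lambda_j = 0$,

$$F_{\text{contrast}} = \frac{L^2}{\mathrm{MSE} \sum_j \lambda_j^2 / n_j},
  \qquad L = \sum_j \lambda_j \bar y_j,$$

with 1 numerator df and the pooled within-group df. Two correlations
summarise it: `r_alerting`, the Pearson correlation between the group
means and the weights — how faithfully the mean pattern follows the
prediction, blind to within-group noise — and `r_effect_size`,
$\sqrt{F / (F + df_{\text{within}})}$ carrying the sign of $L$ — the
same association after the noise is priced in. They deliberately
decouple: a mean pattern can track stage almost perfectly
(r_alerting near 1) while huge within-group variability keeps
r_effect_size near 0, and the test suite constructs exactly that case.
`trend_by_ordinal()` builds the centered equally-spaced weights over
the supplied group order (genotype dose or Rai stage 0-4); the sign of
the result follows that order, so an ordering chosen descending flips
both correlations — declare the order deliberately.

### The bootstrap F null

When the F distribution is in doubt, `bootstrap_f_pvalue()` imposes the
null by centering each group at its own mean, pooling the residuals,
resampling with replacement into the original group sizes B times
(default 10000) and recomputing the statistic; the p-value is
$(1 + \#\{F^* \ge F_{\text{obs}}\})/(B + 1)$, which can never be zero
and is exact-friendly. The scheme assumes exchangeable residuals across
groups (it pools them), which matches the equal-variance working model
of the ANOVA it calibrates. A seed is mandatory — there is no silent
randomness anywhere in the package — and resampling is chunked so
memory stays bounded at any B. Under normality the bootstrap p tracks
the parametric p (mean absolute difference below 0.02 at B = 2000 over
50 datasets, an acceptance property), and it is invariant to relabeling
groups.

### Fisher's LSD and the clique notation

`fisher_lsd()` runs all pairwise t tests with the pooled MSE and its
df, two-sided, unadjusted, at a fixed $\alpha = 0.05$, unprotected (the
omnibus F is reported alongside, not used as a gate). The notation
string renders the maximal cliques of the "not significantly different"
graph: `"AA (AG.GG)"` says AA separates from both AG and GG, which do
not separate from each other; cliques may overlap, singletons print
bare, and ties in ordering are broken lexicographically by group
position so the string is deterministic. The construction is checked
against an independent subset-enumeration oracle on random layouts of
3-5 groups.

## The synthetic cohort generator

`cohort_spec()` + `simulate_case_control()` generate cohorts with the
exact structure the pipeline assumes:

* **Genotypes**: controls drawn from the $(q, f_{\text{ctrl}})$
  three-genotype distribution; cases from the $(q, f_{\text{case}})$
  distribution reweighted multiplicatively by per-genotype odds ratios
  and renormalised. The reweighting is the genotype-level logistic
  model, so the case-control genotype OR of genotype $j$ versus the
  reference homozygote equals the specified $or_j$ *analytically* —
  recovery targets need no simulation calibration.
* **Phenotypes**: per-genotype normal or lognormal draws (location on
  the log scale for the latter), with an additive stage-linear mean
  shift for flagged phenotypes and clamping of percent-scale values to
  [0, 100].
* **Structure**: per-gene single-copy CNV flags at specified fractions,
  per-SNP missing-genotype masking, and ordinal stage labels for cases.

One master seed drives everything through fixed per-component
substreams (SNP k, phenotype m, CNV gene j each get their own derived
seed), so adding a phenotype to a spec never changes the genotype
draws, and identical specs produce byte-identical cohort files.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs (each locus is independent), age/sex or any
confounding structure (the reproduced analyses adjust for nothing),
genotyping error, and informative missingness (masking is uniform).
Passing tests therefore demonstrate that the estimators recover the
parameters of *this* generating model at the stated sizes — they do not
certify behaviour under confounding or correlated loci, which are out
of scope for the pipeline itself as well.

Default validation sizes were chosen once, at the scale of the study
the pipeline reproduces (arms of 439/477; 50,000 draws for
estimator-consistency checks; 100-200 seeds for coverage; 1000
replicates for type-I calibration) and are stated in the tests that use
them.

## Numerical and degenerate-input conventions

* Monomorphic tallies: $f$ is undefined (hard error); the exact HWE
  p is exactly 1 (single outcome).
* Exact-test ties are included in the rejection sum with a $10^{-9}$
  relative tolerance guarding float comparison of equal probabilities.
* Zero cells: corrected ORs are always finite; uncorrected ORs error.
* Empty genotype classes: dropped rows reduce the chi-squared df.
* All-zero residuals: bootstrap p is 1; zero within-group variance
  everywhere makes F a hard error.
* Medians of even-length sets are midpoints except where the
  Rousseeuw-Croux mode specifies high/low medians.
* Displayed percentages and 2-decimal statistics are rounded at output;
  every stored value is full precision.

## The published-table reproduction

`counts_to_cohort()` expands any printed per-arm genotype tally into an
explicit per-sample cohort (deterministically; with several SNPs the
joint assignment is arbitrary but the margins are exact, which is all a
per-SNP analysis reads). `analysis/01_table1_reproduction.R` feeds the
bundled published counts for rs3803800 (G>A) and rs4985726 (C>G)
through the full report and reproduces the printed chi-squared values,
all per-genotype and collapsed-model odds ratios with their intervals,
and the per-arm departure coefficients with theirs, at two-decimal
rounding. One caveat is deliberate: for the rs4985726 control arm the
estimator applied to the printed counts gives $f = -0.0353$ (rounding
to $-0.04$, CI $-0.12$ to $0.05$), while the published row shows
$-0.03$ (CI $-0.11$; $0.048$); the row is internally inconsistent with
its own counts, and the package reports the recomputation rather than
the printed digit.

## Limitations

* No logistic regression or covariate adjustment; association is
  table-based by design.
* No haplotype or multi-locus analysis; no LD modelling.
* VCF support is deliberately minimal: biallelic SNPs with GT only.
* The bootstrap calibrates the F statistic under residual
  exchangeability; it is not a fix for arbitrary dependence.
* Raw per-patient phenotype data behind the published group summaries
  are not available anywhere; the quantitative machinery is therefore
  validated by construction (oracles, calibration, recovery) rather
  than by reproducing those summaries.
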