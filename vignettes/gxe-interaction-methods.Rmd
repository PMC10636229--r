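---
title: "Methods: genome-wide gene-environment interaction analysis in case-control consortia"
author: "gxewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide gene-environment interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxewas)
options(gxewas.quiet = TRUE)
```

## The problem

Dietary folate and supplemental folic acid are leading candidate modifiers of
colorectal cancer risk, but individual genetic background may modify (or even
reverse) the exposure's effect. `gxewas` implements the statistical machinery
for scanning a genome of imputed variant dosages for such gene-environment
(GxE) interactions in a multi-study case-control consortium: per-variant
interaction statistics, two-step weighted hypothesis testing, random-effects
meta-analysis of the marginal exposure association, and genotype-stratified
odds-ratio tables.

Every stage is exercised against a synthetic consortium generator with known
genetic architecture, so that size, power, bias and parameter-recovery
properties are testable facts about the code rather than assumptions.

## Exposure harmonization

Folate exposure is harmonized before modeling:

* **Dietary folate equivalents.** Synthetic folic acid is absorbed more
  efficiently than food folate, so total intake is expressed as
  `DFE (ug/d) = dietary folate + 1.7 x supplemental folic acid`. A supplement
  user with an unknown dose is assigned the standard multivitamin dose of
  400 ug/d; non-users contribute zero. Missing dietary intake propagates.
* **Quartile coding.** Intake is coded 0-3 by sex- and study-specific
  quartiles (linear-interpolation percentiles, type 7). Values equal to a cut
  point fall in the lower quartile — a deterministic, documented tie rule.
  Quartiles are computed on cases and controls combined within sex x study:
  exposure coding should not depend on the outcome. Whether the original
  consortium derived cut points from controls only is not recoverable, so
  both conventions exist; combined is the default. Strata with fewer than
  four non-missing values are set missing with a warning.
* **Covariates.** Alcohol is dichotomized at 1 g/d (nondrinker vs drinker),
  BMI is rescaled so one unit is 5 kg/m^2, and smoking is collapsed to
  never/ever. Harmonization retains the raw columns, making it idempotent.

## The regression engine

All tests are Wald tests from one self-contained fitting engine:
iteratively-reweighted least squares for logistic models and ordinary least
squares for linear ones, with covariance from the inverse observed
information. Numerical choices:

* convergence when the maximum absolute score falls below `1e-8` or the
  relative log-likelihood change falls below `1e-8`; at most 50 iterations;
* step-halving (up to 10 halvings) so the log-likelihood never decreases;
* collinear columns dropped by pivoted QR in input order and reported;
* quasi-complete separation (a fitted probability within `1e-8` of 0 or 1
  together with a diverging coefficient) is *flagged and reported*, not
  repaired — stratified tables deliberately show the resulting extremely wide
  intervals, as consortium reports do for empty strata. A Firth-penalized
  mode exists for users who want finite estimates, but it is off by default.

## The per-variant statistics

For a variant with dosage $g \in [0,2]$ (log-additive coding), exposure $e$,
disease $D$ and covariates $\mathbf{z}$ (age, sex, study indicators,
platform, principal components as available):

* **Standard GxE:** $\mathrm{logit}\,P(D{=}1) = \beta_0 + \beta_G g +
  \beta_E e + \beta_{G\times E}\, ge + \gamma'\mathbf{z}$; the test is the
  1-df Wald test of $\beta_{G\times E}$.
* **Marginal D|G:** the same model without the exposure structure; Wald test
  of $\beta_{D|G}$.
* **G|E correlation:** regression of $e$ on $g$ and covariates — logistic
  for binary exposure, linear on the 0-3 quartile score otherwise — in the
  combined case-control sample ($\delta_G$), and separately among cases only
  (the case-only interaction test).
* **2DF joint test:** the joint Wald chi-square of $(\beta_G,
  \beta_{G\times E})$ *within* the interaction model — one likelihood, not
  two separate models.
* **3DF joint test:** the 2DF chi-square plus the combined-sample G|E
  chi-square, referred to $\chi^2_3$. The combination rule assumes the G|E
  piece is asymptotically independent of the case-control pieces; this is
  verified empirically in the test suite, where the 3DF p-value is uniform
  under the global null (Kolmogorov-Smirnov).

The case-only test is more powerful than the standard interaction test when
gene and environment are independent in the source population, and biased
when they are not; both behaviors are asserted as properties of the
implementation (power comparison at matched n, and an inflated rejection
rate when exposure depends on genotype with log-OR log 1.5 per allele).

Record filters follow consortium practice: variants are retained when
MAF > 0.01 and imputation R^2 > 0.8, both strict inequalities. Default
significance thresholds are 2e-8 (primary, accounting for the use of three
testing procedures) and 5e-8 (suggestive). Models are complete-case per
variant with counts logged; the G|E screen regresses E on G (either
regression direction defines a valid screen; the null-distribution tests
are the guard that this choice preserves size).

## Two-step weighted hypothesis testing

Step 1 ranks all variants by the screening p-value
$p_\text{screen} = P(\chi^2_2 > \chi^2_{D|G} + \chi^2_{G|E})$, a statistic
asymptotically independent of the interaction test under the null. Step 2
tests interactions against rank-dependent thresholds: ranks are grouped into
bins of sizes $B, 2B, 4B, \dots$ (default $B = 5$), bin $b$ receives
$\alpha \cdot 2^{-b}$ split equally over its members, so the total alpha
spent is $\alpha(1 - 2^{-n_\text{bins}}) \le \alpha$. The last bin is
truncated to the remaining variants and keeps its truncated size in the
denominator; because a *heavily* truncated final bin could then receive a
more lenient threshold than its predecessor, thresholds are additionally
capped to be non-increasing in rank (the cap can only reduce alpha spend).
An optional mode redistributes the unspent geometric tail into the last bin.
Ties in the screening statistic are broken by genomic order, making the
procedure deterministic and invariant to input order.

## Meta-analysis of the marginal exposure association

Study-level logistic estimates (per-quartile trend or user-vs-nonuser,
adjusted for age, sex and total energy; BMI and smoking in the sensitivity
set) are pooled by random-effects meta-analysis. The between-study variance
$\tau^2$ uses DerSimonian-Laird by default, $\max(0, (Q - df)/C)$, with a
profile-REML alternative for robustness checks. Confidence intervals use the
Hartung-Knapp adjustment: variance $q/\sum w_i$ with
$q = \sum w_i (y_i - \hat y)^2 / (k-1)$ and a $t_{k-1}$ reference. The plain
(untruncated) HK variance is the default; a modified-HK floor ($q \ge 1$)
is available, since the plain estimator can produce intervals narrower than
the fixed-effect interval under strong homogeneity. Heterogeneity is
summarized by $I^2 = \max(0, (Q - df)/Q) \times 100$; subgroups (sex,
design, site, alcohol, latency strata supplied as labels) are compared with
the fixed-effect between-group statistic $Q_\text{between}$ on $J-1$ df,
which for two subgroups equals the z-test on the difference. Funnel exports
flag studies more than 1.96 standardized errors from the pooled estimate.

## Genotype-stratified tables

Stratified odds ratios are computed in both parameterizations of the
standard interaction report: exposure effect within each genotype stratum,
and genotype effect (vs the common homozygote) within each exposure level.
Strata come from best-guess genotypes (rounded dosage) while fractional cell
counts use per-subject genotype probabilities, so the table mirrors the
discrete-strata-with-fractional-counts presentation of consortium reports.
When only a dosage $d$ is available the class probabilities are
under-determined; the deterministic, dosage-preserving convention
$p_2 = \max(0, d-1)$, $p_1 = d - 2p_2$, $p_0 = 1 - p_1 - p_2$ (mass on
adjacent classes) is used, and exact probabilities (a VCF GP field) are
accepted when present. A *qualitative* interaction is flagged when one
stratum's exposure OR interval lies entirely above 1 and another's entirely
below 1.

Interaction signals that merely tag established susceptibility loci are
routed to a separate stream tested at the Bonferroni threshold
$\alpha / n_\text{loci}$ (0.05/203 = 0.00025 for the standard colorectal
cancer locus list). Routing uses a distance window of ±500 kb (closed
interval) around each known locus; this is a proxy for "driven by" a known
locus, since linkage structure is not modeled here, and the window is
configurable.

## The synthetic consortium generator

The generator exists because no individual-level consortium data can ship
with the package: **all simulator distributions are synthetic stand-ins**,
chosen for testability rather than realism.

* Genotypes are Binomial(2, MAF) per variant — Hardy-Weinberg, no linkage
  disequilibrium, no population stratification. Optional dosage noise adds
  clamped Gaussian perturbation (`[0,2]`), emulating imputation uncertainty
  additively only.
* Binary exposure follows $\mathrm{logit}\,P(E{=}1|g) = a + \theta g$ with
  $a$ solved numerically for the target marginal prevalence; $\theta = 0$
  gives exact gene-environment independence (the case-only test's
  assumption), $\theta \ne 0$ controlled dependence.
* Disease follows the same logistic form the analysis fits, then cases and
  controls are sampled retrospectively from a simulated source population —
  mirroring the case-control design and keeping odds ratios interpretable.
* Covariates: age ~ Normal(60, 8), sex ~ Bernoulli(0.5), energy ~
  Normal(2000, 500) truncated positive — arbitrary, documented,
  configurable.
* Studies are independent; per-study exposure effects are drawn
  Normal($\beta_E$, study_sd^2) to create controllable meta-analysis
  heterogeneity. One global seed spawns per-study substreams, so identical
  configurations reproduce bitwise-identical consortia.

Because the generator omits LD, stratification and differential measurement
error, passing tests demonstrate the *statistical machinery* is correct —
size, power ordering, bias directions, estimator identities — not that any
particular real-data finding would replicate.

## Problem sizes used in the checks

The automated checks run at sizes chosen to give stable Monte Carlo
estimates while staying fast on a single CPU: per-test size uses one null
consortium of 1,500 variants at 1,500 cases / 1,500 controls (acceptance
script: 1,000 at 1,000/1,000); two-step family-wise error uses 100-150 null
replicates of 50-60 variants; paired power uses 40-60 replicates of a
100-variant genome with an interaction variant carrying a marginal signal
($\beta_G = \log 1.3$, $\beta_{G\times E} = \log 1.5$, MAF 0.3); the
qualitative-interaction recovery study uses 100-200 replicates of n = 20,000
(10,000 cases / 10,000 controls) with stratum ORs 0.82 and 1.63
($\beta_{G\times E} = \log(1.63/0.82) \approx 0.687$, MAF 0.15); case-only
comparisons use 100-150 replicates at 300/300. Empirical rates are judged
against exact binomial 99% intervals.

## Known limitations

* No LD or haplotype structure: rank-recovery results say nothing about
  fine-mapping within a locus.
* The G|E screen and 3DF component regress E on G; with strong sampling
  distortion (very large marginal genetic effects under case-control
  sampling) the combined-sample G|E component is no longer centered, which
  affects the 3DF test's null only at variants with real marginal effects.
* Separation is reported rather than corrected by default; rare-variant
  strata produce intervals like "0.02 (0, 100)" by design.
* Model-based (not sandwich) covariance throughout; no GEE/mixed models.
* The binary-dosage container formats of large consortia are not read;
  VCF with a DS FORMAT field is the interchange format.
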