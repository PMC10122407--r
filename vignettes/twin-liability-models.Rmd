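---
title: "Liability-threshold twin models for binary comorbid phenotypes"
author: "twinliab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models for binary comorbid phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinliab)
```

## The scientific problem

Neurodevelopmental conditions such as autism and ADHD co-occur with a
range of physical health conditions — epilepsy, asthma, functional
gastrointestinal disorders among others. The classical twin design asks
how much of that co-occurrence is driven by shared genes versus shared or
individual environment. Monozygotic (MZ) co-twins share all their
segregating DNA, same-sex dizygotic (DZ) co-twins on average half of it;
comparing cross-twin resemblance between the two zygosity groups
identifies additive-genetic (A), shared-environment (C) and
nonshared-environment (E) contributions to a trait, and — in the
bivariate extension — to the *covariance* between two traits.

All phenotypes here are binary diagnoses or screening flags. The package
therefore works on the liability scale: each binary trait is the
indicator that a latent standard-normal liability exceeds a threshold
\(t\) fixed by the prevalence \(K\) through \(P(L > t) = K\). Pairs of
dichotomized liabilities are bivariate (or, for twin pairs measured on
two traits, four-variate) normal, so every model likelihood reduces to
multinomial probabilities given by normal rectangle integrals.

## Model structure

**Univariate (`twin_ace`).** For one trait, liability variance is
decomposed as \(a^2 + c^2 + e^2 = 1\). The implied cross-twin liability
correlations are \(r_{MZ} = a^2 + c^2\) and \(r_{DZ} = a^2/2 + c^2\).
The fit maximizes the joint multinomial likelihood of the MZ and DZ
cross-twin 2×2 tables — the sufficient statistics for binary twin data
without covariates, which makes the fit orders of magnitude faster than a
rowwise likelihood while being exactly equivalent. A single threshold is
shared across twins and zygosity groups (no sex or age moderation in the
core model). Assumptions inherited from the classical design: equal
environments across zygosity, random mating, no A×C interplay, and no
dominance (ACE rather than ADE; with only two zygosity groups C and D are
not jointly identified, and the genetic proportion is interpreted as
broad-sense heritability).

**Bivariate (`twin_biv`).** Two traits per twin give 16 joint patterns
per pair. Cell probabilities are 4-dimensional normal rectangles under
the model-implied correlation matrix: within-person cross-trait
correlation \(r_{PH} = a_1 a_2 r_a + c_1 c_2 r_c + e_1 e_2 r_e\),
cross-twin within-trait \(g\,a_i^2 + c_i^2\), and cross-twin cross-trait
\(g\,a_1 a_2 r_a + c_1 c_2 r_c\), with \(g = 1\) (MZ) or \(1/2\) (DZ).
The model is the bivariate Cholesky decomposition, estimated and reported
in the mathematically equivalent correlated-factors parameterization
(per-trait paths plus the etiologic correlations \(r_a, r_c, r_e\));
the test suite verifies that the two parameterizations produce identical
likelihood values under the standard mapping. `decompose_rph()` splits
\(r_{PH}\) into its genetic, shared- and nonshared-environmental parts;
the genetic share is the bivariate heritability.

**Associations (`fit_clustered_logistic`).** Odds ratios between
phenotype groups and conditions come from population-averaged logistic
regression adjusted for sex and age group, with a pair-clustered robust
(sandwich) variance — i.e. a GEE with independence working correlation.
A within-pair conditional likelihood would absorb pair-constant
covariates and could not produce sex/age-adjusted cohort-level odds
ratios, so the population-averaged form is used. With 13 outcome
conditions the Bonferroni threshold is \(0.05/13 = 0.0038\);
only pairs below it proceed to the bivariate stage in `run_pipeline()`.

**Descriptives.** Prevalences use Wilson score intervals (chosen over
Wald because many conditions have small counts; outputs label the
method). Cross-twin and cross-twin cross-trait correlations are
tetrachorics on double-entered tables — both twin orders counted, making
estimates invariant to within-pair ordering — with standard errors based
on the pair count rather than the doubled table total. Proband-wise
cross-concordances follow the standard rule that every affected
individual is a proband, so concordant-proband pairs contribute twice.

## Two-stage reproduction from published summaries

Individual-level registry data for the motivating cohort are
access-restricted. The package therefore supports a two-stage route that
needs only published summary statistics: `implied_table()` converts a
prevalence, a cross-twin correlation and a pair count into the expected
(fractional) 2×2 table, and `fit_from_summary()` runs the full ML fit on
those tables. `catss_reference()` ships the published prevalences,
MZ/DZ correlations and variance components for 13 physical health
conditions in a cohort of 4,767 MZ and 5,580 same-sex DZ pairs; the
acceptance suite checks that the two-stage fits reproduce the published
A/V and C/V within ±0.03 (±0.01 for asthma, where the Falconer moment
solution is exact and interior).

## Numerical kernels and choices

* **2-D rectangles** use an in-package Drezner–Wesolowsky/Genz angular
  quadrature (`R/bvn.R`): a 20-node Gauss–Legendre rule for
  \(|r| \le 0.925\) and a 96-node rule beyond, which holds the absolute
  error at machine precision across the whole range including
  \(|r| = 0.9999\). The test suite compares it against an independent
  adaptive-quadrature oracle at 1e-8.
* **3–4-D rectangles** use the deterministic Miwa product rule
  (`mvtnorm`, 128 steps; absolute error ≈ 2.5e-8), falling back to
  quasi-Monte Carlo with an internally fixed seed only for near-singular
  correlation matrices, so all results are bit-for-bit reproducible.
* **16-cell probabilities** are assembled by inclusion–exclusion over
  upper-orthant integrals, exploiting the twin-exchange symmetry of the
  pair correlation matrix (4 distinct bivariate, 2 trivariate and 1
  quadrivariate integral per zygosity).
* **Optimization** uses `nlminb` with box constraints on paths and
  correlations, relative tolerance 1e-10 to 1e-12. Tetrachoric fits are
  initialized by a coarse profile over \(r\) at the margin thresholds
  (a cosine-approximation start alone can strand the optimizer when a
  concordance cell expectation is near zero). Bivariate ML fits start
  from the two-stage solution. Non-positive-definite candidate steps are
  rejected and counted (`n_rejected`).
* **Boundaries.** The correlation is kept inside \(|r| \le 1 - 10^{-6}\)
  (avoiding `log(0)`); estimates within that tolerance of 1 carry
  `at_boundary`. If the ACE optimum lands on \(c^2 = 0\), the AE
  solution (which is the constrained ACE maximum) is reported with
  `c2 = 0` and `boundary_c = TRUE` — published tables print 0, not a
  blank. Likelihood-ratio tests for boundary parameters use the plain
  chi-square reference, which is conservative; this matches common
  practice and is stated rather than corrected.
* **Confidence intervals** are profile-likelihood (the published
  intervals are asymmetric, consistent with likelihood-based intervals);
  outputs record the method.
* **Degenerate inputs.** Tables with an empty margin yield a flagged,
  undefined tetrachoric rather than an arbitrary number. Zero cells in
  the 16-cell tables are handled by the likelihood itself — no
  continuity corrections. One genuine information loss is documented:
  when an expected cell count underflows to zero in double precision
  (e.g. prevalence 0.012 with \(r = -0.9\)), the table no longer
  identifies \(r\) and the MLE is a boundary point; round-trip
  identities cannot hold there.

## The synthetic cohort generator

`simulate_cohort()` draws per-pair liabilities from correlated component
factors: additive-genetic factors shared with coefficient 1 (MZ) or 0.5
(DZ) between co-twins, shared environment fully shared, nonshared
environment twin-specific, with the cross-trait correlations
\(r_a, r_c, r_e\) applied inside each component. This is the
correlated-factors parameterization itself, so simulated cohorts have
exactly the covariance structure the models assume (the implied matrix
is also assembled independently and checked for positive
semi-definiteness before any sampling). Defaults mirror the reference
cohort design: 4,767 MZ and 5,580 same-sex DZ pairs, ages 9 and 12 in
the 8125:2222 ratio, equal sex ratio; opposite-sex DZ pairs are
generated only on request and only for descriptive tables, as in the
published design.

A-TAC items (17 autism, 19 ADHD; scored 0 / 0.5 / 1) are emitted by a
graded item model: item latent \(u = \lambda L + \sqrt{1-\lambda^2}\,
\varepsilon\), scored 0.5 above \(\tau_1\) and 1 above \(\tau_1 + g\).
The item model is the package's own device — only the scoring rule and
cutoffs (4.5 for autism, 6.0 for ADHD, inclusive) are externally fixed —
so \(\tau_1\) is calibrated deterministically (exact convolution of the
item-score distribution, integrated over the liability) to hit the
published population screen-positive rates of 3.6% and 10.5%. Defaults
\(\lambda = 0.7\) and \(g = 0.8\) encode a moderately reliable parent
interview item; they were chosen once as plausible and are not fitted.
Cross-trait \(r_c\) and \(r_e\) have no published values, so shipped
example configurations set \(r_c = 0\) and small \(r_e\) — arbitrary,
and labelled as such.

What the generator does **not** emulate: diagnostic misclassification
and registry under-ascertainment (the motivating data exclude primary
care), non-response, assortative mating, dominance, sex-limitation
(different paths by sex), age effects on liability, and item-level
dependence beyond the single common factor. Passing tests therefore
demonstrate internal statistical correctness of the estimators under the
liability model, not robustness to those real-data violations.

## Design choices on open points

* Subclinical groups **include** clinical cases by default; the
  sensitivity variant (`exclude_clinical`, or
  `apply_sensitivity_exclusion()`) removes them, matching the published
  sensitivity analysis. Missing A-TAC items make the module total
  missing and exclude the individual from subclinical classification
  (conservative listwise rule; the count is reported).
* Tetrachoric thresholds are estimated jointly with \(r\) by full ML —
  the convention of ordinal structural-equation software — rather than
  fixed at sample margins.
* The Bonferroni divisor defaults to 13, the number of outcome
  conditions, because \(0.05/13\) reproduces the published 0.0038
  threshold; it is configurable.
* The bivariate model re-estimates thresholds and per-trait paths
  jointly with the cross-trait parameters (rather than fixing them from
  univariate fits); the two-stage mode provides the fixed-stage
  alternative and serves as a cross-check and as the summary-statistics
  route.
* Model fits use single-entered tables (each pair once); double entry is
  used only for descriptive correlations, where it enforces
  order-invariance.

## Problem sizes in the test suite

The suite favours expected-table (noise-free) checks wherever a property
is deterministic, and uses simulated cohorts at sizes chosen to keep
Monte-Carlo error well below the asserted tolerances: 20,000 pairs per
zygosity (20 replicates per condition) for univariate recovery, 50,000
pairs per zygosity for bivariate genetic-correlation recovery, 200
replicates at 1,500 + 1,500 pairs for the boundary-LRT null calibration,
and 30 replicates for the family-wise-error check. Recovery of \(a^2\)
is asserted on the replicate mean (within 0.03): the per-replicate
absolute error at these sizes is dominated by sampling noise (standard
deviation up to ≈ 0.07 for a prevalence of 0.05), which no estimator can
remove; the script reports both the mean error and the raw MAE.

## Limitations

Estimates are only as identifiable as the design allows: C and D are
confounded; rare traits with extreme correlations can place the MLE on a
boundary; profile intervals for \(r_c\) and \(r_e\) are wide when the
corresponding paths are small. The GEE odds ratios are
population-averaged and not comparable to subject-specific conditional
odds ratios. Cross-twin correlations from double-entered tables use an
effective-N correction that is exact only under within-pair
exchangeability, which holds by construction in the simulated design.
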