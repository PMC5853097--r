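---
title: "Evaluating fatty acid panels as individual-level biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating fatty acid panels as individual-level biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fattyroc)
```

## The problem

A candidate diagnostic biomarker must separate affected from unaffected
*individuals*; a statistically significant difference in group means is not
enough, because it ignores the width and overlap of the two distributions.
`fattyroc` implements a complete evaluation pipeline for this question on
erythrocyte-membrane fatty acid panels in a case-control design (ASD cases
versus neurotypical, NEU, controls): 11 measured fatty acids expressed as
percent of total fatty acids, plus 4 derived measures (DHA/AA, EPA/AA,
n-3/n-6, total long-chain PUFA). Every stage runs on synthetic cohorts, so
the full pipeline is exercised and tested without any external download;
the same functions accept a real individual-level CSV through
`read_cohort_csv()`.

## Univariate testing: the gated decision tree

For each analyte, the comparison between cohorts is chosen by a
distribution-driven tree, with all gates at level $\alpha = 0.05$:

1. Each cohort is tested for normality with the Anderson–Darling case-3
   statistic (mean and variance estimated), using the small-sample
   correction $A^{*2} = A^2(1 + 0.75/n + 2.25/n^2)$ and the
   D'Agostino–Stephens piecewise-exponential p-value approximation.
2. If **both** cohorts look normal, an F test ($F = s_1^2/s_2^2$, two-sided)
   gates between the pooled-variance Student's t test and Welch's test
   (Welch–Satterthwaite df).
3. If **either** cohort rejects normality, the two-sample
   Kolmogorov–Smirnov test asks whether the two samples share a
   distributional *shape*. If shape is not rejected, the Mann–Whitney U
   test compares medians; otherwise Welch's test compares means, and the
   row is flagged, since a rank test is hard to interpret across shapes.

`select_and_test()` returns the full routing record so every decision is
auditable; `univariate_table()` applies the tree to all 15 analytes in the
canonical panel order and appends Bonferroni-adjusted (default; Holm
available) p-values via `multiplicity_correct()`.

The a priori sample size uses the normal approximation
$n = 2\left((z_{1-\alpha/2} + z_{\text{power}})/d\right)^2$ per group,
rounded to the nearest integer. With $d = 0.5$, $\alpha = 0.1$ and power
0.8 this gives $2(2.4865/0.5)^2 = 49.47 \to 49$ per group — the nearest-
integer convention is deliberate: a ceiling convention would print 50, and
the simulated power of a t test at $n = 49$ is ≈0.79, i.e. the returned
size sits exactly at the edge the approximation promises, which is how such
a priori calculations are conventionally quoted.

## Densities, intervals, and the C-statistic

Distributions are summarised by Gaussian-kernel density estimates with
Silverman's robust bandwidth $h = 0.9\,\min(s, \text{IQR}/1.34)\,n^{-1/5}$
on a 512-point grid spanning $[\min - 3h, \max + 3h]$. The "95% CI" columns
of the univariate table are equal-tailed 2.5–97.5% quantiles of the KDE's
CDF (trapezoidal integration, linear interpolation) — intervals of the
*distribution*, describing its spread, not confidence intervals on a mean.

Individual-level separation is the C-statistic, the area under the ROC
curve: the probability that a randomly chosen case scores above a randomly
chosen control. Two routes are provided and cross-checked:

* `pdf_integral`: $\int f_{\text{ASD}}(u)\,F_{\text{NEU}}(u)\,du$ on the
  merged KDE grids — mathematically identical to threshold-sweeping the ROC
  of two continuous densities, but numerically simpler;
* `empirical`: the distribution-free identity $U/(n_1 n_2)$ with ties
  counted one half, which is exactly invariant under monotone transforms.

Both are reported orientation-free as $\max(A, 1-A)$, so 0.5 means random
separation and 1 perfect separation regardless of the direction of the
shift. On smooth samples of $n \ge 50$ the two routes agree within about
0.02, which is the package's method-equivalence band; published two-digit
C-statistics are insensitive to the bandwidth variant.

## Multivariate classification and severity regression

`fda_fit()` is a two-class Fisher discriminant:
$w \propto (S_W + \lambda I)^{-1}(\bar{x}_{\text{ASD}} -
\bar{x}_{\text{NEU}})$ with $S_W$ the pooled within-class scatter.
Variables are standardized first — ratios near 0.02 and percentages near 25
live on very different scales; in exact arithmetic standardization leaves
the fitted direction's C-statistic unchanged while conditioning the solve
(ridge default $10^{-8}$ relative to the mean diagonal, a numerical
safeguard only). The discriminant scores are then treated exactly like a
univariate measurement: KDE score densities and a PDF-based C-statistic.
No cross-validation is applied by default because the quantity of interest
here is *fitting* performance — if the fitted classifier already separates
poorly, a cross-validated one will be worse; this asymmetry is the
package's reporting convention and is stated wherever the score
C-statistic is printed.

`pls_regress()` fits NIPALS PLS1 of an opaque severity score on the panel,
or kernel PLS on the double-centered Gram matrix (RBF $\gamma$ defaulting
to 1/median squared pairwise distance; 2 components by default). Two exact
reductions anchor the implementation: full components on full-rank
predictors reproduce least squares, and a linear kernel reproduces linear
PLS. Leave-one-out $R^2$ is available for honest out-of-sample reporting.

`seafood_correlation()` is Pearson by default, matching the
regression-onto-intake framing of the analysis it supports (Spearman as a
sensitivity option), pairwise-complete per analyte and group.

## The synthetic cohort generator

`generate_cohort()` draws from a Gaussian copula: correlated standard
normals (11 analyte dimensions plus one seafood dimension) are transformed
to lognormal (default — concentrations are positive and right-skewed) or
normal marginals with target mean and CV. Case means are shifted by
`cohens_d` × control SD *on the raw scale*, matching how group means are
conventionally reported; seafood meals per month are Poisson counts coupled
through the shared latent layer, so the achieved correlation with DHA/EPA
is verified empirically (Poisson discretisation and the lognormal transform
attenuate the latent correlation by roughly 10–20%).

`default_study_spec()` encodes the reference study conditions: 63 cases
and 49 controls, control means equal to the published panel's central
values (AA 20.16, DGLA 2.226, …, stearic 19.51% of total fatty acids), CVs
back-solved from the published 95% interval widths as
$\text{CV} = (q_{97.5} - q_{2.5})/(2 \times 1.96\,\mu)$, per-analyte
effect sizes back-solved from the case-control central-value gaps (largest:
DGLA $d \approx -0.45$, stearic $d \approx -0.42$ — a near-null panel), 8
Asperger's and 7 PDD-NOS subtype labels among the cases, and a seafood rate
of 4 meals/month (roughly weekly seafood, a realistic Western-diet figure;
the source analysis reports no intake distribution) with latent
correlations 0.40 to DHA and EPA, consistent with the reported
intake-composition correlations of 0.3–0.5.

Three caveats the generator does **not** model:

* **Compositional closure.** The 11 control central values sum to ≈99.8%
  of total fatty acids, so independent marginal draws matching those means
  necessarily straddle a row-sum of 100. The default copula gives the
  abundant saturates/MUFAs mild negative correlation (closure pushes large
  shares apart), which keeps most rows under 100, and `validate_cohort()`
  warns — rather than errors — on closure violations. Exact closure would
  require a constrained simplex sampler that distorts the very means and
  CVs the generator must reproduce; for testing the statistical pipeline,
  marginal fidelity is what matters.
* **Skew asymmetry of the intervals.** The CV back-solve treats the
  published brackets as symmetric. For strongly skewed analytes (EPA,
  palmitoleic — whose published control bracket appears to carry a
  transcription slip in its lower bound, 0.0147 where ≈0.147 is plausible)
  the implied CV is a first-order approximation; the panel spec accepts manual
  CV overrides. Derived checks use DGLA, whose bracket is nearly symmetric.
* **Covariate structure.** Age, gender and comorbidity matching are not
  modelled; cohort labels are exchangeable apart from the mean shifts.

Consequently, passing tests demonstrate that the *pipeline* recovers known
structure under realistic marginals and study sizes — not that real data
satisfy the generator's assumptions.

## Derived-measure composition

The four derived measures are pinned down by the published central values
they must reproduce: DHA/AA and EPA/AA are direct quotients; n-3/n-6 is
$(\text{DHA}+\text{EPA})/(\text{AA}+\text{DGLA}+\text{LA})$ — the control
central value ≈0.113 is only reproduced with LA in the denominator; total
PUFA is the *long-chain* (C20+) sum $\text{AA}+\text{DGLA}+\text{DHA}+
\text{EPA}$ — central values ≈26.5 are only reproduced with LA excluded
(including it would give ≈40). The asymmetry (LA counted in one derived
measure, not the other) is in the source data's own definitions, and is
documented on `compute_derived()`.

## Figure extraction

Many studies publish only scatter plots. `detect_markers()` recovers data
points from a raster: zero-mean normalized cross-correlation of a
user-selected marker patch against the image, local maxima at or above a
threshold (default 0.8, validated on synthetic renders), greedy non-maximum
suppression within a radius (default: template half-width), and sub-pixel
refinement by 1-D quadratic fits around each peak. `axis_calibration()`
maps pixels to data units by two anchors per axis (the y flip is absorbed
by a negative slope). Validation is by round trip on synthetic renders —
`render_scatter()` paints the same template at known positions — recovering
40/40 non-overlapping markers within one pixel. Markers overlapping within
the suppression radius merge into one detection; the original extraction
problem offers no ground truth to disambiguate them, so this is left as a
documented limitation rather than guessed at.

## Numerical choices and degenerate inputs

* Constant vectors are hard errors for AD, KDE and the F test (zero
  variance); ratios with zero denominators become `NA` with a warning,
  never silent zeros — the same policy as unparseable CSV cells.
* Mann–Whitney uses exact enumeration only for small tie-free fixtures
  ($n_1+n_2 \le 12$); at study sizes it uses the tie-corrected normal
  approximation with continuity correction. Two-digit p-values are robust
  to this choice.
* Missing values propagate and are excluded pairwise per analyte, so
  per-analyte n may differ; nothing is imputed.
* The trapezoid rule is used for all KDE integrals; fitted densities
  integrate to 1 within $10^{-3}$, enforced as a test invariant.

## Problem sizes used in the test-suite

Closed-form checks use $n = 2\times10^4$ (binormal C-statistic within
±0.01 of $\Phi(d/\sqrt2)$ at $d \in \{0, 0.5, 1\}$); type-I calibration
uses 1000 null cohorts of 63 + 49; generator recovery uses 500 replicate
cohorts at study size, recovering the DGLA control mean 2.226, the 8%
case deficit, and a PDF-based C-statistic of ≈0.62. These sizes give
Monte-Carlo error comfortably inside each asserted band while keeping the
default suite fast.

## Known limitations

* The PDF-route C-statistic inherits KDE boundary bias for sharply bounded
  data; the empirical route is exact and is always reported alongside.
* The AD p-value approximation is piecewise and accurate to roughly
  ±0.005 in the far tails, more than sufficient for 0.05 gates.
* The generator's seafood coupling targets the *latent* correlation;
  achieved raw-scale correlations run slightly lower (verified, not
  solved analytically).
* Axis calibration is manual (two anchors per axis); there is no automatic
  tick OCR.
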