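---
title: "Two-stage meta-analytic CFA of the TAS-20: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage meta-analytic CFA of the TAS-20: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacfa)
```

## The problem

The 20-item Toronto Alexithymia Scale (TAS-20) is the standard self-report
measure of alexithymia — difficulty identifying feelings (DIF), difficulty
describing feelings (DDF), and an externally oriented thinking style (EOT).
Its internal structure has been contested for decades: besides the intended
three-factor solution, the literature offers one- and two-factor
collapses, alternative three- and four-factor splits of EOT into
"pragmatic thinking" (PT) and "lack of importance of emotions" (IOE)
sub-facets, bifactor representations, a method factor for the five
reverse-worded items, and a correlated-trait–correlated-uniqueness (CTCU)
variant.

`metacfa` implements the two-stage meta-analytic structural equation
modelling (MASEM/TSSEM) workflow used to adjudicate between these models
on the pooled evidence of many primary studies, together with a synthetic
corpus generator so that every stage can be validated end to end without
any external data.

## Stage 1: fixed-effects pooling

Each primary-study sample contributes a 20×20 item correlation matrix:
either reported directly, or reconstructed from a reported factor solution
as the model-implied correlations \(\Lambda \Phi \Lambda^\top\) (off-diagonal
part; the diagonal is fixed at 1 because uniquenesses are not
re-estimated). When a source suppressed loadings below a reporting
threshold (typically .40), the censored cells are zero-imputed before
reconstruction — the established convention, which Monte-Carlo work has
shown to give approximately unbiased pooled patterns.

The unique correlations are pooled under a fixed-effects model as
sample-size-weighted means,
\(\bar r_{jk} = \sum_i n_i\, r_{ijk} / \sum_i n_i\).
The full ML formulation of fixed-effects pooling (a multigroup model with
equality constraints) converges to this closed form for correlation
inputs at the corpus sizes considered here; the closed form is chosen
because it is exactly testable (order invariance, split-merge
consistency) and transparent. Weighting uses \(n\) rather than \(n-1\);
at \(n \ge 99\) the difference is far below every tolerance used anywhere
in the package.

The stage-2 weight matrix is the normal-theory (delta-method,
Olkin–Siotani) asymptotic covariance of the 190 unique correlations,
evaluated **at the pooled matrix** and scaled by \(1/N\) with
\(N = \sum_i n_i\):
\[
N\,\mathrm{cov}(r_{ij}, r_{kl}) =
\tfrac12 \rho_{ij}\rho_{kl}\!\left(\rho_{ik}^2+\rho_{il}^2+\rho_{jk}^2+\rho_{jl}^2\right)
+ \rho_{ik}\rho_{jl} + \rho_{il}\rho_{jk}
- \rho_{ij}\!\left(\rho_{ik}\rho_{il}+\rho_{jk}\rho_{jl}\right)
- \rho_{kl}\!\left(\rho_{ik}\rho_{jk}+\rho_{il}\rho_{jl}\right),
\]
whose diagonal is the familiar \((1-\rho_{jk}^2)^2/N\). Evaluating at the
pooled values (rather than per study) keeps the weights consistent with
the point at which the stage-2 discrepancy is minimised. The exact
variant implemented is pinned by tests: closed forms for the independence
and single-pair cases, the \(1/N\) scaling law, and agreement with the
Monte-Carlo covariance of correlations of simulated multivariate-normal
data within three Monte-Carlo standard errors.

The 190 unique correlations are ordered row-major over the lower triangle
— (2,1), (3,1), (3,2), … — everywhere in the package
(`corr_pair_index()`).

Non-positive-definite input matrices (possible for reconstructed ones)
are accepted with a warning by default, because pooling across studies
restores definiteness in practice; `read_corpus(repair = TRUE)` instead
projects them to the nearest correlation matrix. All input correlations
are assumed computed on recoded items (higher = more alexithymic), so
reverse-keyed items correlate positively with their factor; the
`already_recoded` record flag documents this assumption per study.

## Stage 2: WLS confirmatory factor analysis

Each measurement model is fitted by minimising
\[
F(\theta) = \left(r - \rho(\theta)\right)^\top V^{-1} \left(r - \rho(\theta)\right)
\]
over the unique correlations, with \(V\) the asymptotic covariance above.
Because \(V\) carries \(1/N\), the minimised discrepancy is itself the
model \(\chi^2\); the AIC/BIC conventions \( \chi^2 - 2\,df\) and
\(\chi^2 - \ln(N)\,df\) and the RMSEA definition
\(\sqrt{\max(\chi^2-df,0)/(df\,(N-1))}\) reproduce the published
information-criterion and RMSEA cells of the TAS-20 meta-analysis from
its printed \(\chi^2\), \(df\), and \(N\) alone — the arithmetic anchor
that pins the scaling convention.

Identification is by unit-variance factors with all loadings free
(standardized solution); uniquenesses are implied by the correlation
metric, not free parameters, so \(df = 190 - (\text{free parameters})\).
The optimiser is BFGS with an analytic Jacobian of
\(\rho(\theta)\) and multi-start (default five starts: loadings .5,
factor correlations .3, residual terms 0, plus jittered copies under
fixed derived seeds). Convergence requires the largest gradient element
below \(10^{-6}\max(1, \chi^2)\); Heywood solutions (|loading| > 1 or
negative uniqueness) are flagged with a warning, never silently
accepted. The CFI denominator is floored at \(10^{-10}\) so a perfect
fit yields CFI = 1 rather than 0/0, and the RMSEA 90% interval is
obtained by inverting the noncentral-\(\chi^2\) CDF in the
noncentrality parameter by root search; when the inversion fails the
interval is flagged "not computable" instead of erroring.

Residual-correlation (CTCU) models free the ten pairwise residual terms
among the reverse-keyed items. Internally the free parameter is the
additive residual covariance on the correlation metric; reported
estimates are standardized by the two uniquenesses, which is the scale
on which residual correlations are conventionally discussed.

McDonald's \(\omega = (\sum\lambda)^2 / ((\sum\lambda)^2 + \sum\psi)\) is
computed per content factor from the standardized solution, with
\(\psi_i = 1 - \) communality.

### The model catalogue

The nine competing models ship as configuration plus structure:

| Name | Structure | df |
|------|-----------|----|
| 1  | one general alexithymia factor | 170 |
| 2  | DIF/DDF merged + EOT | 169 |
| 3a | DIF, DDF, EOT (standard scoring key) | 167 |
| 3b | DIF/DDF + PT + IOE | 167 |
| 3c | alternative DIF/DDF–EOT–IOE allocation | 167 |
| 4  | DIF, DDF, PT, IOE | 164 |
| 5  | bifactor: general + 3 orthogonal specifics | 150 |
| 6  | 3a + orthogonal method factor on the 5 reverse-keyed items | 162 |
| 7  | 3a + 10 free residual correlations (CTCU) | 157 |

The item lists live in `inst/extdata/tas20_models.yaml`, not in code. The
standard scoring key (DIF: 1,3,6,7,9,13,14; DDF: 2,4,11,12,17; EOT:
5,8,10,15,16,18,19,20; reverse-keyed 4,5,10,18,19) is uncontroversial;
the PT/IOE split (PT: 5,8,15,20; IOE: 10,16,18,19) and the 3c allocation
are taken from the four-factor literature and are configuration-only —
the published degrees of freedom, which the catalogue reproduces model
by model, are the decisive structural check, and they do not depend on
the exact split. A reference-factor bifactor variant with DDF as
reference (model 5b, df 155) is available behind
`build_catalog(include_5b = TRUE)`.

## Exploratory toolkit

Four factor-number criteria are computed on the pooled matrix: Velicer's
MAP test (average squared partial correlation after partialling m
principal components; the fourth-power variant is deliberately not the
default), Horn's parallel analysis (mean-eigenvalue rule over 100 seeded
replications of \(N \times 20\) standard-normal data; a 95th-percentile
rule is available), the sample-size-adjusted BIC
\(\chi^2_m - df_m \ln((N+2)/24)\) over ML exploratory solutions, and the
sequential exact-fit \(\chi^2\) test at \(\alpha = .05\) (smallest
non-significant m; the difference-test variant was considered and not
adopted because the exact-fit convention is the common default and the
criterion is reported jointly with three others anyway).

The bass-ackwards hierarchy extracts 1, 2, …, L varimax-rotated
principal-component solutions (PCA, not common factors — matching how
such hierarchies are conventionally displayed) and links adjacent levels
by component-score correlations. With regression weights
\(W_l = R^{-1}\Lambda_l\) the scores have exactly unit variance and zero
within-level correlation, so the cross-level correlations
\(W_l^\top R\, W_{l+1}\) are the only non-trivial structure; varimax
preserves the total communality at each level, and both properties are
asserted to numerical tolerance in the tests. Signs are fixed so each
component's largest-magnitude loading is positive, making results
deterministic. The conventional rendering thresholds (omit |r| < .30,
dash |r| < .50) are applied by `bass_ackwards_edges()` and are
configurable; the default depth is 4 levels, the depth at which the
DIF/DDF block finally separates.

## Measurement invariance

The invariance analysis is deliberately configural-only: groups
(languages with at least five samples, or clinical status) are pooled and
fitted **separately**, and standardized loadings are compared against a
reference group (default English) as
\(\Delta\lambda = \lambda_{\text{group}} - \lambda_{\text{reference}}\).
No equality-constrained simultaneous estimation is implemented — the
comparison of separately fitted standardized solutions is the analysis
this pipeline reproduces, and constrained invariance hierarchies are a
declared extension point. The fixed-effects consistency property (group
pools recombine exactly to the global pool) is tested, and the
clinical/nonclinical comparison runs through the identical machinery
with no special-casing.

## The synthetic corpus

The generator defines the study conditions; it is configuration, not a
tuning dial (`inst/extdata/tas20_population.yaml`):

* **Population structure**: three factors with correlations .77
  (DIF–DDF), .47 (DDF–EOT), .32 (DIF–EOT); loadings .62–.75 (DIF),
  .58–.68 (DDF), and .36–.58 (EOT, weakest for the reverse-keyed items) —
  the qualitative profile of the English version, with an optional
  residual-correlation overlay among the five reverse-keyed items for
  CTCU recovery studies.
* **Corpus composition**: k = 88 samples; 16 languages with counts
  34/8/7/6/5/5 for English/French/German/Farsi/Portuguese/Japanese and
  the published tail; 20 clinical samples; reporting mix 3 raw
  correlation matrices, 27 EFA patterns, 58 CFA patterns.
* **Sample sizes**: lognormal with median 327. The published minimum
  (99) and maximum (12,706) of 88 draws imply a log-scale spread between
  roughly 0.47 and 1.23 depending on which tail is matched; 0.8 is used
  as the compromise, with draws clamped at 99.
* **Reporting degradation**: EFA records are principal-axis solutions
  with promax rotation, censored at .40 (the factor correlation matrix
  travels with the pattern, as reconstruction requires); CFA records are
  three-factor WLS fits of the package's own engine to the sample
  matrix, reported in full. Data are multivariate normal — the pipeline
  pools Pearson correlations, and an ordinal/Likert generator would be a
  robustness extension, not a different analysis.
* **Cross-group perturbations**: translated versions receive +.14 on
  item 5 and −.11 on item 12 (the two item-level translation effects the
  invariance stage is designed to detect), applied additively to the
  primary loading.

What passing tests show — and what they do not: the generator emulates
sampling error, censored reporting, reporting-route heterogeneity, and
planted cross-group effects, so end-to-end tests demonstrate that the
estimators recover known structure under those conditions. It does not
emulate ordinal item scales, skewed response distributions, publication
bias, overlapping samples, or construct-level cultural differences, so
agreement on synthetic corpora is evidence about the estimators, not
about the TAS-20 itself.

Measured properties under the default conditions (regression-tested as
bounds, reported here as observations): an all-raw unperturbed corpus at
total N ≈ 30,000–40,000 recovers every loading and factor correlation
within ±.02 (typically ±.01) with CFI ≥ .99 and RMSEA ≤ .01; censoring
EFA patterns at .40 leaves the reconstruction correlating ≈ .93
elementwise with the sample matrix (RMS deviation ≈ .066 from the
uncensored reconstruction) because the weak EOT loadings fall below the
threshold, and the pooled three-factor fit then shows mean absolute
loading error below .06 while CFI stays above .95; a unidimensional fit
to a three-factor corpus loses at least .10 CFI relative to the
three-factor model.

## Problem sizes and numerical choices

The test suite and the acceptance script run the corpus-scale analyses at
the study conditions themselves (k = 88, total N in the tens of
thousands) — these are cheap because stage 2 operates on a 20×20 matrix
regardless of N. Replicated-bias studies use 50 corpora of k = 30;
Monte-Carlo validation of the asymptotic covariance uses 20,000
four-variable datasets of N = 2,000; the brute-force WLS oracle uses a
two-stage grid (coarse 0.05, then exhaustive 1e-3 within ±.06 of the
coarse optimum). Parallel analysis uses 100 replications by default.

Known limitations: no random-effects pooling (the fixed-effects model is
the analysis implemented; heterogeneity is addressed through per-group
refits), no corrections for unreliability or range restriction, no
modification indices or robust (mean-and-variance-adjusted) test
statistics, and raw-response ingestion is out of scope — raw-data
studies enter as precomputed correlation matrices.
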