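---
title: "Two-sample and two-step MR: models, choices and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and two-step MR: models, choices and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The causal model

Two-sample Mendelian randomization treats genetic variants as natural
randomization devices. A variant is a valid instrument for an exposure
when it (i) associates with the exposure, (ii) shares no confounder with
the exposure–outcome relationship, and (iii) affects the outcome only
through the exposure. Under these assumptions the per-variant Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect, and the
estimators in this package are different ways of pooling those ratios
with different robustness to assumption (iii):

* **IVW** pools with inverse outcome-variance weights — efficient, but
  biased by any net (directional) pleiotropy.
* **MR-Egger** frees the intercept; the slope stays consistent under
  directional pleiotropy provided instrument strength is independent of
  the pleiotropic effects, and the intercept's p-value is the pleiotropy
  test.
* The **weighted median** is consistent as long as more than half of the
  total weight comes from valid instruments.

Binary outcomes are handled on the log-odds scale throughout: odds ratios
are converted with `logor()` before any effect is combined, so "effects
add" is true by construction.

The two-step (mediation) layer runs the same machinery three times:
exposure→outcome with exposure instruments gives the total effect
$\beta_0$; exposure→mediator with the same instruments gives $\beta_1$;
mediator→outcome with the *mediator's* instruments gives $\beta_2$. The
product-of-coefficients decomposition is then

$$\text{indirect} = \beta_1\beta_2,\qquad
  \text{direct} = \beta_0 - \beta_1\beta_2,\qquad
  \text{proportion mediated} = \beta_1\beta_2/\beta_0 .$$

### Delta-method uncertainty

First-order propagation treating the three estimates as independent gives
$\mathrm{Var}(\beta_1\beta_2)=\beta_1^2\sigma_2^2+\beta_2^2\sigma_1^2$ and

$$\mathrm{Var}\!\left(\frac{\beta_1\beta_2}{\beta_0}\right)
 = \frac{\beta_1^2\sigma_2^2+\beta_2^2\sigma_1^2}{\beta_0^2}
 + \frac{(\beta_1\beta_2)^2\,\sigma_0^2}{\beta_0^4}.$$

The second term — the sampling variance of the total effect — matters: on
the published education/autoimmune rows shipped with the package, the
two-term formula reproduces the printed SE column (e.g. 0.2046 for the
cognitive-performance→income→psoriasis row) while the one-term version
gives ≈ 0.165. The covariance between $\beta_0$ and $\beta_1$ (estimated
from the same instruments) is ignored, which the printed numbers imply as
well; this is a recognised approximation, not an exact treatment.
Proportions outside $[0,1]$ are reported as computed — with a weak total
effect or opposing direct and indirect paths they are legitimate outcomes,
and truncating them would bias any downstream summary. When $\beta_0 = 0$
the proportion is undefined and returned as `NA` with a warning, while the
indirect effect is still reported.

All intervals use the fixed multiplier 1.96; `se_from_ci()` inverts the
same convention when only published odds-ratio intervals are available.

## Instrument selection and harmonization

Defaults mirror standard two-sample MR practice: significance threshold
$5\times10^{-8}$, greedy clumping with a 10,000 kb window and an LD $r^2$
threshold of 0.001, and removal of instruments already associated with
the outcome at $5\times10^{-8}$ (a conservative reading of the
exclusion-restriction assumption; the threshold is configurable).
Clumping is made deterministic by ordering on (p-value, variant ID); ties
in p-values therefore never make the result depend on input order.

Allele harmonization resolves orientation through the standard ladder —
exact match, swapped alleles (beta negated), strand complement,
complement-and-swap — and treats palindromic (A/T, C/G) variants
specially: letters cannot identify the strand, so a palindromic variant
is kept only when both allele frequencies sit on the same side of 0.5 and
outside $0.5\pm0.08$. The 0.08 window matches the default behaviour of
widely used MR harmonization workflows. Palindromic variants with a
missing frequency are dropped by default (configurable), and indels or
multi-allelic records are rejected at parse time — the methods here are
defined for biallelic SNPs.

Instrument strength uses $F=(R^2/K)/((1-R^2)/(N-K-1))$ with $N$ the
*smallest* per-variant sample size (conservative; GWAS meta-analyses have
variant-level N). Two per-variant $R^2$ estimators are exposed because
published summary statistics differ in what they provide: `z_n`
($z^2/(z^2+n-2)$, needs no allele frequency; the default) and `eaf_beta`
($2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$, valid for standardized
continuous traits).

## Numerical and algorithmic choices

* **Random-effects IVW** is multiplicative: the point estimate is the
  fixed-effect one and the SE is inflated by $\max(1,\sqrt{Q/(n-1)})$.
  This is the common default in two-sample MR software; additive random
  effects are not implemented.
* **Weighted median**: weights are the inverse first-order variances of
  the ratios, $\hat\beta_{Xj}^2/\sigma_{Yj}^2$; the median uses the
  midpoint convention (cumulative weight minus half the variant's own
  weight, linearly interpolated at 0.5). Exact ties in the ratio are
  pooled before interpolation, which makes the estimate exactly invariant
  to duplicating every instrument. The SE comes from a parametric
  bootstrap (default 1000 resamples) with an explicit seed; a fixed seed
  gives bit-identical results.
* **MR-PRESSO**: the global statistic is the sum of leave-one-out
  standardized squared residuals against the fixed-effect IVW fit; its
  null distribution is simulated (default 1000 draws) and the tail
  proportion carries a $1/(n_{\mathrm{sim}}+1)$ continuity correction, so
  p-values are never exactly zero. Outlier p-values are Bonferroni
  adjusted across instruments; the distortion test is out of scope. With
  1000 simulations the smallest attainable adjusted p is
  $n_{\mathrm{snp}}/1001$, so outlier detection needs
  $n_{\mathrm{sim}}$ comfortably above $20\,n_{\mathrm{snp}}$.
* **P-values** are two-sided normal (estimates) or chi-square (Q); no
  small-sample t correction, which is appropriate at the instrument
  counts this workflow targets (dozens to hundreds). All p-values are
  clamped into $(0,1]$; missing p-value columns are imputed from
  $|\beta/\sigma|$.
* **Egger orientation**: pairs are flipped so exposure betas are
  non-negative before fitting; the fit is invariant to flipping both
  signs of any pair.

## What the simulator emulates — and what it does not

`simulate_sumstats()` draws summary statistics directly from their
theoretical sampling distributions under a linear structural model
instrument→exposure→(mediator→)outcome, which is exactly the setting
two-sample MR theory assumes. Defaults are chosen to resemble a
consortium-scale education/disease analysis shrunk to desk scale: 100
exposure instruments each explaining 0.1% of exposure variance, 100
mediator-specific instruments, 50 null variants, GWAS sizes 50,000 /
30,000 / 30,000, a binary outcome with 10% cases (outcome SEs scale with
$\sqrt{\mathrm{cf}(1-\mathrm{cf})}$), minor-allele frequencies uniform on
(0.05, 0.5), and generating effects $\beta_1=0.41$, $\beta_2=-0.60$,
direct $=-0.13$ — a total effect of $-0.376$ with about 65% mediated,
matching the magnitude of a strong income-type mediation signal.
Mediator-specific instruments are drawn at the same expected chi-square
as exposure instruments so that significance selection behaves alike in
both GWAS. Instrument effects have fixed magnitude and random sign, which
pins the per-variant variance explained exactly.

Pleiotropy is available as `balanced` (mean-zero direct outcome effects)
or `directional` (mean shift equal to `pleiotropy_sd`); a configurable
fraction of exposure instruments can additionally be invalid through a
direct mediator effect. LD is block-constant $r^2$ over consecutive
blocks, which is enough to exercise clumping but is *not* a realistic LD
landscape. Other simplifications: no sample overlap between the two
samples, no population stratification, no allele-frequency error, no
strand misassignment, and summary statistics are exactly normal. Passing
tests on these data therefore validate the estimators and plumbing under
the model's own assumptions; they cannot certify behaviour under
real-data pathologies such as stratification or overlapping samples.

## Problem sizes used by the test suite

The stochastic calibration suite runs at 100 instruments with 500
replicates for estimator recovery and IVW coverage, 1000 replicates for
the Egger intercept type-I error, 60 replicates for the weighted-median
contamination check, 500 for the Cochran's Q distributional check, and
300 pipeline replicates for the end-to-end bias bound — sizes at which
Monte-Carlo error is small relative to the tested tolerances while the
whole suite stays fast on a single CPU. Acceptance checks against the
published education/autoimmune rows are exact table arithmetic and run in
milliseconds.

## Known limitations

* No multivariable MR: the direct effect is $\beta_0-\beta_1\beta_2$, not
  a multivariable-adjusted estimate, so exposure-associated instruments
  in the mediator→outcome leg are not excluded by default (configurable).
* No Steiger filtering, proxy-SNP lookup, VCF input or liftover.
* The weighted-median bootstrap resamples betas independently per
  instrument; correlated instruments (imperfect clumping) would make its
  SE optimistic.
* MR-Egger retains its usual caveats: low power, sensitivity to influence
  points, and reliance on the instrument-strength-independent-of-direct
  -effects assumption.
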