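---
title: "Fitness-related white matter covariance patterns with the Scaled Subprofile Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-related white matter covariance patterns with the Scaled Subprofile Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aerobic fitness in older adults is associated with the microstructural
integrity of cerebral white matter. Tractography pipelines summarise each
participant's diffusion MRI as one scalar per white matter bundle and per
metric — axial (AD), radial (RD) and mean (MD) diffusivity in mm²/s, and
fractional anisotropy (FA, dimensionless) — typically over 42 bundles.
Relating fitness to each tract separately ignores that white matter ages as
a coordinated system: individual differences express themselves as
*covariance patterns* spanning many tracts. `ssmfit` implements the Scaled
Subprofile Model (SSM), a PCA-based multivariate technique developed in the
neuroimaging literature for exactly this setting, and couples it to a
fitness covariate, maximal oxygen consumption (VO~2~max, ml/kg/min).

## The model

Let $M$ be the $n \times p$ matrix of one metric (participants × tracts),
strictly positive. The SSM preprocessing is

$$C_{ij} = \ln M_{ij} - \overline{\ln M}_{i\cdot} - \overline{\ln M}_{\cdot j}
          + \overline{\ln M}_{\cdot\cdot},$$

i.e. a natural log transform followed by double mean-centering. On the log
scale, a global multiplicative factor per participant (head size, scanner
gain, hydration) is an additive row effect, and the group's mean regional
profile is an additive column effect; double-centering annihilates both
exactly, leaving only the participant-by-tract interaction. `ssmfit`
verifies this algebraically: multiplying any row of $M$ by any positive
constant leaves $C$ unchanged to machine precision.

$C$ is then decomposed by SVD into orthonormal tract loading vectors
$v_1, v_2, \dots$ (the regional covariance pattern components) and subject
scores $s_{ic}$ (the degree to which participant $i$ expresses component
$c$), with eigenvalues $\lambda_c = d_c^2/(n-1)$ equal to the score
variances. After double-centering the rank is at most $\min(n-1, p-1)$.

**Component selection.** The number $k$ of leading components whose linear
combination best predicts VO~2~max is chosen by the Bayesian Information
Criterion over *nested leading* sets $\{1\}, \{1,2\}, \dots$:

$$\mathrm{BIC}(k) = n \ln(\mathrm{RSS}_k / n) + (k+1)\ln n,$$

where $\mathrm{RSS}_k$ is the residual sum of squares of the OLS fit of
VO~2~max on score columns $1..k$ with intercept, and the $k+1$ counts the
intercept. Ties break toward smaller $k$. Restricting to nested leading
sets keeps the search space one-dimensional and favours high-variance,
reproducible components; BIC's $\ln n$ penalty makes the selection
conservative relative to AIC.

**Combined pattern.** With OLS coefficients $b_1..b_k$, the combined
pattern has per-tract loadings $w = \sum_c b_c v_c$ and per-participant
expression $e_i = \sum_c b_c s_{ic}$. Expression is z-scored and the pair
$(w, e)$ is negated if needed so that expression correlates positively
with VO~2~max — higher expression always means the fitness-associated
direction. For this single combined predictor the standardized $\beta$
equals the Pearson correlation and
$R^2_{\mathrm{adj}} = 1 - (1-\beta^2)(n-1)/(n-2)$; both are reported,
along with the same association after adjusting for total intracranial
volume (TIV) in a two-block regression (standardized $\beta$ of expression
in the full model, and the adjusted-$R^2$ change over the TIV-only model).

**Bootstrap reliability.** Tract-level reliability of $w$ comes from
resampling participants with replacement (default 10,000 iterations) and
rerunning the entire derivation — centering, PCA, combination — with $k$
*frozen* at the full-sample selection. Freezing $k$ targets the question
"how stable are the loadings of the observed pattern?"; re-selecting per
replicate would mix model-selection variance into the intervals. Because
PCA loadings are identified only up to sign, each replicate vector is
negated when its correlation with the full-sample $w$ is negative before
percentile intervals (2.5th/97.5th) are formed. A tract is flagged
significant when its interval excludes zero. Replicates whose
decomposition drops below rank $k$ are discarded and counted; more than 1%
of them triggers a warning. Bias-corrected accelerated (BCa) intervals are
available behind `type = "bca"`; percentile is the default. Procrustes
alignment of the whole component subspace would be an alternative to
single-vector sign alignment, but the object of interest here is one
combined vector, so the simpler rule is used.

**Follow-up statistics.** Univariate per-tract simple regressions of the
log metric on VO~2~max (standardized $\beta$, t-based slope CI) are
corrected with the Benjamini–Hochberg step-up procedure; the FDR family is
the tested subset, by default the bootstrap-significant tracts. Block-wise
hierarchical regressions of pattern expression on covariates proceed
through TIV; + age, sex; + high vascular risk level, APOE ε4 carriage;
+ log WMH volume, reporting standardized (all predictors z-scored, binary
ones included — the SPSS convention) and unstandardized coefficients,
adjusted $R^2$ and the model F per block. Rows missing any predictor of
the largest block are dropped from *all* blocks so $R^2$ changes compare a
common sample.

## Quality control

Before any modelling, a cell (participant × tract × metric) is flagged
when its raw value lies outside $[Q_1 - 3\,\mathrm{IQR},\;
Q_3 + 3\,\mathrm{IQR}]$ of that tract's cross-participant distribution for
that metric. A participant is excluded when two or more metrics are
flagged on the same tract, or one metric is flagged on two or more tracts.
Two details are deliberate and documented because flags at the margin
depend on them: quartiles use the linear-interpolation definition
(`quantile` type 7), and the quartile scope is per tract per metric across
participants (a pooled per-metric scope is available via `qc_scope`).
Missing cells after QC are a hard error — the analysis assumes complete
data after exclusions, and no imputation is attempted.

Note that on right-skewed raw diffusivities the upper 3-IQR fence is
closer, in SD units of the log scale, than the Gaussian intuition of
~4.7 SD suggests; sporadic chance flags on clean data are therefore
expected at cohort scale (real tractography cohorts likewise lose a few
participants to this rule), and only coincident flags exclude anyone.

## The synthetic cohort generator

No tract-level cohort is shipped with the package; validation runs on
simulated cohorts with known ground truth, generated by
`simulate_cohort()` from a `ground_truth()` object. On the log
scale of each metric,

$$\ln M_{ij} = \ln b_j + g_i + \sum_{c=1}^{k_{\mathrm{true}}} s_{ic} v_c[j]
               + \varepsilon_{ij},$$

with $b$ a strictly positive baseline regional profile (defaults in native
units: AD 1.2×10⁻³, RD 5.5×10⁻⁴, MD 7.5×10⁻⁴ mm²/s, FA 0.45, with ±20%
smooth regional variation), $g_i \sim N(0, 0.1^2)$ the global subject
scaling factor the double-centering exists to remove, $v_1$ the planted
unit-norm pattern, and $\varepsilon$ i.i.d. tract noise. The defaults are
the package's reference study conditions: $n = 167$ participants aged
50–88, 42 tracts with TRACULA-style labels, and VO~2~max built as
$\mathrm{ss}\cdot u + \sqrt{1-\mathrm{ss}^2}\,z$ (population mean 24.43,
SD 5.40 ml/kg/min) so that its expected correlation with the combined
component driver $u$ is exactly the configured `signal_strength`
(default 0.7).

Choices worth stating explicitly:

* **Noise scale.** The per-cell SD of the planted signal is
  $\sqrt{\mathrm{mean}(v_j^2)} = 1/\sqrt{p}$ (≈0.154 at $p=42$). The
  default `noise_sd` is half that (≈0.077, i.e. ~8% tract-level noise on
  the log scale) — the strongest noise at which the planted pattern
  remains reliably recoverable, and a realistic dispersion for
  tract-averaged metrics.
* **Component spectrum.** Additional planted components
  ($v_2..v_{k_{\mathrm{true}}}$, drawn orthonormal to $v_1$ by
  Gram–Schmidt) receive geometrically decaying expression variances
  (ratio 0.7). An exactly degenerate spectrum would make the sample
  principal components an arbitrary rotation of the planted ones and the
  notion of "the first $k$ components" meaningless; a decaying spectrum
  keeps the order identifiable while the VO~2~max driver still weights the
  standardized expressions equally.
* **Covariates.** Age is uniform on 50–88 (population SD 10.97 y); sex,
  APOE ε4 and five vascular risk indicators are independent Bernoulli
  draws with prevalences matching a community cohort of older adults
  (e.g. hypertension 55/167, smoking history 66/167); high vascular risk
  is *derived* as ≥2 positive indicators, giving an implied prevalence of
  0.367 under independence. WMH volume is log-normal; TIV is normal with
  a male offset, which makes TIV–sex correlation available to the
  block-wise models. Standardized covariate effects (defaults: age −0.5,
  male sex +0.15, high vascular risk −0.15, log WMH −0.25, APOE 0) enter
  the planted expression additively, with the residual scaled so the
  expression has unit population variance — the configured effects *are*
  the population standardized coefficients.
* **What is not emulated.** No spatial structure within tracts, no
  between-tract residual correlation beyond the planted patterns (an
  exchangeable `residual_cor` parameter exists but defaults to 0 — a
  choice, not an empirical fact), no missingness, and no realistic
  tail behaviour of tractography failures. Passing recovery tests on
  these cohorts therefore demonstrates correctness of the estimator under
  its own assumptions, not robustness to everything real data can do.

## Numerical choices

PCA is computed by SVD of the centered data matrix rather than an
eigendecomposition of the covariance matrix (stability; the
eigendecomposition is retained as the test oracle). Rank is determined at
relative tolerance 1e−10 of the leading singular value. Component signs
at the decomposition layer follow "largest-magnitude loading entry
positive"; the fitness-facing sign of the combined pattern is fixed
afterwards. An all-zero centered matrix yields an empty decomposition,
not an error. In the bootstrap's inner loop the OLS coefficients use the
exact orthogonality of score columns (scalar projections), which is
algebraically identical to the full regression. Perfect fits in the
block-wise models are flagged (`F = Inf`) rather than raised as errors;
rank-deficient designs are rejected naming the collinear columns;
collinearity of TIV with expression beyond 1−1e−10 degrades gracefully to
a warning with `NA` inferential statistics.

All randomness is seeded: cohorts, bootstraps and the pipeline are
byte-reproducible given their seeds, and the pipeline splits one root seed
deterministically per metric and stage. Simulation routines restore the
caller's RNG state.

## Validation scale

The shipped validation suite exercises the estimator at the reference
cohort scale ($n = 167$, 42 tracts): planted-pattern recovery over 100
simulated cohorts, component-count selection over 200, bootstrap coverage
of population loadings (from one $n = 50{,}000$ reference run) over 200
cohorts with 1,000 inner resamples, FDR behaviour under the global null
over 500 cohorts, and covariate-effect recovery at $n = 2000$. These
sizes were chosen to give stable Monte-Carlo estimates of each operating
characteristic while keeping the full suite comfortably rerunnable.

## Limitations

The forward-scoring utility (`predict()` on new participants) applies a
frozen pattern using the training centering profile; it is exposed for
prospective use but not validated against an external cohort. No
permutation test of whole-pattern significance is provided. The
univariate follow-ups are unadjusted simple regressions on the log scale
(both choices configurable), and the FDR family defaults to the
bootstrap-significant subset — analysts testing all tracts should pass
the full label set explicitly.
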