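# ssmfit

Scaled Subprofile Model (SSM) analysis of tract-level white matter
diffusion metrics in relation to cardiorespiratory fitness.

Tractography pipelines reduce a diffusion MRI scan to one scalar per
white matter bundle per metric — axial, radial and mean diffusivity (AD,
RD, MD, mm²/s) and fractional anisotropy (FA) over ~42 bundles. White
matter ages as a coordinated system, so `ssmfit` models *regional
covariance patterns* rather than isolated tracts: it is written for
researchers in brain aging and exercise physiology who have a
participants × tracts table per metric and a fitness covariate
(VO₂max, ml/kg/min), and want the multivariate pattern of white matter
integrity that tracks fitness, with honest reliability estimates.

## The method

For a strictly positive participants × tracts matrix `M`:

1. **Log + double-centering.** `C = ln M` minus row means, column means,
   plus the grand mean. This removes each participant's global scaling
   factor and the group's mean regional profile exactly, leaving the
   participant-by-tract interaction.
2. **PCA.** `C = S Vᵀ` by SVD: orthonormal tract loading vectors
   (covariance pattern components) and per-participant subject scores.
3. **BIC selection.** The number `k` of *leading* components whose linear
   combination best predicts VO₂max minimizes
   `BIC(k) = n·ln(RSS_k/n) + (k+1)·ln n` over nested candidate sets
   `{1}, {1,2}, …`.
4. **Combined pattern.** Loadings `w = Σ b_c v_c` and z-scored expression
   scores, oriented so higher expression ↔ higher fitness; standardized β,
   adjusted R², and the same association after adjusting for total
   intracranial volume.
5. **Bootstrap reliability.** Participants are resampled (default 10,000
   iterations) and the whole derivation is rerun with `k` frozen;
   sign-aligned percentile CIs flag the tracts that reliably contribute.
6. **Follow-ups.** Benjamini–Hochberg-corrected univariate tract
   regressions, and 4-block hierarchical regressions of pattern
   expression on TIV; age and sex; vascular risk and APOE ε4; and log WMH
   volume.

A 3-IQR quality-control step (per tract, per metric) with the two
standard exclusion rules precedes modelling, and a synthetic cohort
generator with planted patterns and known ground truth backs the test
suite. See the vignette (`vignettes/ssm-white-matter-patterns.Rmd`) for
the full model description and design rationale.

## Worked example

```r
library(ssmfit)

truth  <- ground_truth(42, seed = 7)            # planted pattern, effects
cohort <- simulate_cohort(167, 42, truth)       # 167 participants, 4 metrics

fit <- ssm_fit(cohort$metrics$RD, cohort$covariates$vo2max, metric = "RD")
fit
#> SSM covariance pattern fit (RD)
#>    167 participants x 42 tracts; 41 components
#>   BIC-selected k = 1
#>   expression ~ VO2max: beta = 0.653, adj. R2 = 0.424, p = 1.05e-21

boot <- ssm_bootstrap(fit, n_iterations = 2000, seed = 8)
boot
#> SSM bootstrap reliability (percentile CIs, level 0.95)
#>    2000 iterations, 167 participants, k = 1
#>   significant tracts: 38 of 42

tiv_adjusted_fit(fit, cohort$covariates$vo2max, cohort$covariates$tiv)
#> beta = 0.657, adjusted R2 change = 0.427

abs(cosine_similarity(coef(fit), truth$planted_loadings))
#> 0.966   # the planted loading vector is recovered
```

The fit says: one component suffices (the generator planted one), its
expression explains 42% of VO₂max variance in this cohort (β = 0.65,
i.e. the simulated signal strength 0.7 less sampling noise), 38 of 42
tract loadings are reliably nonzero, the association survives head-size
adjustment, and the estimated pattern is within 15° of the planted one.
`plot(boot)` draws the loading bar chart with CI whiskers;
`blockwise_regression(fit$expression, cohort$covariates)` runs the
covariate blocks; `run_ssm_pipeline(config)` executes everything for all
four metrics from delimited text files and writes per-metric reports plus
a manifest.

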