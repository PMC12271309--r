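# segqa — technical validation of multi-class abdominal tissue segmentations

Automated fat and muscle segmentation of abdominal MRI promises objective
monitoring of cachexia and sarcopaenia in oncology, but a segmentation
model is only a usable biomarker source if three questions are answered
quantitatively: how **accurate** is it against expert consensus, how
**repeatable** are its derived tissue volumes under test–retest imaging,
and how large must a **longitudinal change** be before it exceeds
measurement noise? `segqa` implements this validation pipeline for the
six-class abdominal labelling (0 background, 1 cavity-excluded, 2
subcutaneous fat SF, 3 visceral fat VF, 4 psoas muscle PM, 5 external
muscle EM; total fat TF = SF+VF, total muscle TM = PM+EM) and ships a
synthetic phantom/cohort generator so every statistic can be exercised
against known ground truth.

The statistical core:

* **Accuracy** — class-wise DSC, IoU (`IoU = DSC/(2−DSC)`), 95th-percentile
  Hausdorff distance and normalised surface Dice (tolerance τ, default
  2 mm), computed on an exact anisotropic Euclidean distance transform;
  reference-weighted means over foreground classes.
* **Consensus** — STAPLE expectation–maximisation over multiple raters
  (per-voxel consensus weight `W_i = a_i/(a_i + b_i)` from rater
  sensitivities/specificities), extended one-vs-rest to the 6-class
  scheme, with reader-study ranking against the consensus.
* **Ensembles & post-processing** — probability averaging and hard-label
  voting, the canonical 15 configurations of 4 base models, and
  largest-26-connected-component cleanup.
* **Repeatability** — within-subject coefficient of variation
  `wCV = 100·sqrt(mean((x₁−x₂)²/2m²))`, one-way random-effects ICC(1,1),
  and asymmetric log-scale limits of agreement
  `100·(exp(±1.96·√2·σ_w)−1)`, stratifiable by gender or architecture.
* **Bias model** — a hierarchical Bayesian model of per-slice area
  differences, `δ_nm = α + β(a_n − ā) + u_m + ε_nm` with
  `u_m ~ N(0, σ²_inter)`, `ε_nm ~ N(0, σ²_intra)`, fitted by the
  package's Hamiltonian Monte Carlo sampler (3 chains × 1500 draws after
  500 warmup by default) with split Gelman–Rubin diagnostics
  (convergence bar r̂ < 1.1), posterior predictive bands and
  `ICC = σ²_intra/(σ²_intra + σ²_inter)`.
* **Longitudinal change** — percent change against the averaged double
  baseline, classified against repeatability-coefficient limits (strict
  exceedance; 95% confidence), plus cohort-level paired t-tests and
  gender group comparisons.

## Worked example

```r
library(segqa)

## synthetic ground truth and five imperfect raters
ph <- make_phantom()
raters <- lapply(1:5, function(s)
  corrupt_segmentation(ph, corruption_spec(displacement_mm = 1.5, seed = s)))
names(raters) <- sprintf("H%d", 1:5)

## STAPLE consensus + ranking
rs <- reader_study(raters)
rs$table[, c("id", "dsc_2", "dsc_3", "weighted_dsc", "rank")]
#>   id dsc_2 dsc_3 weighted_dsc rank
#> 1 H1 0.940 0.897        0.922    1
#> 2 H2 0.901 0.921        0.910    2
#> 3 H3 0.915 0.913        0.898    3
#> 4 H4 0.891 0.899        0.879    4
#> 5 H5 0.885 0.859        0.859    5

## test-retest repeatability of a simulated 49-patient double-baseline cohort
tab <- simulate_cohort(cohort_spec(seed = 7))
r <- stratified_repeatability(tab)
r[, c("class", "n", "wcv_pct", "icc", "loa_lower_pct", "loa_upper_pct")]
#>   class  n wcv_pct   icc loa_lower_pct loa_upper_pct
#> 1    SF 49    3.74 0.997         -9.84         10.92
#> 2    VF 49   10.73 0.956        -25.85         34.87
#> 3    PM 49    2.75 0.988         -7.34          7.93
#> 4    EM 49    1.65 0.996         -4.48          4.69

## hierarchical bias model by HMC
obs <- simulate_bias_observations(bias_sim_spec(seed = 1))
fit <- fit_bias_model(obs, seed = 1)
fit
#> <bias_fit> 375 obs (25 slices x 15 models), 3 chains x 1500 draws (+500 warmup)
#> max split-rhat 1.001 (converged); mean acceptance 0.95
#>    parameter     mean ci_lower ci_upper   rhat
#>        alpha -5.03446 -5.73947 -4.32891 1.0013
#>         beta -0.05277 -0.06129 -0.04441 0.9995
#>  sigma_inter  1.12592  0.50471  1.93131 1.0001
#>  sigma_intra  3.91625  3.64963  4.22237 0.9994
#>          icc  0.91825  0.79938  0.98400     NA
#>     bias_pct -3.87959 -4.42287 -3.33589     NA
```

Reading the outputs: per-rater rows are sorted by agreement with the
STAPLE consensus (weighted mean DSC over foreground classes). The
repeatability table shows visceral fat as the least repeatable tissue
(wCV ≈ 11%, limits −26%/+35%): an individual patient's VF change must
exceed those limits before it is a real change at 95% confidence. The
bias-model fit recovers the generating parameters (α = −5, β = −0.05,
σ_inter = 1.5, σ_intra = 4) within its 95% credible intervals, and the
high ICC says models differ from each other far less than their residual
slice-to-slice error.

See `vignettes/segqa-methods.Rmd` for the full model descriptions,
conventions, parameter defaults and limitations.

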