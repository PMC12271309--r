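---
title: "Validating automated abdominal tissue segmentations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated abdominal tissue segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segqa)
```

## Scope

`segqa` provides the statistical machinery for the technical validation of
multi-class fat/muscle segmentations of abdominal MRI: accuracy against a
multi-rater consensus, ensemble combination and post-processing, a
hierarchical Bayesian model of segmentation bias, test-retest repeatability
of the derived tissue volumes, and classification of longitudinal change
against repeatability thresholds. Because clinical MRI and trained networks
cannot ship with a package, a synthetic phantom and cohort generator supply
fully specified inputs whose ground truth is known; every statistical claim
in the test suite is made against that known truth.

The fixed label scheme is 0 background, 1 cavity-excluded, 2 subcutaneous
fat (SF), 3 visceral fat (VF), 4 psoas muscle (PM), 5 external muscle (EM).
Total fat TF = SF + VF and total muscle TM = PM + EM are always derived,
never stored. Volumes are voxel counts times the voxel volume, reported in
mL; all geometry is in mm.

## Accuracy metrics

For each class, one-vs-rest masks are compared with:

* **DSC** `2|A∩B|/(|A|+|B|)` and **IoU** `|A∩B|/|A∪B|`, which satisfy
  `IoU = DSC/(2−DSC)` identically — the suite checks this to 1e-12.
* **HD95**: the 95th percentile (linear interpolation, `quantile` type 7)
  of the pooled bidirectional surface distances. A surface voxel is a
  foreground voxel with at least one face-adjacent (6-connectivity)
  background neighbour; distances are Euclidean between surface-voxel
  centres, scaled by the spacing. Pooling both directions makes the metric
  symmetric; the max-of-directed-percentiles variant is available via
  `convention = "max_directed"`.
* **NSD** at tolerance τ (default 2 mm, configurable): the fraction of the
  combined surface within τ of the other surface.

Conventions for degenerate masks: both empty gives DSC/IoU/NSD = 1 and
HD95 = 0 with a `both_empty` flag; one empty gives DSC/IoU/NSD = 0 and
HD95 = `NA` (undefined). The weighted mean DSC weights classes by the
reference voxel count of the foreground classes 1–5; background is
excluded. Both the τ default and the weight convention are reported in the
output so downstream users can see exactly what was computed. Aggregation
over test subjects is an unweighted mean.

Correctness is anchored to an independent brute-force oracle (full pairwise
distance matrices computed by direct definition) on random small masks;
implementation and oracle agree exactly.

## STAPLE consensus

`staple_binary()` is the classic EM estimator of a probabilistic consensus
plus per-rater sensitivity p and specificity q. The E-step weights each
voxel by the likelihood of the rater decisions under (p, q) and the prior
foreground probability π; the M-step re-estimates (p, q) from the weights.
Defaults: π = the empirical foreground fraction of the rater average,
initial p = q = 1 − 1e-5, tolerance 1e-6 on max |ΔW|, 100 iterations. The
EM log-likelihood trace is retained and tested to be non-decreasing.

Multi-class consensus runs the binary estimator one-vs-rest for classes
1–5 and assigns the argmax weight, background when all weights fall below
0.5, with exact ties broken to the lowest class index. This per-class
dialect matches how the accuracy analysis is reported (class-wise DSC);
a full confusion-matrix multi-label STAPLE is out of scope.

Two caveats worth knowing. All-foreground or all-background stacks are
degenerate for EM, so the estimator warns and falls back to majority
voting. And on very small stacks (a handful of voxels) the re-estimated
(p, q) can deviate from the majority rule in ways that are statistically
consistent but surprising; the clean theoretical statement — symmetric
raters (p = q) and π = 0.5 reduce the consensus to exact majority voting —
holds for the E-step and is verified exhaustively over all 3-rater,
4-voxel stacks.

## Ensembles and post-processing

Probability averaging takes the argmax of channel-wise means; voting takes
the per-voxel modal label; both resolve exact ties to the lowest class
index so results are deterministic and order-invariant. From four base
segmentation models, `enumerate_ensembles()` produces the canonical 15
configurations (4 singletons, 6 pairs, 4 triples, 1 quadruple) in
lexicographic order. Post-processing keeps the largest 26-connected
component of the union of foreground classes — computed by a
frontier-vectorised flood fill — so stray islands of any class (e.g. arms
labelled outside the abdominal region) are removed while labels inside the
main body are untouched. Connectivity and the union-of-classes reading are
package choices; per-class post-processing would behave differently on
touching structures.

## Test-retest repeatability

From double-baseline volume pairs:

* **wCV** uses the squared-relative-difference estimator
  `100·sqrt(mean((x1−x2)^2 / (2 m^2)))`, m the pair mean.
* **ICC** is the one-way random-effects ICC(1,1) for two interchangeable
  replicates, `(MSB − MSW)/(MSB + MSW)`.
* **Asymmetric LOA** work on the log scale: within-subject SD
  `σ_w = sqrt(Σ(ln x1 − ln x2)^2 / 2n)`, repeatability coefficient
  `RC = 1.96·√2·σ_w`, limits `100·(exp(±RC) − 1)`. These limits are
  reciprocal-symmetric — `(1 + U/100)(1 + L/100) = 1` — which is the
  natural behaviour for a multiplicative (log-normal) error model and the
  reason the upper limit is always larger in magnitude than the lower.

The wCV and log-scale estimators agree to first order for small CVs; the
log-scale route is used for the limits because reciprocal symmetry is what
published test-retest limit pairs display. The ICC variant (one-way random
effects) is a package choice recorded in its documentation; two-way forms
differ only in how systematic visit effects are treated, which a
double-baseline design does not identify well.

Stratified analysis (`stratified_repeatability()`) computes all three per
tissue class within strata such as gender; strata with fewer than two
complete pairs are skipped with a warning.

## Hierarchical bias model

For slice n with consensus area `a_n` and model m, the difference
`δ_nm = A_nm − a_n` is modelled as

```
δ_nm = α + β (a_n − ā) + u_m + ε_nm
u_m ~ Normal(0, σ_inter²),  ε_nm ~ Normal(0, σ_intra²)
```

Centering at the mean area ā makes α the bias at the mean area (also
reported as a percentage, 100·α/ā). β captures the linear dependence of
bias on the reference area. The intraclass correlation is defined as
σ_intra²/(σ_intra² + σ_inter²): values well above 0.5 mean the models
behave similarly to one another (between-model spread small relative to
residual spread). Priors are weakly informative and scale-adaptive —
α, β ~ Normal(0, (10·sd(δ))²), half-Normal(5·sd(δ)) on both SDs — with a
non-centred parameterisation of u_m.

Inference is by the package's own Hamiltonian Monte Carlo sampler: static
trajectories with jittered path length, dual-averaging step-size
adaptation (target acceptance 0.95) and a diagonal mass matrix estimated
from a warmup window. Defaults are 3 chains × 1500 retained draws after
500 warmup iterations, no thinning — warmup and retained counts are
configured separately. Convergence is monitored with the split-chain
Gelman-Rubin statistic on all natural-scale parameters (α, β, every u_m,
both σs) against the conventional 1.1 bar; non-convergence flags the fit
rather than raising an error. The posterior is validated in three
independent ways in the suite: near-noiseless data reproduce the
least-squares line to <1%; credible intervals attain nominal coverage over
repeated simulation; and posterior means agree with an independent Gibbs
sampler (JAGS) on the same model.

Exact zero residual variance is pathological for this likelihood (the
posterior density diverges as σ_intra → 0), so fully noiseless fixtures
are rejected as degenerate; validation uses near-noiseless data instead.

The 95% posterior predictive band redraws a new model effect and residual
per posterior draw — the spread expected for a previously unseen model on
a new slice — and always contains the fitted line. Group-wise fits (e.g.
CNN-based vs transformer-based architectures) are fully independent, with
no pooling.

## Longitudinal change classification

Percent change is measured against the mean of the two pre-treatment
baselines. A change is declared only when it strictly exceeds the
asymmetric limits; boundary values are `no_change`. Cohort summaries
report category counts/percentages per tissue class and a two-sided paired
t-test (raw volume scale) of day-180 versus baseline mean; group volume
comparisons use Welch's t-test on per-patient averaged baselines.

One subtlety the package is explicit about: the RC limits are calibrated
for the difference of two single measurements, so exactly 5% of pure
test-retest pairs exceed them by construction. The pipeline's change
score, however, compares a follow-up to the *average* of two baselines,
whose null SD is √1.5·σ_w rather than √2·σ_w; the realised false-positive
rate is therefore ≈ 2Φ(−1.96·√2/√1.5) ≈ 2.4% — conservative relative to
the nominal 5%. The suite verifies both rates.

## The synthetic test bench

`make_phantom()` voxelises a nested-ellipse abdomen — an SF rim, an EM
ring, a cavity with VF blobs and two PM discs — deterministically, so
analytic elliptic-cylinder volumes are available as an independent check
(voxel-counted volumes agree within 2% at 1.5 mm in-plane spacing).
`corrupt_segmentation()` emulates imperfect raters with a smooth random
in-plane boundary-displacement field (RMS amplitude in mm), per-class
dilation/erosion bias, and sparse label flips; acting in physical units
makes degradation transfer across resolutions. Default corruption levels
were chosen to produce DSC in the 0.6–0.95 range typical of abdominal
tissue delineation, and are not claims about any particular dataset.

`simulate_cohort()` draws per-gender log-normal true volumes with
multiplicative within-subject error — the model under which
wCV ≈ σ_w and the LOA are reciprocal-symmetric. Default within-subject
SDs (SF 0.041, VF 0.092, PM 0.030, EM 0.019) reproduce test-retest limit
magnitudes typical of repeated abdominal segmentation (≈ ±11% SF, ±26% VF,
±5% EM), with VF deliberately the least repeatable tissue; volume scales
and gender contrasts (more SF in females, more VF/muscle in males) are set
at realistic abdominal levels. `simulate_bias_observations()` generates
the slice-area differences consumed by the bias model with every
parameter known.

What the generators do **not** emulate: MRI intensities and artefacts,
anatomically realistic shape variation, spatial correlation between
slices of one patient, and rater biases that correlate across raters.
Passing tests therefore demonstrate the statistical machinery is correct
under its stated model, not that any particular network is accurate on
real data.

All generators are bit-reproducible given (spec, seed); one master seed
fans out to independent sub-seeds through a counter-based scheme.

## Numerical choices and problem sizes

EM and HMC tolerances, tie-breaks, and degenerate-input conventions are
listed above with their defaults. The test suite sizes its simulations to
run on a single CPU in minutes: phantoms of 48–96 voxels per side and a
handful of slices, cohorts of 500–1000 patients for rate checks, 50
simulated datasets at reduced sampler settings (2 chains × 600 draws, 400
warmup) for credible-interval coverage, with the full 3 × 1500 + 500
configuration exercised end-to-end where convergence itself is the claim.
These sizes are the package's own choices; all checks are statistical and
hold with margin at these scales.

## Known limitations

* One-vs-rest STAPLE ignores between-class confusion structure.
* The bias model assumes Gaussian residuals and exchangeable model
  effects; slices from the same patient are treated as independent.
* The ICC variant and the HD95 percentile convention are choices among
  several in circulation; both are documented and configurable where
  alternatives exist.
* Surface distances are between voxel centres, so sub-voxel boundary
  placement is not represented.
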