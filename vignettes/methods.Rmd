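---
title: "Models and design choices in antmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in antmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antmorph)
```

## The problem

Cestode-infected *Temnothorax* workers develop a "parasitogenic" phenotype:
a consistent, species-specific shift of many linear body measurements away
from the healthy (wild-type) morphology. Such specimens confound
morphometric species identification and, when a taxon was described from an
infected individual, cannot simply be discarded. `antmorph` implements
three linked analyses on tables of 21 linear trait measurements (in μm, see
`trait_registry()`):

1. **Quantify** the infection effect per species and trait with linear
   models and marginal-mean contrasts.
2. **Classify** specimens to species from traits plus infection status with
   a small feed-forward neural network, judged by stratified k-fold
   cross-validation.
3. **Reconstruct** the putative wild-type trait values of infected
   specimens by per-trait Gaussian distribution mapping.

## Linear-model stage

The global model stacks the table to long format (one row per specimen ×
trait) and fits `value ~ trait * status * species`, reporting the
sequential (Type I) analysis-of-variance decomposition in model order. A
significant three-way term says infection moves different traits
differently in different species. Two conventions deserve comment:

* **Sums-of-squares type.** Sequential decomposition in model order is
  used, which is what base R's `anova()` computes and what published
  tables of this design show; with the unbalanced group sizes here,
  marginal (Type II/III) tables would differ.
* **Prescaling.** The default divides μm values by 1000. On the millimetre
  scale the trait main effect dominates the decomposition and the residual
  mean square is of order 10⁻⁴, matching the magnitudes seen in published
  tables of this design; `prescale = "species_z"` (which removes trait and
  species main effects) and `prescale = "none"` are available for
  replicating other conventions.

The per-trait models follow the field's procedure exactly: trait values
are standardized within species (subtract the species mean, divide by the
species sample SD — `scale_by_species()`, invertible via its stored
metadata), then `value ~ species * status` is fitted per trait. The
species:status interaction p-values are Bonferroni-adjusted across the
21-trait family (`p_adj = min(1, 21 p_raw)`). Infection contrasts
(uninfected − infected) are computed from estimated marginal means via the
`emmeans` package within each species; because they are differences of
fitted cell means they are invariant to the factor coding. The Bonferroni
family size is exposed (`family_size`) rather than hard-coded, since the
contrast family is a reporting choice.

**What the contrast estimates estimate.** On the standardized scale, a
simulated shift of δ within-group SDs is not recovered as δ itself: the
shift contributes δ²·p(1−p) (with p the infected fraction) to the pooled
species variance used for standardization, so with equal cell sizes the
estimand is δ/√(1 + δ²/4). The parameter-recovery tests compare against
this analytic value; ignoring the attenuation would make the test target
a biased quantity.

## Synthetic data

`species_spec()` defines the generative model per species: trait j of a
specimen is

\[ y_j = b_j e^{z} + \epsilon_j + I\,\delta_j\,\sigma_j, \]

with baseline mean \(b_j\), a shared log-normal size factor
\(z \sim N(0, s^2)\) inducing positive correlations among all traits of a
specimen (a single size axis, the dominant covariance structure of linear
size traits), independent Gaussian noise \(\epsilon_j\), and an additive
infection effect expressed in units of the analytic within-group SD
\(\sigma_j = \sqrt{b_j^2 e^{s^2}(e^{s^2}-1) + \tau_j^2}\), so simulated
effects are directly comparable to the standardized contrasts the model
stage estimates.

`study_scenario()` fixes the study conditions: three species with
uninfected/infected counts 20/19, 15/10 and 11/6 (81 workers), baseline
means typical of *Temnothorax* (CL 560 μm, SL 430 μm, ...), per-species
size multipliers 1.00/1.35/0.70 placing species ≥ 6 within-species SDs
apart, size factor SD 0.04 (a 4% coefficient of variation, the order
observed in conspecific ant workers), noise SD 1% of the baseline
(measurement error at 150× magnification is small relative to biological
variation), and infection shifts −0.8, −0.5 and +0.6 SD — two species
shrink under infection, the third enlarges, reproducing the study's
qualitative finding.

The generator emulates group means, a one-factor covariance structure, and
Gaussian within-group variation. It does **not** emulate colony structure,
allometric slope changes, non-Gaussian tails, or measurement batch
effects, so passing tests demonstrate correctness of the machinery under
the model's own assumptions, not robustness to violations of them.

## Neural-network classifier

The model matrix holds 43 predictors: the 21 raw traits, the 0/1 infection
indicator, and the 21 trait × infection products (raw product columns; all
43 are z-scaled together afterwards). Scaling parameters are learned by
`train_nn()` from its training rows only and stored in the model, so
cross-validation cannot leak held-out information.

The network has three hidden layers of ten units with logistic activations
throughout, one output unit per species, and is trained by full-batch
gradient descent with backpropagation on the multiclass cross-entropy.
Class probabilities are the logistic output activations normalized by
their sum. The more common alternative — softmax over raw output
pre-activations — was deliberately not used so that every node keeps a
logistic activation; softmax applied *on top of* logistic activations (a
third option) compresses all logits into [0, 1] and its gradient vanishes
at sigmoid saturation, which in our experiments left one class permanently
unlearned on trivially separable data. Sum-normalization keeps the
gradient of the true-class unit bounded away from zero
(\(\partial L/\partial z_k = (a_k/S - y_k)(1-a_k)\)) and trains cleanly.

Defaults: learning rate 0.2, at most 3000 epochs, early stop when the loss
improves by < 10⁻⁸, Xavier-style uniform initialization from the run seed.
A rate of 0.05 also converges but needs roughly 5000 epochs on the default
scenario; 0.2 reaches a lower loss sooner with no observed instability.
All hyperparameters are arguments and recorded in pipeline output.

Cross-validation is stratified: each species' members are spread across
the k folds so per-class fold counts differ by at most one. Performance
per fold: accuracy, one-vs-rest precision/sensitivity/specificity
(macro-averaged by default; micro available — the published per-fold
values' aggregation rule is not documented, so it is a switch), and the
multiclass Matthews correlation coefficient
\(\mathrm{MCC} = (cs - \sum_k p_k t_k)/\sqrt{(s^2-\sum p_k^2)(s^2-\sum t_k^2)}\),
which reduces exactly to the binary closed form on 2 × 2 tables.
Argmax ties break toward the first class in level order, for determinism.

## Distribution-mapping reconstruction

Group moments are Gaussian maximum-likelihood estimates per species ×
status × trait (mean; SD with divisor *n*, the ML convention — divisor
*n − 1* is available and the convention used is recorded in the output).
An infected specimen's value *y* is standardized within the infected
distribution, *d* = (*y* − μ_inf)/σ_inf, and mapped to
*p* = *d*·σ_un + μ_inf + *s* with *s* = μ_un − μ_inf (algebraically
*d*·σ_un + μ_un; both forms are computed and asserted equal at run time).
The map is affine with positive slope σ_un/σ_inf, so it preserves specimen
order within a trait and transfers the infected sample's ML moments
*exactly* onto (μ_un, σ_un) — the tests assert this to 10⁻⁹ rather than
statistically. Reconstruction is univariate per trait; no cross-trait
covariance mapping is attempted, since the underlying transform is defined
trait-wise. Cells smaller than `min_cell = 5` warn (moment estimates from
so few specimens are unstable) but proceed, since reference studies
reconstruct from cells as small as 6. Species without uninfected reference
specimens cannot be reconstructed at all — the method's inherent
limitation.

## Ordination

PCA is fitted per species (`fit_pca()` on the correlation matrix by
default, as traits share units but differ tenfold in magnitude), and
reconstructed specimens are *projected* into the space fitted on observed
specimens rather than refitted, so their position is comparable.
Components carry a deterministic sign (largest-magnitude loading
positive). The per-species reconstruction-overlap check is quantitative:
the reconstructed centroid must lie closer to the uninfected centroid than
the raw infected centroid does.

## Numerical and degenerate-input policy

* Validation is total: missing columns, unknown infection encodings,
  non-positive or missing trait values, duplicated ids, constant traits
  within a species, empty design cells, undersized moment cells and
  dimension mismatches each raise a typed condition.
* Sample SD (n − 1) for per-species standardization; ML SD (n) for
  reconstruction moments; each recorded where it is used.
* Degenerate classifier states: constant predictor columns get unit scale;
  non-finite loss or weights abort with a divergence error; an all-equal
  probability row predicts the first class.

## Problem sizes in the tests

The test suite runs entirely on generated data: the study-scale scenario
(81 specimens), reduced scenarios of 30–60 specimens for unit tests, a
500-replicate null simulation for the type-I calibration of the
interaction test (rejection rate within 2 Monte-Carlo SE of 5%), a
10-seed cross-validation study at 81 specimens each, and n = 200 per cell
for contrast parameter recovery. These sizes give Monte-Carlo error well
below the tolerances asserted while keeping a full run to a few minutes.

## Known limitations

* Reconstruction assumes within-group normality and a common affine
  infection action; heavy tails or variance heterogeneity within a group
  will map incorrectly even though the moment transfer still holds.
* The classifier is a fixed small architecture; no regularization or
  architecture search is attempted (out of scope by design).
* Colony membership is ignored (no random effects); in real data,
  colony-level variation inflates the apparent infection effect if
  infection is colony-clustered.
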