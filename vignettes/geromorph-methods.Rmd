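---
title: "Local brain age from cortical morphometry: models, parameters and design choices"
author: "geromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local brain age from cortical morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Brain age is the age a predictive model assigns to a scan; the brain-age
gap (predicted minus chronological age) is a candidate marker of advanced
or delayed brain aging. `geromorph` estimates brain age *locally* — one
value per vertex of a cortical surface mesh — from five per-vertex
morphometric features (cortical thickness, sulcal depth, curvature, surface
area, gray/white intensity ratio), so that regional aging is measured
directly rather than inferred from a global score.

The predictor is a graph U-Net over a hierarchy of nested icosphere
atlases. Each scan is a pair of spheres (one per hemisphere) concatenated
into a single disconnected graph; mesh edges define adjacency and never
cross hemispheres. The encoder applies, at each resolution from finest to
coarsest, a spectral graph convolution
$\hat A X W + b$ with $\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$,
then batch normalisation and ReLU, and pools down between resolutions. The
decoder mirrors this with unpooling, concatenation of the encoder skip
tensor, and the same block structure. The output block is a single graph
convolution to one channel: the local brain age. Pooling is fixed by the
atlas geometry, not learned: the receptive field of a coarse vertex is its
nearest fine vertex (same hemisphere, Euclidean distance on the sphere,
ties to the lowest index) together with that vertex's 1-hop neighbours;
downsampling averages over receptive fields and upsampling averages over
their exact set-dual inverses.

Training minimises the vertex-wise mean absolute error against the scan's
chronological age broadcast to every vertex, with Adam over shuffled
mini-batches. Batch-norm statistics are computed over all vertices of all
graphs in a batch; inference uses the stored running statistics, so
prediction is deterministic.

## Assumptions

- Scans are registered to a common spherical atlas, so vertex $v$ means the
  same cortical location in every subject; all spatial correspondence comes
  from upstream registration, which the package consumes, not reproduces.
- The five features carry an age signal that is locally decodable: a vertex
  neighbourhood's features suffice to estimate that location's aging state.
- Age enters the loss in years, unstandardised; features are z-scored per
  column with training-set global mean/SD (stored with the model, and the
  reference frame for the zero baseline of integrated gradients).

# Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `featureWidths` | 5, 8, 16 | channels | input width must equal the number of feature assays |
| `epochs` | 50 | – | reference value; see the step-budget rule below |
| `batchSize` | 128 | scans | batch-norm statistics pool all vertices in the batch |
| `learningRate` | 0.01 | – | Adam |
| smoothing `hops` / `iterations` | 2 / 4 | graph steps / passes | synchronous neighbourhood averaging |
| medial-wall `wallRadius` | 0.25 | rad | geodesic cap around each hemisphere's medial pole |
| IG `steps` | 50 | – | right-endpoint Riemann sum |
| sex bootstrap `reps` | 500 | – | one male/female pair per overlapping integer year |
| BH threshold | 0.05 | – | adjusted p at or above it is flagged insignificant |

## Desk-scale training: two numerical choices

**Output-bias initialisation.** Weights are Glorot-uniform under the run
seed. The output-layer bias is initialised at the training-set mean age
rather than zero: with a mean-absolute-error loss the gradient magnitude is
bounded, so Adam moves each parameter by at most roughly the learning rate
per step, and starting the output at 0 years would spend thousands of steps
drifting to the high-60s before any signal fitting happens. Starting from
the best *constant* predictor removes that transient without affecting what
the optimum is.

**Step budget.** Epoch counts only make sense relative to cohort size: the
reference regime's 50 epochs on a production-size cohort is thousands of
optimiser steps, while 50 epochs on a 400-scan cohort would be 200. The
helper `scaledEpochs()` therefore holds the optimiser-step budget fixed
(default 1500 steps) and raises the epoch count accordingly; this is the
default used by `endToEndFixture()`. Problem sizes used by the shipped
experiments: the parameter-recovery experiment runs 400 subjects on a
two-hemisphere level-0/1/2 hierarchy (324 joint vertices) with 1500 steps;
the repeated lesion-recovery property uses 80 subjects on a level-0/1
hierarchy with 300 steps per replicate.

# The synthetic cohort generator

`simulateCohort()` emulates the statistical structure of registered
morphometry, not its biophysics. Per feature it builds a smooth baseline
spatial field (white noise diffused by the package's own mesh smoother,
scaled to unit SD), a smooth slope-modulation field in [0.5, 1.5], and then
sets feature = baseline + slope·(localAge − midAge) + Gaussian noise. The
ground-truth local age is chronological age (drawn uniformly, default
45–90 y) plus a configurable lesion offset (default +10 y) on designated
parcellation regions of an accelerated-aging subgroup (default 25% of
subjects), plus an optional global male offset (default 0). Cognitive
scores are linear in the true global gap plus noise: "memory" (higher =
better) and a TMT-B-like score with a hard ceiling at 300. Everything is
deterministic under the config seed.

What this does **not** emulate: realistic feature distributions or
covariances, scanner/site effects, registration error, spatially varying
noise, longitudinal structure. Passing tests therefore demonstrate that the
algorithms are implemented correctly and can recover a planted signal under
favourable conditions (slope 1 per year against noise SD 0.1) — they say
nothing about accuracy on real MRI, and the headline accuracies of
production-scale cohorts are out of scope here.

A desk-scale caveat worth knowing: on an 84- or 324-vertex mesh the 2-hop,
4-iteration smoother spans a large fraction of a hemisphere, so a lesion
confined to one small region is strongly diluted before the group
comparison. The recoverable signal at this scale is the lesioned region's
*rank* in the difference map, not the absolute difference in years.

# Numerical and design choices

- **Nearest-neighbour ties** in receptive-field matching break to the
  lowest vertex index, for bitwise reproducibility. On nested icospheres
  matching is exact (distance 0) because subdivision keeps parents as a
  prefix of the child vertex ordering.
- **Empty inverse fields** cannot occur on nested icospheres (asserted in
  tests). For non-nested inputs, uncovered fine vertices are imputed in
  increasing-index waves as the mean of already-covered 1-hop neighbours;
  the count of imputed vertices is reported on the operator.
- **Smoothing** includes the centre vertex and is synchronous
  (Jacobi-style), so results do not depend on vertex order; wall removal
  precedes smoothing and wall vertices are excluded from neighbourhoods.
- **Medial wall**: no public geometric definition exists for the wall on a
  synthetic sphere, so it is a geodesic cap (default 0.25 rad) around the
  pole facing the other hemisphere; real atlas annotations can be
  substituted wherever a mask is accepted.
- **Bias correction** follows the prose definition of the adjustment term,
  LBA′ = LBA − (m_μ·CA + b_μ); the term is subtracted as a whole. Fitting
  and applying on the same cohort yields a grand-mean corrected gap of 0
  analytically (OLS residuals have zero mean per vertex; averaging
  coefficients preserves the identity), which the tests assert to 1e-8.
- **Training target** includes medial-wall vertices (the wall is removed
  only after training); a `maskWallLoss` switch exposes the alternative.
- **Integrated gradients** need a scalar target; the package uses the mean
  predicted age over non-wall vertices, the natural cohort-comparable
  reduction, evaluated with batch-norm in inference mode so the gradients
  are exact gradients of the deterministic predictor. The Riemann sum uses
  right endpoints. The cohort baseline draws one batch of reference scans
  (default the training batch size, capped at cohort size) under a recorded
  seed and reuses it for every target scan.
- **t-tests** are equal-variance Student tests by default (a Welch switch
  is exposed); the regional-LBA-versus-CA comparison is implemented as the
  literal independent two-sample test, with the conventional paired
  alternative available to the user by testing the gaps directly.
- **Sex** is coded as a 0/1 indicator in regressions; each analysis forms
  one BH family (one per test battery within a cohort; one per region set
  within a comparison).
- **Parcellation** for synthetic data is a deterministic geodesic-patch
  construction (farthest-point seeds on graph distance, nearest-seed
  assignment, ties to the lowest seed index) with a configurable region
  count; real data can supply FreeSurfer annot files or plain
  label-per-vertex text.

# Known limitations

- No GPU path and no hyperparameter search; the network code is written for
  desk-scale correctness and the production ico4/5/6 configuration is
  buildable but slow in pure R/sparse-BLAS.
- The graph U-Net mixes information hemisphere-wide through its coarsest
  level, so predictions are not strictly local; locality is bounded (and
  tested) but regional attribution at desk scale leans on the skip
  connections.
- Dropout and weight decay are not implemented (none are part of the
  reference configuration).
- The bias-correction, bootstrap and regression machinery assumes one scan
  per subject; repeated scans would need subject-level clustering that is
  out of scope.
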