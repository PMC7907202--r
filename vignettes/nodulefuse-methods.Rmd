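---
title: "Methods: shape, appearance, size and breath markers for nodule classification"
author: "nodulefuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape, appearance, size and breath markers for nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulefuse)
```

# The problem

Most pulmonary nodules found on screening CT are benign, but telling them
apart from early lung cancer currently requires serial imaging over months
to years, or biopsy. `nodulefuse` implements a non-invasive classification
pipeline that combines four marker groups available from a single CT scan
and a single exhaled-breath test:

* **Shape** — malignant nodules grow irregularly and develop spiculated
  surfaces; smooth surfaces need few spherical harmonics to approximate,
  spiculated ones need many.
* **Appearance** — malignant tissue is spatially heterogeneous in
  attenuation; a high-order Markov–Gibbs random field (MGRF) summarizes
  local voxel interactions as a Gibbs energy.
* **Size** — larger nodules are more often malignant; size alone is a weak
  but cheap marker.
* **Breath** — concentrations of 27 carbonyl volatile organic compounds
  (VOCs) in exhaled breath shift with malignancy.

Each image marker and the breath panel feeds its own stacked-autoencoder
(AE) + softmax classifier; their class probabilities, together with a size
k-NN probability, are fused by a second-stage classifier.

# Conventions

Volumes are R arrays indexed `[x, y, z]` (1-based, column-major) with voxel
spacing `(dx, dy, dz)` in mm; the world coordinate of voxel `(i, j, k)` is
`origin + (c(i, j, k) - 1) * spacing`. Masks are binary, single
26-connected components; multi-component masks are rejected unless the
caller opts into keeping the largest component. HU values are stored as
integers when the source is integer.

# Shape branch

## Surface extraction

The mask is smoothed with a small Gaussian (default bandwidth 1.2 mm) so
the 0.5 level set tracks the true surface with sub-voxel accuracy, then
triangulated by marching tetrahedra (each grid cell split into six
tetrahedra around its main diagonal). This produces a closed, edge-manifold
mesh without the ambiguous configurations of cube-based tables; on a
voxelized 8 mm-radius ball the mesh area is within a few percent of the
analytic `4*pi*r^2`. A resampling step (default 1.75 mm) controls mesh
resolution — about 1100 nodes for an 8 mm nodule — which bounds the cost of
the quadratic-in-nodes relaxation below.

## Attraction–Repulsion spherical mapping

Nodes are first projected radially to the unit sphere, then relaxed by
alternating two steps per cycle, both computed Jacobi-style from the
previous cycle's coordinates:

* attraction, `C'_i = C_i + sum_j [ c_A1 d_ji |d_ji|^2 + c_A2 d_ji/|d_ji| ]`
  over the mesh neighbors `j` of `i`, with `d_ji = C_j - C_i`, pulls each
  node toward the centroid of its neighbors and equalizes neighbor
  distances;
* repulsion, `C°_i = C'_i + (c_R/2I) sum_{j != i} (C_i - C_j)/|C_i - C_j|^2`
  over all `I` nodes, pushes crowded nodes apart, after which every node is
  back-projected to the unit sphere.

The repulsion term is written here with its repulsive sign (away from
nearby nodes); the attraction step keeps both terms inside the neighbor
sum. Coincident pairs are skipped and exactly-zero updated vectors receive
a 1e-9 jitter, so no cycle can divide by zero.

Constants are tunables with no canonical values; the defaults
`c_A1 = 0.3`, `c_A2 = 0.02`, `c_R = 1`, tolerance `1e-4` (max per-node
displacement per cycle) and 200-cycle budget were chosen for stable
convergence: at `c_A2` an order of magnitude larger the unit-vector term
dominates the local edge length and the iteration oscillates without
converging. On ball fixtures the defaults converge in ~130 cycles while
the coefficient of variation (CV) of neighbor distances falls from ~0.6 to
~0.2; non-convergence is reported in the `converged` flag, never as an
error.

## Harmonic error curve

With each node's unit-sphere image assigning it spherical angles, the three
coordinate functions of the original surface are regressed on the real,
orthonormal spherical-harmonic basis (Condon–Shortley phase omitted;
fully-normalized associated-Legendre recurrences keep degree-70 values
finite). The shape feature is the normalized root-mean-square residual of
the best degree-`k` fit for `k = 1..70` — a shape-complexity signature
that is invariant to orientation conventions and, being normalized, exactly
invariant to uniform scaling. Smooth surfaces drop quickly; spiculated
surfaces keep residual energy at high degrees.

Residuals for all orders come from one incremental block Gram–Schmidt pass
(degree block by degree block, with reorthogonalization), which is
algebraically identical to refitting at every order and therefore monotone
non-increasing by construction. The fit uses at most 900 nodes
(deterministic subsample) and caps the order at the largest `L` with
`(L+1)^2` not exceeding the node count; beyond that the curve is padded
with its last value and the feasible order recorded — a ~1100-node mesh
supports orders near 30, which is where the information for the
8 mm-scale fixtures lives anyway.

# Appearance branch

The 7th-order MGRF couples each voxel with its six axial neighbors at
distance `rho` (7-voxel cliques, one clique family per radius, default
radii 1–5). The clique code `beta` is the number of neighbors whose HU
strictly exceeds the center (ties count as "not greater"), so
`beta` ranges over 0..6 and is invariant to any offset or positive scaling
of the HU scale — the contrast/offset invariance that motivates ordinal
coding. Under the independent-continuous-signal null the center's rank is
uniform among the seven values, giving the analytic core distribution
`F_core(beta) = 1/7`.

Potentials are the analytic maximum-likelihood approximation

```
v(beta) = (F_core(beta) - F_emp(beta)) / (F_core(beta) (1 - F_core(beta)))
```

with `F_emp` the pooled in-mask marginal of the code over the training
nodules. The per-voxel Gibbs energy is the sum of `v` over the
configured radii; the appearance feature is its 1000-bin histogram over the
training energy range (frozen into the model; inference values clamped),
normalized to sum 1. The partition function of the underlying Gibbs
distribution is never needed — only energies are used downstream.
Degenerate case: if the training energy range has zero width, all mass
lands in the first bin.

Homogeneous (benign-like) and clumped (malignant-like) textures separate in
this energy: the homogeneous class sits at higher energy, matching the
intuition that its codes stay closer to the noise-driven uniform law.

# Size and breath branches

Size is summarized as the equivalent sphere diameter
`d = (6V/pi)^(1/3)` from the voxel-count volume, the convention used when
nodules are characterized by diameter. A basic k-NN (default `k = 5`, odd
to avoid 50/50 ties; absolute diameter difference; distance ties broken by
training-record order) returns the malignant fraction among the `k`
nearest training nodules as an initial malignancy probability. Within
training cohorts each subject's own record is excluded from its neighbor
pool.

Breath panels are 27 opaque ordered channels of non-negative
concentrations (nmol/L). They are standardized per channel on the log
scale, `z = (log(c + 1e-6) - mean)/sd`, with the SD floored at 1e-8 so a
constant channel maps to finite zeros; location and scale always come from
the training panels in scope.

# Classifiers

Each branch classifier min-max scales its inputs to `[0, 1]` (scaling
learned on the training rows), pre-trains its hidden layers greedily as
autoencoders — sigmoid encoder `h = sigmoid(W u + b)`, linear decoder
(inputs are real-valued), squared reconstruction error — and then
fine-tunes the full stack with a two-class softmax head on the
cross-entropy. Hidden stacks taper geometrically to the prescribed
bottlenecks: shape 70→40→20→10, appearance 1000→500→250→100, breath
27→20→15→10, so the default feature space is 1098 raw dimensions reduced
to 121 (100 + 10 + 1 + 10, the 1 being size).

Optimization is full-batch gradient descent with classical momentum 0.9
and learning rate 0.5. Epoch budgets are per branch: the small networks
(shape, breath, fusion) default to 60 pre-training and 200 fine-tuning
epochs; the appearance stack, whose first layer alone carries half a
million weights and dominates the training cost, uses 20 and 60. An
under-trained small branch is worse than useless under
leave-one-subject-out evaluation: a classifier that falls back on the
training prior predicts the *opposite* of each held-out subject's class
(the held-out subject is always in the training minority), so the cheap
branches get budgets that train them to convergence. Two numerical choices matter at cohort-sized n: the decoder is
linear (a sigmoid decoder on `[0, 1]`-scaled histograms saturates), and
encoder/softmax biases are initialized at `-mean(A W)` so the sigmoids
start in their linear regime — without this the all-positive activations
drive a three-layer stack into saturation and the bottleneck collapses to
a constant. All weight initializations draw from a seeded uniform law, so
training is deterministic given the configuration seed.

The fusion stage consumes the 7-vector of the three branch probability
pairs plus the k-NN probability. Its default form is a small 7→4→2 AE with
a softmax head; `fusion_mode = "softmax_only"` gives the plainer reading
(a softmax directly on the seven probabilities). The decision threshold is
fixed at 0.5; AUC is computed threshold-free from the ranked
probabilities.

# Evaluation protocols and leakage

`evaluate_cohort()` implements leave-one-subject-out (LOSO) and stratified
75/25 split protocols. Everything learned from data — MGRF potentials and
energy range, breath normalizer, branch classifiers, k-NN neighbor pool,
fusion stage — is re-learned inside every fold from the training subjects
only, so the held-out subject's features and label cannot influence its
own prediction; permuting a held-out label provably leaves its prediction
unchanged, and the test suite asserts exactly that. To make fold-wise
relearning cheap, per-nodule clique-code tables are cached once and
fold-specific potentials, ranges and histograms are re-derived from the
cached codes.

Reports carry the confusion counts, accuracy/sensitivity/specificity in
percent, AUC, per-subject predictions with all branch probabilities, and
the feature-space dimensions.

One behavior of LOSO on *uninformative* features is worth knowing when
reading the zero-contrast control: a classifier that falls back on the
training class frequencies predicts the majority of its training fold,
and in a balanced cohort the held-out subject is always in the training
minority — so a prior-driven branch scores near 0%, not 50%. This
anti-learning artifact is a well-known property of leave-one-out
estimates under the null, affects the per-branch accuracies of the
control cohort, and washes out at the fused level, which stays inside
the binomial chance band around 50%.

# The synthetic cohort generator

Real paired CT + breath cohorts are not publicly available, so the package
ships a generator that emulates exactly the contrasts the pipeline claims
to exploit, with ground truth by construction:

* **Geometry** — a radial surface `r(theta, phi)`: benign nodules are
  spheres of the base radius (8 mm default, within the 4–20 mm diameter
  range typical of screening); malignant surfaces are modulated by a
  random degree-8 spherical-harmonic combination scaled to a 0.25 peak
  relative amplitude. The radial parameterization makes the
  smooth/spiculated classes controlled by construction.
* **Texture** — benign interiors are a constant −50 HU plus a smooth
  low-frequency field (amplitude 10 HU, 5 mm scale) plus 10 HU Gaussian
  noise; malignant interiors are a two-level field (±60 HU around the
  mean, i.e. 120 HU contrast) obtained by thresholding 3 mm-smoothed noise
  at its in-mask median, plus the same noise.
* **Breath** — log-normal concentrations, benign log-mean `log(10)` and
  log-SD 0.5 on all 27 channels, with a +0.4 additive log-shift on the
  first 10 channels for malignant panels. These levels were chosen so
  breath alone is a moderate marker (single-channel effect 0.8 SD,
  combined Mahalanobis distance ≈ 2.5), far from sufficient on its own —
  mirroring the reported ordering in which breath markers alone reach
  roughly 75–80% accuracy while imaging markers do better.
* **Cohorts** — `round(prevalence * n)` malignant subjects, shuffled, each
  with its own sub-seed, so cohorts are reproducible as a whole and per
  subject. `zero_contrast_params()` switches every contrast off (no
  spiculation, no texture contrast, no low-frequency field, no VOC shift),
  making the two classes identical in law — the negative control under
  which any classifier can only perform at chance.

What the generator does **not** emulate: lung background anatomy, partial
volume and reconstruction-kernel effects, beam hardening, vessel/pleura
attachment, radiologist segmentation variability, or correlated VOC
chemistry. A side effect of the radial modulation is that malignant masks
are on average slightly larger than the fixed-radius benign masks, so the
size branch is more informative on synthetic cohorts than on clinical
data. Passing tests on these fixtures therefore demonstrates that the
implementation recovers the signals it models — not clinical performance.

# Problem sizes and runtime choices

The default experiment sizes used by the test suite and the acceptance
script are a 60-subject cohort at prevalence 0.5 (seed-derived sub-seeds),
~25³-voxel nodule grids at 1 mm spacing, ~1100-node meshes (1.75 mm
resampling) mapped with a 200-cycle budget, SH fits on ≤900 nodes, and
MGRF radii 1–5. With these
sizes one LOSO pass over 60 subjects (including per-fold retraining of all
branches) takes a few minutes on a single core. All of these are
configuration values, not constants.

# Known limitations

* The AR mapping is not guaranteed fold-free (bijective); strong
  non-convexity can still alias the parameterization, which inflates
  low-order reconstruction errors for both classes.
* The per-order error curve is used as the 70-dimensional shape feature;
  raw SH coefficients are not comparable across subjects without a
  registration step, which is out of scope.
* Appearance histograms from ~2000 in-mask voxels over 1000 bins are
  sparse; the branch needs tens of training subjects before it becomes
  reliable.
* With cohort-sized training sets the fusion stage sees nearly perfect
  in-sample branch probabilities, so it cannot learn that a branch
  generalizes poorly; fusion quality therefore tracks the branches'
  out-of-sample quality.
* The pipeline classifies benign vs malignant only; it does not
  discriminate cancer subtypes.
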