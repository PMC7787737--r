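---
title: "Region-fusion craniofacial reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-fusion craniofacial reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniofuse)
```

## The problem

Craniofacial reconstruction estimates a face surface from a skull surface
using skull–face shape relations learned from a corresponded database: all
skulls share one triangle-mesh topology, all faces another, and vertex `i`
is the same anatomical location in every sample of a modality. Because the
skull–face relation differs between facial regions, this package models it
*regionally*: the meshes are partitioned into five regions (left eye, right
eye, nose, mouth, and the remaining frame), each region gets its own pair of
latent shape spaces and its own regression, and the five regional
predictions are spliced back into one smooth face.

The processing chain for training is

1. **Segmentation** — fuzzy c-means (FCM) on per-vertex features derived
   from across-sample displacement covariation (`segment_modality()`),
2. **Latent embedding** — one Gaussian process latent variable model
   (GP-LVM) per region and modality (`fit_gplvm()`),
3. **Regression** — multi-output least-squares support vector regression
   (LSSVR) from skull latents, optionally augmented with age and BMI, to
   face latents (`train_multi()`),

and for reconstruction

4. the unknown skull's regions are projected into the skull latent spaces
   (`gplvm_encode()`), mapped to face latents, decoded to regional face
   meshes (`gplvm_decode()`), and
5. fused into one mesh by thin-plate-spline (TPS) splicing across blend
   bands (`fuse_regions()`).

## Models

### GP-LVM

For one region and modality, the `M` training shapes are flattened to rows
of `Y` (`M x D`, `D = 3 x` vertex count, mm) and centered. All `D` output
dimensions share one latent configuration `X` (`M x q`) and one ARD
squared-exponential kernel
`k(x, x') = sigma_f^2 exp(-1/2 sum_d (x_d - x'_d)^2 / M_d)`, giving the log
marginal likelihood

```
L = -(D/2) log det(K + sigma_n^2 I)
    - (1/2) tr((K + sigma_n^2 I)^{-1} Y Y^T) - (M D / 2) log 2 pi .
```

`X` (initialized from PCA scores) and the log kernel parameters are
optimized jointly by L-BFGS with analytic gradients, checked against finite
differences in the test suite. Decoding is the standard GP posterior mean
plus the stored data mean; the predictive variance is shared across output
dimensions.

The latent dimension `q` is chosen per region as the number of PCA
eigenvalues standing clearly above the noise floor (share above
`max(0.5%, 5 x median share)`), capped at 8 and `M - 2`. Shape spectra here
are a few strong modes over a flat noise tail, which a fixed
variance-fraction rule reads badly: a 95% rule truncates genuine modes
hiding behind one dominant mode, a 99% rule accumulates dozens of noise
dimensions.

**Encoding** a new shape — the projection step the reconstruction needs —
is not part of the classical GP-LVM and is formulated here as minimizing
the negative predictive log-density of the new shape over the latent
point, `D/2 log v(x) + ||y - mu(x)||^2 / (2 v(x))` with
`v = Sigma*(x) + sigma_n^2`. The surface is sharp when `sigma_n^2` is
small, so the optimizer is run from several starts (the latents of the
nearest training shapes), constrained to the training latent hull with
margin, refined by a short Nelder-Mead pass, and never returns a point
worse than its best start.

### LSSVR

LSSVR replaces classical SVR's inequality constraints by equalities with
squared slacks, so training one output is a single linear KKT system

```
[[0, 1^T], [1, Omega + I/C]] [b; alpha] = [0; y],
Omega_ij = exp(-||x_i - x_j||^2 / (2 sigma^2)) ,
```

whose first row forces `sum(alpha) = 0`. The multi-output wrapper trains
one model per face-latent dimension; all outputs share the support inputs
and hyperparameters, so one factorization serves all right-hand sides. The
customary initial values `C = 1000`, `sigma^2 = 100` are refined by seeded
5-fold cross-validation over log grids (`C` in `10^2..10^5`, `sigma^2` in
`10^0..10^3`); on z-scored latent inputs the initial `sigma^2 = 100` is far
too wide (the kernel is nearly constant), and the CV reliably moves to a
useful width. The regression target is the face *latent* coordinates,
decoded afterwards by the face GP-LVM — regressing raw face coordinates
would forfeit the nonlinear decoder.

Attribute conditioning appends z-scored age and BMI to the regression
inputs; the training statistics are stored in the bundle and reused at
reconstruction time.

### Segmentation

The paper class of methods clusters vertices with FCM on robust-PCA
features but leaves the feature construction open. The features used here
are built from the across-sample displacement trajectories projected on the
mean-mesh normal (the soft-tissue displacement scalar):

1. robust PCA (principal component pursuit by inexact augmented
   Lagrangian) denoises the trajectory matrix. The sparsity weight is set
   to `4/sqrt(max(dim))`, deliberately above the standard `1/sqrt(max(dim))`:
   spatially localized region modes themselves look "sparse" to principal
   component pursuit at the standard weight and would be stripped from the
   low-rank part, which is precisely the signal the segmentation needs;
2. attribute effects are regressed out (they are global soft-tissue modes,
   uninformative for a partition), and remaining *global* modes — singular
   vectors whose energy spreads over more than 20% of vertices, such as
   overall size — are projected out by participation ratio;
3. the remaining localized covariation defines an `|cor|` affinity between
   vertices (entries below `max(0.35, 2.5/sqrt(M))`, the scale of sampling
   noise, are zeroed), and the normalized spectral embedding of that
   affinity, weighted per vertex by its residual energy share, is the
   feature matrix. Vertices without localized variation — the frame —
   collapse into one tight cluster at the origin, which keeps the strongly
   unbalanced cluster sizes from breaking FCM;
4. FCM with `m = 2`, `C = 5` (best of three seeded initializations by the
   objective) assigns crisp labels, which are then majority-smoothed on the
   mesh graph and reduced to one connected component per feature region.

Regions are named anatomically from their centroids in the canonical frame
(largest cluster = frame; most lateral pair = eyes by the sign of x; of the
remaining two the higher is the nose, the lower the mouth). Skull and face
are segmented independently and corresponded by name. Segmentation is
computed once on the training set and transferred to any corresponded mesh
by vertex index.

### Region fusion

Each feature-region prediction is spliced onto the global base mesh. The
region boundary `B0` shrinks `k` rings into the part (graph erosion;
`k = max(1, round(S0 / mean edge length))`) to a fixed contour, and
reversely `k` rings into the base side. Two thin-plate splines (radial
basis `r^3` plus affine part, pure interpolation) move each side's boundary
to the midpoints `P2 = (P0 + P1)/2` while fixing the inner contours, so
both sides meet exactly at `P2` and vertices outside the bands are
untouched bit-for-bit. Parts are processed largest boundary first, and
overlapping blend bands are an error.

The pipeline assembles the base as the frame reconstruction on frame
vertices plus the regional reconstructions on their own vertices (the
initial fusion), then blends the frame-side bands. Two consequences worth
noting:

* `fuse_regions()` offers rigid pre-positioning of each part (orthogonal
  Procrustes, reflections disallowed), but the pipeline passes
  `align = FALSE`: its parts are decoded in the global frame by
  construction, and re-aligning them onto the base would cancel exactly
  the predicted positional offsets the regression worked to produce.
* the pipeline's default shrink step is `S0 = 2 x` mean edge length (two
  blend rings). Three rings would demand wider corridors between feature
  regions than eye-to-nose distances provide, here and on real faces.

If a learned segmentation makes splicing geometrically infeasible
(overlapping bands, a region without interior), the pipeline falls back to
the initial fusion with a warning rather than failing the reconstruction.

## The synthetic testbed

The reference CT database of corresponded head meshes is private, so the
package ships a generator whose *statistical* structure mirrors what the
method assumes about such data:

* a deformed-ellipsoid grid head (half-axes 70 x 85 x 90 mm,
  `n_theta x n_phi` grid closed by two poles; default 40 x 40, ~1,600
  vertices); the face template is the skull offset 6 mm outward along
  vertex normals;
* five planted regions; per region, `q_r = 3` latent factors drive the
  skull displacement linearly and the face displacement through a distinct
  *nonlinear* map (`0.6 linear + 0.35 tanh + 0.25 centered-quadratic` of
  orthogonally mixed latents) over smooth windowed basis fields, so the
  skull-to-face relation is region-specific and nonlinear — the premise
  the regional method exploits. Feature-region fields use box-local
  harmonics (global low-order harmonics are nearly constant over a small
  box and would collapse the region's effective rank); frame fields are
  global low-order modes (uniform size, large-scale shape), the realistic
  regime for the non-feature remainder;
* region windows are plateaus with a narrow raised-cosine rim, so region
  displacement stays region-local instead of leaking a frame mode deep
  into every feature region;
* age ~ U(19, 75) and BMI ~ N(24, 3) add outward soft-tissue offsets
  through fixed positive weight fields (defaults 0.3 mm per decade from
  age 45, 0.25 mm per BMI unit from 24 — plausible soft-tissue scales);
* iid Gaussian vertex noise (default 0.2 mm, a sub-millimetre acquisition
  regime) on both meshes.

Default population sizes are 72 pairs (60 train / 12 test), minutes on one
CPU. Everything is deterministic given the config seed, and the truth
record keeps the noise-free faces as an error floor for tests.

What the generator does *not* emulate: anatomical realism (teeth, orbits,
mandible articulation), correspondence error, scanner artefacts, and any
skull-face relation outside its planted model class. Passing tests
demonstrate that the implementation recovers structure it is designed to
recover under controlled conditions — not clinical accuracy on real CT
data.

## Numerical choices

* Cholesky factorizations use an escalating jitter ladder
  (`0, 1e-10 .. 1e-6`); kernel log-parameters are box-bounded during
  optimization.
* FCM handles a point coincident with a center by giving it full
  membership there; ties split equally. The empty-cluster case re-seeds
  once, then errors.
* The TPS systems are solved exactly (no bending regularization); a
  singular system gets one `1e-9` jitter attempt, then errors.
* `rigid_align` rejects rank-deficient configurations and forces
  `det(R) = +1`.
* OBJ/PLY I/O is triangle-only by design: silent triangulation of a quad
  would silently break dense correspondence.
* Pose normalization (`normalize_pose`) is an anchor-based stand-in for
  anatomical (Frankfurt-plane) alignment, which needs landmarks no
  algorithm here detects; synthetic data is generated already canonical.

## Known limitations

* The regression treats face-latent dimensions independently; correlated
  residuals between face latents are not modelled.
* Encoding an unknown skull is a non-convex optimization; the multi-start
  scheme is robust in practice but carries no global guarantee.
* The fusion assumes feature regions are islands in the frame with
  corridors at least `2k + 1` rings wide; segmentations violating that
  fall back to the unspliced initial fusion.
* Real-data performance claims require the private CT database; the
  package's quantitative statements are about the synthetic testbed only.
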