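---
title: "Methods: synthetic tongue surfaces and the papillae analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic tongue surfaces and the papillae analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup}
library(papillar)
```

`papillar` analyses the microscopic 3D shape of tongue papillae on
triangulated surface meshes (coordinates in micrometres). Real scan data of
this kind is rarely public, so the package ships a synthetic-surface
generator with exact ground-truth annotations, and the full downstream
pipeline: candidate-segment extraction, three feature families
(baseline, curvature, topological), classification studies with balanced
accuracy, permutation feature importance, and whole-surface papillae
mapping. This vignette documents the model, every default, and the
numerical choices, including where the package had to make decisions that
published descriptions of such pipelines leave open.

## The synthetic surface model

A surface is a regular-grid heightfield over a `width` × `depth` rectangle,
triangulated into a mesh, with three additive components:

1. **Base undulation.** A low-frequency sinusoidal swell,
   `z = A [sin(2πx/λ + φ₁) + sin(2πy/λ + φ₂)] / 2`, with amplitude
   `A = 30 µm` and wavelength `λ = 3500 µm` by default. This emulates the
   gentle large-scale relief of a tongue impression without creating local
   maxima that compete with papillae.
2. **Papillae.** Radial bumps placed by dart throwing (uniform random
   centres, rejected until all base disks are pairwise disjoint plus a
   `min_separation` gap; a bounded number of retries, after which a
   placement error is raised).
   - *Fungiform* (dome): `z = h (1 − (ρ/R)²)^p` over the base disk, with
     defaults `R = 439 µm` (diameter ≈ 878 µm) and `h = 250 µm`;
     `p = max(0.6, sharpness)`.
   - *Filiform* (crown): a central peak of support radius `0.38 R` plus
     `spike_count` (default 6) sub-peaks arranged on a ring of radius
     `0.62 R`, each of height `0.85 h`; defaults `R = 177.5 µm`
     (diameter ≈ 355 µm), `h = 170 µm`, profile exponent
     `q = max(1.1, 1.5 · sharpness)`. The crown geometry is a package
     choice: "crown-like" is a qualitative description, and this
     construction produces the sharper curvature and the richer
     one-dimensional homology that distinguish filiform shapes.
3. **Measurement noise.** Per-vertex Gaussian displacement of standard
   deviation `noise_sd = 2 µm` along the vertex normal, emulating
   reconstruction roughness. Noise is along normals, not isotropic, so flat
   regions stay statistically flat.

The mesh pitch defaults to `25 µm`; at this resolution a default fungiform
dome spans ~35 grid cells across, enough to resolve the rim crease where
Gaussian curvature turns negative.

Per-papilla biological variability is lognormal jitter on base radius
(sd 0.15), height (sd 0.25) and sharpness (sd 0.15). These are fixed
package-wide constants, chosen a priori so that the baseline features
(height, radius) of the two types overlap rather than separate trivially.

### Cohorts and planted effects

`generate_cohort()` draws participants with gender, age (22–37 years,
alternating draws below/above the age-group cut-off of 28/29 so groups are
balanced), and latent shape offsets. Effects act multiplicatively on
papilla sharpness through `cohort_effects()`:

* female participants: sharpness × `exp(0.30)`;
* younger participants: sharpness × `exp(0.20 · (29.1 − age)/3.7)`;
* participant identity: lognormal sharpness offsets (sd 0.25) and size
  offsets (sd 0.10), plus a ±1 jitter of the crown spike count.

The direction of the gender and age effects (sharper, higher-curvature
papillae for female and younger participants) mirrors the qualitative
finding the pipeline is designed to detect; the magnitudes are package
choices fixed before any evaluation was run. `cohort_effects_null()` zeroes
all participant-level variation so that participant identity becomes
unlearnable — a negative control used by the acceptance suite.

What the generator does **not** emulate: real papillae anatomy (no
mushroom overhangs — heightfields cannot fold over), spatial density
gradients across tongue regions, scanning artefacts other than isotropic
normal noise, and any correlation between gender/age and papilla *density*.
Conclusions about real tongues cannot be drawn from synthetic cohorts; the
generator exists to validate the pipeline's ability to recover planted
structure.

## Segment extraction

`extract_segment()` implements the candidate-finding procedure in five
steps: (1) collect vertices within `r + δ` of the seed point P; (2) keep
only the mesh-edge-connected component containing P; (3) fit a base plane
to the component by RANSAC; (4) take M, the component vertex with maximum
signed distance above the plane, then re-apply steps 1–4 centred on M until
M is a fixed point (bounded at 20 rounds); (5) cut the patch as the
vertices within `r` of M, again restricted to M's component. Defaults
`r = max(439, 177.5)` and `δ = 100 µm`.

The re-centring in step (4) makes M a genuine local maximum of the surface.
Without it, a seed landing just beyond `r + δ` of a papilla apex claims a
*flank* point as its maximum — the apex is outside the seed's ball — and
during a sweep that flank segment's suppression ball then permanently
blocks the true apex. The annulus of such seeds is larger than the disk of
well-placed ones, so sparse surfaces would systematically lose papillae;
re-centring converges to the apex from both flank captures and filiform
spike tips.

`sweep_surface()` repeats this from random unvisited seed vertices,
suppressing any new maximum within `suppress_r` (= `r`) of an accepted one,
and stops when the seed pool is exhausted, after `max_iterations = 5000`
attempts, or after `stop_after = 100` consecutive attempts that yield no
new maximum. The stopping rule is a package decision: the sweep has no
natural termination criterion, and 100 consecutive failures bounds the
expected number of missed maxima while keeping runtime predictable.

RANSAC hyperparameters (`ransac_params()`): inlier threshold `20 µm` —
well below papilla heights, so papilla flanks never dominate the base-plane
fit — and 1000 random 3-point hypotheses with a final least-squares refit
on the inlier set. The plane normal is oriented toward the mean outward
vertex normal of the component so "above the plane" is well defined.

## Feature families

Twenty features per segment, in three families (`feature_families()`).

**Baseline** — `height_um`: unsigned distance from M to the segment's base
plane. The plane from the extraction step (fitted over the `r + δ` ball) is
reused deliberately: the patch alone (the `r`-ball around M) contains no
base surface for tall papillae, so refitting on the patch would measure the
flank, not the base. `radius_um`: the 90 %-containment radius around M,
grown from 100 µm in 10 µm steps (so quantised to that grid, never below
100 µm).

**Curvature** — discrete Gaussian curvature by angle deficit over mixed
Voronoi areas and mean curvature from the cotangent Laplace–Beltrami
vector, following the Meyer–Desbrun–Schröder–Barr mixed
finite-element/finite-volume discretisation, with the obtuse-triangle area
correction. Mean curvature is signed by the outward vertex normal.
Boundary vertices are excluded from all statistics. Summaries: max/min of
both curvatures, `k_ratio = min(x, y)/max(x, y)` and
`k_positiveratio = x/(x + y)` where `x`, `y` count positively/negatively
curved vertices. On closed meshes the angle-deficit sum reproduces
Gauss–Bonnet (`2πχ`) to 1e-9 relative — this is tested.

**Topological** — Vietoris–Rips persistent homology (dimensions 0 and 1)
of the patch point cloud, subsampled to `topo_subsample` points. Twelve
summaries: short-bar counts (persistence in (0, 10] µm), persistent
entropies, and landscape / image / Wasserstein / bottleneck amplitudes,
each for H0 and H1.

### Numerical choices in the topology stack

* The Rips computation is implemented in C++ inside the package (no TDA
  library is available in this toolchain): H0 by union–find over
  distance-sorted edges (equivalently, single-linkage merge heights), H1 by
  boundary-matrix reduction over GF(2) on triangle columns with a pivot
  map. The test suite checks H0 exactly against `stats::hclust`
  single-linkage heights and H1 against an independent pure-R full
  reduction on small clouds.
* `max_filtration` defaults to the cloud's **enclosing radius**
  (`min_i max_j d(i, j)`). At that scale the Rips complex is a cone, hence
  contractible, so the finite part of the diagram is complete and no
  essential H1 class can be truncated.
* For segment-scale clouds the enclosing radius makes exact reduction
  intractable at 1000 points (the complex is essentially complete, O(n³)
  triangles), so the cohort-study entry points (`assemble_features()` via
  `study_config()`/`run_study()`, `map_papillae()`) cap the filtration at
  **100 µm**. Bars still alive at the cap are censored (dropped from the
  finite diagram); 100 µm is about four mesh pitches, which retains the
  spike-scale H1 structure that distinguishes papilla shapes while cutting
  the triangle count by orders of magnitude. With this cap, a 1000-point
  subsample costs ~0.3 s per segment instead of minutes.
* Persistent entropy is reported in its Shannon form
  `−Σ p_i log p_i ≥ 0` (natural log); `shannon = FALSE` gives the raw
  signed sum.
* The landscape amplitude is the L² norm of the first landscape function
  `λ₁` on a uniform grid of 1000 points (trapezoid rule); a single bar
  `(0, 2s)` reproduces the analytic `s^{3/2}√(2/3)` within 1 %.
* The persistence image uses a 100 × 100 raster in birth–persistence
  coordinates, Gaussian bandwidth `0.1 ×` the coordinate range, and linear
  persistence weighting; the amplitude is the L² norm of the raster.
* Wasserstein amplitude `A_p = (√2/2)(Σ l_i^p)^{1/p}` with `p = 2`;
  bottleneck amplitude is the `p → ∞` limit `(√2/2) max l_i`.

## Classification study

`assemble_features()` builds one row per segment (failed segments are
dropped with a warning); `prune_correlated()` greedily removes features
whose absolute Pearson correlation with an already-kept feature exceeds
0.65, walking the canonical column order, and logs every removal.

`evaluate_task()` runs one of four tasks — papilla `type`
(fungiform/filiform/none), `gender`, `age` group (young ≤ 28 / old ≥ 29),
`participant` — for one feature family and model:

* **SVM-RBF** (`e1071::svm`), cost 1, `gamma = 1/(n_features · var)` on
  z-scored features (the conventional "scale" heuristic).
* **Ridge logistic regression** (`glmnet`, `alpha = 0`) with
  `lambda = 1/n_train`, matching the conventional unit-strength L2
  regularisation of logistic regression at that sample size.

Split schemes: 50 stratified random 80/20 splits, or leave-one-group-out
(LOGO) by participant. The score is **balanced accuracy** (macro-averaged
recall). The participant task cannot be evaluated under LOGO — the held-out
participant's label never occurs in training — so that combination raises
an error and is excluded from `run_study()`'s grid. LOGO folds whose
training rows contain a single class (possible on very small cohorts) are
skipped with a warning.

`permutation_importance()` takes the first split achieving the maximum
balanced accuracy, refits on its training rows, and permutes each feature
of the held-out rows 30 times, recording the mean and sd of the
balanced-accuracy drop (negative drops are possible for irrelevant
features). Family-level relative importances are the positive-part mean
drops aggregated by family and normalised to sum to 1.

`run_study()` chains everything — cohort, sweeps, features, the full task
× family × model × scheme grid, importance, and a papillae map of one
surface — as a pure function of `(config, seed)`, and optionally writes CSV
/ JSON artifacts.

## Determinism

Every stochastic stage consumes a seed derived from one top-level integer
via `derive_seed(seed, offset)` (a fixed affine map modulo 2³¹ − 1), so any
stage can be replayed in isolation and a whole study is reproducible from a
single seed. RNG state is restored after each seeded operation.

## Problem sizes at desk scale

The reference analysis subsamples each segment cloud to
`topo_subsample = 1000` points; the package keeps that subsample size and
makes exact Rips H1 affordable with the 100 µm filtration cap described
above. (An earlier alternative — keeping the full enclosing-radius
filtration but shrinking the subsample to ~120 points — was measured and
rejected: at that sampling density a filiform crown receives only a dozen
points, its loop structure aliases away, and the topological feature family
drops to barely above chance.) Cohorts in the test suite and acceptance
script are reduced to 6 participants × 60 segments (4 × 30 for the
null-effects control) as a compute-budget choice made by this package;
nothing in the implementation depends on the reduced sizes.

## A small worked example

```{r example, message = FALSE}
s <- generate_surface(width = 3000, depth = 3000,
                      counts = c(fungiform = 1, filiform = 4),
                      min_separation = 100, seed = 21,
                      participant = participant_profile("P01", "F", 26))
segs <- label_segments(sweep_surface(s$mesh, seed = 3), s)
tab <- suppressWarnings(assemble_features(segs, topo_subsample = 400,
                                          max_filtration = 100, seed = 5))
dplyr::count(tab, type)
```

```{r diagram}
seg <- segs[[1]]
dg <- rips_persistence(subsample_points(seg$patch$vertices, 100, seed = 1))
ggplot2::autoplot(dg)
```

## Limitations

* Heightfield surfaces cannot represent overhangs or true 3D papilla
  microanatomy; curvature distributions are therefore milder than on real
  scans.
* The effect sizes injected into cohorts are assumptions, not estimates;
  absolute balanced accuracies on synthetic cohorts say nothing about
  accuracies on real data.
* H1 computation is exact but cubic in the subsample size at full
  filtration; large clouds require the filtration cap (which censors
  long-lived bars), and H2 and higher are not computed.
* The RANSAC base plane assumes papillae sit on a locally planar base;
  strongly curved substrates would bias height estimates.
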