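# papillar

Geometric and topological analysis of tongue papillae in 3D surface scans.

The tongue's surface is covered by papillae: large dome-shaped **fungiform**
papillae (diameter ≈ 878 µm) and small crown-shaped **filiform** papillae
(diameter ≈ 355 µm, 100–200 per cm²). High-resolution 3D scans of tongue
impressions make the shape of individual papillae measurable, and that shape
carries signal: it differs between papilla types and varies with the
person's gender, age, and identity. `papillar` implements the full analysis
pipeline for such data on triangulated meshes (coordinates in micrometres):

* **Synthetic surfaces with ground truth** — real scan datasets of this kind
  are rarely public, so the package generates undulating tongue-like sheets
  bearing planted fungiform/filiform papillae, measurement noise, and
  participant-level effects (sharper papillae for female and younger
  synthetic participants), with exact annotations riding along.
* **Segment extraction** — RANSAC base-plane fitting and local-maximum
  detection cut disk-like candidate patches out of a surface; a sweep with
  duplicate suppression maps a whole surface.
* **Three feature families per segment** — baseline (height above the base
  plane, 90 %-containment radius), discrete curvature (angle-deficit
  Gaussian and cotangent mean curvature with mixed Voronoi areas), and
  topological (Vietoris–Rips persistent homology in dimensions 0/1,
  summarised by short-bar counts, persistent entropy, and landscape /
  image / Wasserstein / bottleneck amplitudes). The Rips computation is
  implemented in C++ inside the package and tested against independent
  oracles.
* **Interpretable classification studies** — papilla type, gender, age
  group, and participant identity, with SVM-RBF and ridge logistic
  regression, balanced accuracy over repeated stratified splits or
  leave-one-participant-out folds, correlation pruning at 0.65, and
  permutation feature importance.
* **Papillae mapping** — a trained type classifier turns a sweep of a new
  surface into a "tongue print": positions and types of all detected
  papillae.

Everything is tibble-first: feature tables are tibbles, fitted objects have
`tidy()`/`glance()` methods, and result objects have `autoplot()` methods.

## Worked example

```r
library(papillar)

# a 3 x 3 mm synthetic patch: 1 fungiform + 4 filiform papillae
s <- generate_surface(width = 3000, depth = 3000,
                      counts = c(fungiform = 1, filiform = 4),
                      min_separation = 100, seed = 21,
                      participant = participant_profile("P01", "F", 26))
s
#> <annotated_surface> 3.0 x 3.0 mm, pitch 25 um, noise sd 2 um
#>   5 planted papillae (1 fungiform, 4 filiform)
#> <tri_mesh> 14641 vertices, 28800 triangles, 43440 edges
#>   bbox [um]: x -0.2..3000.2  y -0.2..3000.2  z -30.6..299.4

# sweep the surface for candidate segments and label them from ground truth;
# every planted papilla is claimed by exactly one segment
segs <- label_segments(sweep_surface(s$mesh, seed = 3), s)
tab  <- assemble_features(segs, topo_subsample = 400, max_filtration = 100,
                          seed = 5)
dplyr::count(tab, type)
#> # A tibble: 3 × 2
#>   type          n
#>   <chr>     <int>
#> 1 filiform      4
#> 2 fungiform     1
#> 3 none         14

dplyr::select(tab, type, height_um, radius_um, gauss_max, entropy_h1) |>
  dplyr::slice_head(n = 4)
#> # A tibble: 4 × 5
#>   type     height_um radius_um gauss_max entropy_h1
#>   <chr>        <dbl>     <dbl>     <dbl>      <dbl>
#> 1 none         11.6        420  0.000261       4.96
#> 2 none          5.67       420  0.000424       5.42
#> 3 filiform    284.         430  0.00157        5.11
#> 4 none         12.1        420  0.00118        4.56

# classify papilla type from all features, 10 stratified 80/20 splits
ev <- evaluate_task(tab, task = "type", family = "all", model = "svm",
                    scheme = "random", n_splits = 10, seed = 7)
ev
#> <papilla_eval> task type | all features | SVM | random
#>   balanced accuracy 1.000 +/- 0.000 over 10 splits (n = 19)

# map the surface with a trained classifier ("tongue print")
clf <- train_type_classifier(tab, model = "svm")
map_papillae(s, clf, topo_subsample = 400, seed = 9, surface_id = "P01")
#> <papillae_map> P01: 4 detections from 19 candidate segments
#>   filiform: 3
#>   fungiform: 1
```

(The perfect split accuracy above is what a 19-segment toy table buys you;
see `run_study()` for cohort-scale evaluations with honest variance, and
`vignette("papillae-methods")` for every modelling and numerical choice.)

A full study — cohort generation, sweeps, features, the task × family ×
model × scheme grid, importance, and a map — is one call:

```r
st <- run_study(study_config(n_participants = 6), seed = 1,
                out_dir = "study-artifacts")
st$results          # balanced accuracies per evaluation
tidy(st$importance) # permutation importances
```

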