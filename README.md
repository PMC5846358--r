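# daphtrack

Quantitative analysis of swimming behavior for aquatic biomonitoring with
*Daphnia magna*. Given 2-D video-tracking coordinates of individual animals
recorded at a fixed frame interval (0.25 s) in a small observation arena
(60 mm × 50 mm by default), the package quantifies how behavior changes
between a pre-treatment and a post-treatment recording — the typical design
when an indicator organism is exposed to a chemical stressor and its
movement is used as an early-warning endpoint.

Two complementary time scales are analyzed:

* **Long windows (10 min): movement complexity.** Each window's trajectory
  is rasterized onto an *M* × *M* binary grid (*M* a power of 2) and its
  **box-counting fractal dimension** is estimated as the least-squares slope

  D = slope of log N(δ) versus log(1/δ),

  where N(δ) is the number of δ×δ grid boxes visited by the track. For
  planar tracks D runs from 1.0 (a straight path) to 2.0 (a path covering
  the arena evenly), so a drop in D indicates reduced, more localized
  movement.

* **Short segments (5 s): movement patterns.** Seven instantaneous
  parameters are computed per segment — speed (mm/s), acceleration
  (mm/s²), locomotory rate (mm/s; distance over *moving* time only), stop
  number, stop time (s), turning rate (rad/s) and meander (rad/mm). The
  min-max normalized feature vectors train a sequential **Kohonen
  self-organizing map**: each presented vector x selects the best-matching
  node c by Euclidean distance d_j = Σᵢ (xᵢ − w_ij)², and every node is
  updated by

  w_ij ← w_ij + α(t) · h_cj(t) · (xᵢ − w_ij),

  with a Gaussian lattice neighborhood h around the winner and linearly
  decaying α and neighborhood radius σ. **Ward clustering** of the trained
  codebook cuts the map into six canonical movement patterns — P1 line,
  P2 loop, P3 cross, P4 shaking, P5 swirl, P6 stay — named automatically
  from their denormalized parameter profiles.

Per-subject endpoint means (each movement parameter, the windowed fractal
dimension, and each pattern's percentage) are compared across phases with
one-tailed **paired t-tests** (df = n − 1 subjects).

Because raw tracking data of this kind are rarely published, the package
includes a seeded correlated-random-walk generator that emulates the study
design: six movement archetypes, 5-s blocks drawn from per-phase pattern
compositions, specular reflection at the arena walls, and ten subjects
recorded before and after treatment.

## Worked example

```r
library(daphtrack)

# one synthetic 5-s "swirl" segment and its seven parameters
seg <- generate_segment(archetype_params("swirl"), seed = 42)
round(compute_features(seg), 3)
#>           speed    acceleration locomotory_rate     stop_number       stop_time
#>           1.504           2.059           1.667           1.000           0.500
#>    turning_rate         meander
#>           2.800           1.862

# a full synthetic study: 10 subjects x 2 phases x 1 h, then the pipeline
study <- default_study(seed = 1)
res <- analyze_study(study, seed = 1)
res$report
```

The report prints per-subject phase means and paired one-tailed t-tests.
With seed 1 the treated phase shows the full signature of a stressed
animal: mean speed falls from 4.56 to 3.50 mm/s (t = 23.1, df = 9), the
mean 10-min fractal dimension falls from 1.584 to 1.521 (t = 12.6), the
linear pattern P1 drops from 25.7% to 17.7% of segments and the stop
pattern P6 rises from 15.4% to 21.9%, every endpoint significant at
p < 0.01:

```
Fractal dimension (10-min windows, per-subject means):
          endpoint mean_before sd_before mean_after sd_after      t df        p
 fractal_dimension       1.584     0.013      1.521    0.019 12.604  9 2.53e-07

Pattern percentages (per subject, paired across phases):
 endpoint mean_before sd_before mean_after sd_after       t df        p
       P1      25.694     2.066     17.708    1.815  10.793  9 9.45e-07
       ...
       P6      15.431     1.264     21.944    1.364 -11.233  9 6.74e-07
```

Individual stages are available as plain functions: `read_track()` /
`write_track()` (CSV `frame,t_s,x_mm,y_mm`), `segment_track()`,
`compute_features()` / `build_feature_matrix()`, `rasterize()` /
`box_counts()` / `fit_dimension()` / `track_fractal_dimension()`,
`normalize_features()` / `train_som()` / `ward_cluster()` /
`name_patterns()` / `classify_segments()`, `composition()` /
`paired_t_test()` / `compare_phases()`. Trained maps serialize with
`write_som()` and the Ward tree exports as Newick via
`export_dendrogram()`.

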