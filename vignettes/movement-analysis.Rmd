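---
title: "Movement complexity and movement patterns of Daphnia tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement complexity and movement patterns of Daphnia tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphtrack)
```

## The problem

Small crustaceans such as *Daphnia magna* respond to sublethal chemical
stress by changing how they swim long before mortality endpoints react.
A video-tracking system records one animal per arena at 4 frames/s; the
analysis task is to turn the resulting coordinate stream into
interpretable, statistically testable endpoints for a paired
before/after-treatment design. `daphtrack` implements that analysis at two
time scales: 10-minute windows summarized by a box-counting fractal
dimension (overall movement complexity), and 5-second segments classified
into six canonical movement patterns by a self-organizing map (SOM) with
Ward clustering.

## Data model and segmentation

A track is a strictly uniform time series of positions (mm) in a
rectangular arena, 60 mm × 50 mm by default, origin at the lower-left
corner. The frame interval defaults to 0.25 s; behaviors faster than one
frame (e.g. sub-frame trembling) are outside the model's resolution, and
tracking dropouts are treated as validation errors rather than imputed,
since the upstream recognition system reports continuously.

A window of `window_s` seconds spans `window_s/dt` inter-frame *intervals*
and hence `window_s/dt + 1` frames: a 5-s window holds 21 frames. Windows
advance by whole intervals, so adjacent windows share their boundary frame
while every interval — and therefore every millimetre of path — belongs to
exactly one window. A trailing partial window is discarded. Both 5-s and
600-s windows are consecutive by default; nothing in the implementation
requires them to be (any list of segments can be assembled by the caller),
but consecutive windows are the natural reading of a continuous recording.

## The seven movement parameters

Per 5-s segment, from the per-interval step geometry (distance, heading by
`atan2`, step speed):

| parameter | definition | units |
|---|---|---|
| speed | total path length / elapsed time | mm/s |
| acceleration | mean \|Δ step speed\| / frame interval | mm/s² |
| locomotory rate | path length over moving steps / moving time | mm/s |
| stop number | count of maximal runs of stopped steps | – |
| stop time | stopped steps × frame interval | s |
| turning rate | Σ \|wrapped heading change\| / elapsed time | rad/s |
| meander | Σ \|wrapped heading change\| / path length | rad/mm |

A step is *stopped* when its speed falls below a configurable threshold,
default 1.0 mm/s — roughly one pixel of tracking jitter per frame for this
kind of system; the threshold is the `stop_speed_threshold` argument
throughout. The locomotory rate excludes stop time from its denominator,
so it is never below speed when stops occur. Three aggregation choices are
deliberately conservative:

* acceleration is reported as the mean *absolute* per-step speed change,
  because the classifier needs one non-negative scalar per segment;
* turning is accumulated as absolute wrapped angle (range (−π, π]), so
  turning rate and meander are magnitudes — direction of rotation is not an
  endpoint;
* a zero-length step has no heading; heading changes touching such a step
  contribute zero turn rather than propagating missing values, which keeps
  the feature matrix dense.

All seven features are invariant under rigid motion of the segment (tested
to 1e-9).

## Box-counting fractal dimension

Each 10-min window is rasterized onto an M × M binary grid (default
M = 256) with one isotropic scale `(M − 1)/max(width, height)` anchored at
the arena origin — a non-square arena is never stretched, which would
distort headings and the fitted dimension. Because 0.25-s samples of a
few-mm/s swimmer are disconnected dots whose fine-scale counts collapse,
the pixels along the straight line between consecutive samples are filled
by default (`raster_mode = "lines"`), giving an 8-connected curve;
`"points"` mode is available for sensitivity checks.

Boxes of side δ (pixels) partition the grid anchored at the origin; N(δ)
counts boxes containing at least one occupied pixel ("at least one" is the
standard box-counting rule). The schedule is dyadic, δ ∈ {2, 4, …, M/2},
the natural choice when M is a power of 2; at M = 256 the finest box spans
≈ 0.47 mm in the default arena, below a typical per-frame displacement, so
at least three informative scales remain. The dimension is the ordinary
least-squares slope of log N(δ) on log(1/δ).

Two kinds of scale carry no information and are excluded before fitting:
N = 1 (the whole object inside one box) and fully saturated
N = (M/δ)² scales. A genuinely space-filling image saturates *every*
scale; in that single case the filter would discard everything, so the fit
falls back to the unfiltered points, which lie exactly on a slope-2 line.
Fewer than three usable points in any other configuration is an error.
Calibration: a straight diagonal track fits D = 1.036 and a boustrophedon
sweep of the whole arena fits D = 2.000 at M = 256 (the acceptance script
recomputes both), and a depth-7 Sierpinski raster recovers
log 3/log 2 ≈ 1.585.

## Self-organizing map and pattern naming

Features are min-max normalized to [0, 1] per parameter; the training
minima/maxima are stored in the model so held-out segments are scaled with
the *training* statistics and the transform inverts exactly. Min-max (as
opposed to z-scoring) matches the usual normalized-component-plane
presentation of SOM studies.

Training is the classical sequential Kohonen procedure on a rectangular
8 × 8 lattice (64 nodes comfortably over-provisions six clusters for the
~2000 training segments of a two-phase study): squared-Euclidean winner
search with lowest-index tie-breaking, then

w_ij ← w_ij + α(t) · exp(−d²(c, j) / 2σ(t)²) · (xᵢ − w_ij)

for every node j, where d(c, j) is Euclidean distance on the lattice. The
Gaussian neighborhood is the canonical way to realize "the winner and its
close neurons are updated"; squared distance is used for the winner search
since argmin is invariant to the square root. α decays linearly from 0.5
to 0.01 and σ from max(R, C)/2 to 0.5 over the total number of
presentations (epochs × n, default 10 epochs); presentation order is a
fresh seeded permutation per epoch and initialization samples distinct
data rows, so training is bit-for-bit reproducible for a fixed seed.

The final radius of 0.5 deserves a note: it makes the last phase of
training effectively winner-only. Ending at σ = 1 instead leaves a
substantially smoothed codebook in which many nodes sit between classes
and never win a segment; Ward's k = 6 cut then tends to spend clusters on
those interpolation bands and to merge the two fastest patterns. With
σ → 0.5 the codebook tracks the data structure closely enough that the cut
recovers the planted six-class structure across seeds (held-out agreement
≥ 0.98 in the validation suite).

Ward linkage (`hclust`, `ward.D2`, Euclidean) clusters the 64 codebook
vectors — not the raw segments — keeping the dendrogram readable at 64
leaves; it is exportable as Newick. The cut at k = 6 is then *named*
deterministically from denormalized cluster profiles, replacing the visual
inspection such studies traditionally use: P1 (line) takes the cluster
with the highest mean speed, P6 (stay) the highest stop time among the
rest, P3 (cross) the highest acceleration among the rest, and the
remaining three are ordered by decreasing speed as P2 (loop), P4
(shaking), P5 (swirl). Exact ties abort with a request for manual
assignment rather than guessing.

Classification of any segment is: normalize with stored statistics → find
the best-matching node → report its cluster's pattern name.

## Statistical comparison

Every endpoint is reduced to one value per subject per phase (mean
parameter, mean windowed D, pattern percentage of that subject's
segments), and phases are compared with the classical paired t statistic
t = mean(d)/(sd(d)/√n), d = before − after, df = n − 1 — so a ten-subject
study always tests at df = 9, including the per-pattern proportion tests.
Directions are declared a priori and fixed in the defaults: activity
endpoints (speed, acceleration, locomotory rate, fractal dimension, P1–P3
shares) are tested for a decrease, and turning, stopping and P4–P6 shares
for an increase, the canonical stress signature. One-tailed p-values come
from the t distribution. No multiple-testing correction is applied by
default, matching single-endpoint reporting conventions; a Bonferroni
option exists for the pattern family. The implementation is the textbook
formula rather than a wrapper, and is verified against `t.test()` to 1e-9
in the test suite.

## The synthetic generator

Since tracking data of this kind are not generally released, validation
runs on a correlated random walk with six archetype parameter sets
(per-step truncated-Gaussian speed; heading increments with fixed,
alternating or zero-mean random sign; an optional contiguous forced-stop
bout). Sessions chain 5-s blocks drawn from a per-phase pattern
composition with pose continuity, so ground-truth labels map one-to-one
onto analysis segments. Wall handling is pure specular reflection
(a triangle-wave fold of the unfolded trajectory, an isometry of path
length); no boundary-specific behavioral state is modelled.

The default study is 10 subjects × 2 phases. The composition anchors are
the published shift for a 10 mg/L toluene exposure — P1 25.4% → 17.1%,
P6 14.7% → 22.5% — with the unpublished P2–P5 values chosen once to
complete each composition (before: 23.0/18.0/10.0/8.9%; after:
15.0/12.0/15.0/18.4%) while preserving the reported directions. A small
additive jitter (sd 0.008) individualizes subjects. Archetype kinematics
are calibration choices, not published facts: they are set so that phase
mean speed (≈ 4.6 → 3.5 mm/s) and turning rate sit in the reported
few-mm/s and few-rad/s ranges and so that the six classes are separable in
feature space (nearest-centroid recovery ≥ 90%, a prerequisite for any
clustering to be assessable). Key values: line 8.2 mm/s nearly straight;
loop 5.8 mm/s at 3 rad/s fixed-sign; cross 4.6 ± 2.2 mm/s with 3.5 rad/s
random-sign turns (the high-acceleration class); shaking 2.6 mm/s
alternating ± 8 rad/s; swirl 1.6 mm/s at 3 rad/s fixed-sign; stay
0.12 mm/s with an 85% stop bout.

The default session length is 1 h (720 segments, 6 fractal windows per
subject), which keeps a full pipeline run around ten seconds while leaving
every per-subject estimate well resolved; the original 24-h design is
available via `duration_s = 86400`.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: tracking noise and dropout, gradual or
time-varying intoxication (phase compositions are stationary), behavioral
autocorrelation beyond 5-s blocks, wall-following and other boundary
states, and any 3-D component of swimming. The pipeline's recovery of the
planted structure validates the *computation*, not the biology.

## Numerical choices and edge cases

* Rounding in rasterization is half-up (`floor(x + 0.5)`), not banker's
  rounding, for determinism across platforms.
* A motionless segment has speed 0, one stop bout spanning the segment,
  and meander defined as 0 (no path length); a segment whose steps are all
  stopped has locomotory rate 0.
* Degenerate t-tests (zero variance of differences) are errors, not NaN.
* `fit_dimension` requires ≥ 3 usable scales and names the saturation
  filter in its error.
* All randomness is seed-controlled; `default_study`, `train_som` and the
  subsamplers take explicit seeds and reproduce bit-identically.

## Limitations

Pattern naming assumes the six planted profiles; on real data with
different cluster structure the profile-ranking rule may need manual
override. The fractal estimate depends on M, the δ schedule and the fit
range — all exposed as arguments — and on line interpolation; estimates
from different settings should not be compared directly. The SOM is a
plain rectangular-lattice sequential implementation: batch training,
hexagonal or toroidal lattices and automatic cluster-count selection are
out of scope (k is fixed at 6).
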