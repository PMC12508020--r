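---
title: "Movement-tracking analysis with movetrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-tracking analysis with movetrack: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In movement-tracking (mouse-, finger- or hand-tracking) experiments,
participants choose between two response options by moving a pointer from a
start position to one of two boxes while the position is recorded at a high,
roughly constant rate (typically every 10 ms). The recorded trajectory is
taken to carry a trace of the underlying decision process: when both options
attract the response simultaneously, movements curve toward the nonchosen
option, reverse direction, or stall. `movetrack` implements the full
processing and analysis chain for such data: import, spatial transformation,
resampling, per-sample kinematics, trial-level indices, homogeneity
diagnostics, type-based analyses, and temporal-dynamics analyses, together
with a synthetic generator that produces datasets with known ground truth.

```{r, eval = FALSE}
library(movetrack)
sim <- generate_tracking_data(synth_spec(seed = 1))
ds  <- time_normalize(align_start(remap_symmetric(sim$data)))
measures <- add_sample_entropy(ds, measures = compute_measures(ds))
```

## Data model

A `track_data` object couples a trial-level metadata table (one row per
trial, keyed by `trial_id`) with named *representations*: 3-D numeric arrays
`[trial x point x feature]`. Features always include `timestamps` (ms),
`xpos` and `ypos` (px); derived channels (`dist`, `vel`, `acc`, `angle_v`,
`angle_p`) are appended by the kinematics operations. Trials differ in
length, so arrays are padded with `NA` beyond each trial's last sample --
never with zeros, since zero is a legal coordinate. Every operation appends
one provenance record and returns a new container.

Conventions fixed at import: timestamps are shifted so each trial starts at
0 (trajectory indices are trial-relative); the y axis points up
(`screen_y_down = TRUE` negates screen coordinates at the boundary); trial
ids are the id-column values joined with `"_"`; duplicate timestamps within
a trial keep the first sample, with a warning.

## Spatial transformation and resampling

`remap_symmetric()` mirrors trajectories about the vertical through their
start so all movements end on one side; the side of a trial is the x sign of
its last point relative to its first, and an exact tie counts as already on
the target side (deterministic, logged, idempotent). `align_start()`
translates rigidly; `align_start_end()` additionally rescales per axis,
which distorts the pixel metric and is therefore never applied silently.

Three resampling modes, all piecewise linear (endpoints preserved exactly):

* **time normalization** (default 101 steps): temporally equidistant points
  spanning the trial's duration; step *k* means "fraction *k*/100 of the
  trial" and is the basis of all per-step analyses;
* **length normalization** (default 20 points): points equidistant in arc
  length along the x/y polyline, with timestamps interpolated in arc
  length; this weights all parts of the movement equally and is the basis
  of shape comparisons (distance matrices, prototype mapping). Note that
  equal *arc* spacing implies equal chord spacing only where the path is
  locally straight; on realistic, smoothly sampled movements the resampled
  polyline conserves path length to well under 0.5%;
* **constant interval**: timestamps at multiples of `interval_ms`, with the
  final timestamp appended when the grid misses it; a 2-s trial at 10 ms
  yields 201 positions, mirroring a 100-Hz recording.

## Trial-level indices

Curvature is measured against the *idealized trajectory*, the straight
segment from the trial's first to its last point. Pointwise deviations are
perpendicular distances to that segment, signed positive toward the
nonchosen side -- the horizontal side opposite the endpoint, i.e. positive x
after left-remapping (for a purely horizontal ideal line, "above" is taken
as positive). From these, `compute_measures()` derives MAD (the deviation of
maximal absolute value, sign kept, earliest point on ties, with its
timestamp), MD_above (largest deviation toward the nonchosen side, floored
at 0), AD (mean signed deviation over all recorded points), and AUC (signed
shoelace area between trajectory and ideal segment, chosen-side area
subtracted). Deviations are evaluated at recorded points only, on whichever
representation is passed in (raw by default).

Complexity: `x_flips`/`y_flips` count sign alternations among successive
coordinate deltas after discarding deltas of magnitude `<= flip_threshold`
(default 0 -- zero deltas never count as direction changes); `x_reversals`
counts strict sign changes of x relative to the start x, skipping samples
exactly on that midline. Sample entropy is `-log(A/B)` with `B` the number
of ordered pairs of distinct `m`-length templates at Chebyshev distance
`<= r` and `A` the same for length `m + 1`; defaults are the
literature-standard `m = 3`, `r = 0.2` SD of the analyzed series, computed
on x positions of time-normalized trajectories. Self-matches are excluded;
when no template pair matches (possible for short, noise-like series) the
value is undefined and returned as `NA` with a warning.

Temporal: `RT = t_last - t_first`; `movement_time` sums inter-sample
intervals with displacement beyond `jitter_tol` (default 0, exact position
change); `idle_time = RT - movement_time`; `initiation_time` is the
timestamp of the last sample still at the start position before the first
displacement -- i.e. the idle duration before movement onset -- with the
alternative convention (first moved sample) behind a flag;
`motor_pauses = idle_time - initiation_time`. These identities hold exactly
by construction. `vel_max`/`acc_max` are reported when `add_derivatives()`
channels are present.

Kinematic channels use explicit stencils: `dist[i]` is the Euclidean step
from sample `i - 1`; `vel = dist/dt` is unsigned speed; `acc` is the forward
difference of velocity, undefined at the first and last sample. `angle_v` is
the signed angle of each segment against the vertical, positive toward
negative x (toward the chosen option after left-remapping), range
`(-pi, pi]`; `angle_p` is the interior angle at each point, `pi` for
collinear continuation. A segment of 90 degrees to the left is `+pi/2` --
angles are plain radians throughout.

## Homogeneity diagnostics

Index-based analyses presume trajectories of one common kind; two
diagnostics and two visual tools probe that assumption.

The bimodality coefficient is `(g1^2 + 1) / (g2 + 3(n-1)^2/((n-2)(n-3)))`
with finite-sample corrected skewness `g1` and excess kurtosis `g2`; its
analytic anchors are 1/3 for a normal sample, 5/9 for a uniform one, and 1
for a symmetric two-point mass. The conventional 5/9 reading threshold is
documented but never applied automatically.

Hartigan's dip statistic -- the maximal distance between the empirical CDF
and the closest unimodal CDF -- is computed by the classical iterative
greatest-convex-minorant / least-concave-majorant refinement. It is bounded
below by `1/(2n)` (a two-point sample attains 0.25 exactly) and is invariant
under affine transforms of the values; it is *not* invariant under arbitrary
monotone transforms, because nonlinear reparameterization does not preserve
unimodality. An optional bootstrap p-value resamples from the standard
uniform null, the usual calibration, and requires a seed.

`density_grid()` rasterizes trajectories after resampling each polyline at a
constant arc-length step no larger than one grid cell, so intensity measures
line coverage rather than sampling rate. Smoothing distributes each cell's
mass over a clipped, renormalized Gaussian (SD = `smooth_radius/2` cells),
which conserves total mass exactly at any radius. `diff_grid()` subtracts
unit-mass-normalized grids and optionally quantizes to `n_shades` signed
levels.

## Type-based analysis

The trajectory distance is the pointwise sum
`d[i,j] = sum_k sqrt((x[i,k]-x[j,k])^2 + (y[i,k]-y[j,k])^2)`, computed on a
representation with equal point counts (length-normalized, 20 points, by
convention).

*Bottom-up*: agglomerative hierarchical clustering with `ward.D` linkage
(delegated to `stats::hclust`, which is deterministic given the distance
matrix), cut at 5 clusters by default; labels are relabeled by descending
cluster size and each cluster is summarized by the pointwise mean of its
members. Clustering is an exploration tool: it depends on the data at hand
and tends to split dominant types rather than isolate rare ones.

*Top-down*: trajectories are mapped to the nearest of five canonical
prototypes ordered by the response competition they reflect: straight (1),
curved (2), continuous change of mind cCoM (3), discrete change of mind
dCoM (4), and double discrete change of mind dCoM2 (5). The exact vertices
of the published reference set are not available, so the package declares
its own canonical polylines in a unit space from (0,0) to (-1,1.5) --
straight segment; quadratic arcs through (+0.25,0.75) and (+0.6,0.9); corner
paths through (+1,1.5) and through (-0.5,0.75),(+0.7,1.3) -- fully
documented and overridable; borderline assignments on real data may differ
from other reference sets. Per trial, each prototype is rescaled (one affine
map per axis) onto the trial's start/end, both curves are length-normalized
to 20 points, and the minimal distance wins, ties going to the lower rank.
This per-trial rescaling (rather than projecting trials into prototype
space) keeps the mapping invariant under rigid transforms of the data.

Frequencies of mapped types per condition are tested with the Pearson
chi-square test of independence without continuity correction (the residual
convention `(O - E)/sqrt(E)` satisfies `sum(residuals^2) = chi2` exactly);
`ordinal_types()` exports rank-coded assignments for external ordinal
regression -- model estimation is deliberately out of scope.

The same machinery drives outlier screening: trials whose distance to their
closest prototype exceeds 2 SDs within the mapped group
(`flag_outliers_by_prototype()`) are flagged as anomalous rather than
silently dropped.

## Temporal dynamics

`step_aggregate()` reduces a time-normalized feature channel to per-step
group means, SDs and counts. `step_tests()` fits an ordinary linear model at
every step; with a subject column it reports CR1 cluster-robust standard
errors with a t(G-1) reference. This single-level approach is a deliberate
substitute for per-step mixed models, whose estimation the package delegates
to dedicated statistical tooling via tidy exports: per-step mixed models
inherit all multiple-testing fragility of the step-by-step idea, and a joint
model is the statistically sound alternative. Steps significant at `alpha`
(default .05) are screened into maximal runs, and runs shorter than
`min_run` (default 10 of 101 steps; the consecutive-significance heuristic
is cited in the literature without a number) are suppressed. Two caveats are
worth stating plainly: adjacent steps share data, so per-step p-values are
strongly autocorrelated -- under the null, isolated runs of ten or more
significant steps still occur in roughly a tenth of replicates, which is why
run screening is a heuristic and not an error-rate guarantee; and the
per-step false-positive *rate* is calibrated (0.05 within Monte-Carlo error
in the package's own 200-replicate null calibration at 30 subjects).

`stratified_step_aggregate()` re-runs the aggregation within response-time
strata (e.g. 0-1500, 1501-2500, 2501-5000 ms, excluding slower trials) so
that effects expressed on the normalized time axis can be checked where
absolute durations are comparable. `type_kinematic_profiles()` crops leading
samples still at the start and trailing stationary samples, computes
velocity/acceleration on the raw samples, time-normalizes them, smooths with
a reflected-boundary Gaussian (SD 2 steps by default; 0 disables), and
averages per assigned type; discrete change-of-mind types show interior
velocity dips near zero where submovements pause.

## The synthetic generator

`synth_spec()`/`generate_tracking_data()` emulate a two-option forced-choice
categorization study: 60 subjects x 19 trials (10 "typical", 9 "atypical"),
start at the bottom center, chosen option at (-665, 974) px, 100-Hz
sampling, per-trial sample counts clamped to 72-2159. Each trial draws a
movement type from its condition's mixture -- by default the observed
worked-example proportions, 506:116:54:52:16 (typical) and 165:38:37:56:24
(atypical), so the atypical condition shifts mass from straight toward
change-of-mind types -- and traverses the scaled prototype path with one
minimum-jerk (bell-speed) submovement per path leg. Discrete types pause
between legs (truncated normal, mean 150 ms, floor 20 ms). Pre-movement idle
is lognormal (median 250 ms); total movement time is lognormal (median
1.1 s) scaled by relative path length, which makes change-of-mind trials
naturally slower (typical/atypical median RTs land near the 1.5 s / 2 s
reported for real data). Isotropic Gaussian noise (default SD 8 px, a
realistic pointer jitter on a full-HD screen) is added to *moving* samples
only; an idle physical pointer reports literally constant coordinates, which
keeps initiation/idle measures exact. Timestamps get uniform jitter
(default 1 ms) on interior samples.

What the generator does *not* emulate: autocorrelated sensor noise, device
quantization, within-subject style differences (no subject random effects),
dynamic re-planning beyond the fixed prototype paths, and the real data's
extreme slow tail (its maximum duration clamp of 21.6 s is essentially never
reached by the lognormal). Passing tests therefore demonstrate algorithmic
correctness and sensitivity under controlled conditions, not distributional
fidelity to any particular experiment.

`inject_step_effect()` adds a condition shift to a feature inside a known
step window, giving per-step tests a programmed ground truth.

## Numerical choices and problem sizes

Interpolation is piecewise linear everywhere; equality assertions use 1e-9
absolute tolerance; index computations are validated against brute-force
oracles (projection geometry, trapezoidal integration, linear scans, naive
template counting) on 1000 randomized trajectories at 1e-6 relative
tolerance. Type-recovery checks use ~500 trials at noise SD 4 px; the null
calibration of per-step tests uses 200 replicates of 30 subjects x 10 trials
at 20-ms sampling; bimodality limits use samples of 1e5. These sizes are the
package's validation design and run comfortably on one CPU.

## Known limitations

* The canonical prototype vertices are this package's reconstruction from
  verbal/graphical descriptions; absolute agreement with other
  implementations' borderline assignments is not guaranteed.
* Mixed-effects and ordinal model estimation is out of scope by design; the
  package exports model-ready tables instead.
* `step_tests()` treats steps separately; joint inference across steps is
  explicitly not provided.
* The dip statistic's bootstrap p uses the uniform null; for heavily tied
  data the statistic sits at its lower bound and the p-value is
  uninformative.
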