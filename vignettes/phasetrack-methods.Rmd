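---
title: "Methods: automated tracking of slow-moving cells and the choice of the acquisition interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tracking of slow-moving cells and the choice of the acquisition interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasetrack)
```

## The problem

Phase-contrast time-lapse microscopy is the workhorse for watching adherent
cells migrate: it is label-free and uses an order of magnitude less light
than fluorescence, so cells can be imaged for a day with little
photodamage. Automated analysis of such film has two stages: *segmentation*
(separating moving foreground from static background in each frame) and
*particle tracking* (reducing each segmented object to its centroid and
linking centroids across frames into trajectories). The central
experimental variable this package is built around is the **time step
interval** — the time between consecutive acquisitions. Short intervals
make linking easy (cells barely move between frames) but expose cells to
more light and produce enormous datasets; long intervals are gentle and
cheap but degrade tracking. `phasetrack` implements the full pipeline, a
systematic sweep over intervals, and a closed-loop controller that adapts
the interval to the observed tracking quality.

The cells of interest are slow-moving adherent lines (fibrosarcoma
HT1080, normal human keratinocytes): mesenchymal migration at roughly one
cell-body length per hour, i.e. under 1 µm/min, imaged at 4× (1.61 µm/px)
every 30 s. Phase contrast gives these cells a bright halo around the rim
while the interior can flip between dark and bright — both properties
drive the design of the two segmentation backends.

## Segmentation

**Edge detection + active contour** (`detect_edges()`,
`evolve_contours()`). Gradients of the Gaussian-smoothed frame (Sobel
operators, scale `sigma = 2` px) are thresholded with hysteresis at the
0.80/0.95 magnitude quantiles. The resulting edge map seeds a two-phase
piecewise-constant (Chan–Vese-style) region evolution. Two numerical
choices matter:

* the evolution runs on `|I - median(I)|` rather than on `I`, so dark and
  bright interiors are both "object-like" relative to the dominant
  background grey; interior holes are filled at the end. This is what
  absorbs intensity flips inside a closed contour.
* regularisation is a morphological closing with a disc of radius
  `2 * smoothing` applied each iteration. Like a curvature penalty it
  keeps the front from threading the narrow gap between near-touching
  cells. The documented failure mode of this backend is therefore
  *under*-segmentation: cells closer than about `4 * smoothing` px merge
  into one object.

The evolution is global per frame (one two-phase partition), not one
contour per object; with the edge-seeded initialisation and the front
restricted to ±1 px per iteration the result behaves like per-object
contours while remaining cheap and deterministic.

**Background reconstruction + subtraction** (`reconstruct_background()`,
`subtract_and_threshold()`). The static background is estimated per pixel
as the *temporal mode* of the intensity across all frames: because cells
move and the culture is sparse, the most frequent value at a pixel is the
background (or a stationary artefact, which may be treated as
background). Ties take the smallest intensity, making the estimate
deterministic; 16-bit data with more than 4096 distinct levels fall back
to 256 equal-width bins. Foreground is `|frame - background| > tau`, with
the absolute value again covering dark and bright interiors. The default
`tau` is 3× a robust noise estimate (1.4826 × median absolute
frame-minus-background residual). This backend *over*-detects: an
elongated cell whose mid-section matches the background splits into
fragments, so counts at most double the true cell number on clean scenes.
No morphological clean-up is applied; small fragments are left to the
shared area filter.

The temporal mode has one practical failure worth knowing about: a cell
that does not vacate its own footprint for more than half the sequence is
absorbed into the background, and only its moving rim is detected. For
diffusive slow cells this matters on short clips; the interval sweep
therefore reconstructs the background once from the **full** acquisition
(all stored frames) and reuses it at every subsampled interval, which both
matches the "all frames" definition and maximises the number of looks per
pixel.

## Tracking

`mask_to_objects()` labels 8-connected components (halo pixels touching
diagonally belong together), discards components outside the area bounds
(default 20–5000 px², removing noise specks and merged-sheet artefacts),
and takes the unweighted pixel centroid.

`link_frames()` implements the greedy global-minimum linker. Given the
centroid sets of two consecutive frames it forms the `N_A x N_B`
Euclidean distance array and recursively: links the globally smallest
entry, deletes its row and column, and stops when the smallest remaining
distance exceeds the plausibility threshold `D`. This is deliberately
*not* an optimal-assignment solver — it encodes the assumption that a
cell moves to the closest target within its vicinity, and the test suite
pins this semantics against a literal re-sort-every-step oracle,
including an instance where the greedy total (6 px) exceeds the optimal
assignment (4 px). Ties take the lexicographically smallest `(i, j)`;
determinism is required for reproducible runs.

`D` scales with the interval through `threshold_rule()`: 10 px at 30 s
rising to 50 px at 15 min. Only the two anchors are physically motivated
(≈16 µm and ≈83 µm at 1.61 µm/px); the linear interpolation between them
is a modelling choice — any monotone rule through the anchors would do.

Trajectories are chains of links (`build_trajectories()`): every object
without an incoming link starts a track, a track ends at its first frame
without an outgoing link, and there is no gap closing or motion
prediction. Single-point tracks are materialised and left to the duration
filter, so assembly conserves objects. `filter_trajectories()` keeps
tracks lasting at least 15% of the experiment duration — 3.6 h for a 24 h
acquisition — where duration is `(points - 1) x interval` and the
experiment duration is always that of the *original* acquisition, never
the subsampled one. The bound is inclusive; there is no upper bound.

## Statistics and evaluation

A track is **south-moving** iff its endpoint row strictly exceeds its
start row (image rows grow southward; the chemoattractant sits at the
south edge), and east-moving analogously for columns; exact ties count as
neither. Percentages are rounded half-up to one decimal, as printed in
migration tables. `star_plot()` overlays all starting points at the
origin. **Confluence** is the covered fraction of the view plane,
reported as a min–max range over frames. **Strict accuracy**
(`evaluate_accuracy()`) assigns every track point to the nearest
ground-truth cell within a match radius (default: the `D` of that
interval) and calls a track correct only if all points are assigned to
one and the same cell — one identity switch or lost point fails the whole
track. For interval-comparison studies the bundled analyses instead fix
`match_radius` at 10 px (the base-interval `D`): letting the radius grow
with `D` makes the scoring protocol itself more lenient at long
intervals, which confounds the very trend being measured. `interval_sweep()` repeats subsample → segment → link → filter →
tabulate for each interval in the ladder 30 s, 1, 2, 3, 5, 7.5, 10,
15 min.

## The adaptive controller

`run_adaptive()` closes the loop between tracking quality and
acquisition. The quality signal is the *link ratio* — the fraction of
objects in the previous acquisition that receive a link into the new one.
The controller halves the interval when the windowed mean ratio falls
below `q_low`, doubles it above `q_high`, holds otherwise; changes are
frozen for a cooldown period and the window is cleared on change, which
together with the hysteresis gap prevents oscillation. The stored 30 s
sequence acts as a virtual microscope (each acquisition serves the stored
frame nearest the requested time) because every longer interval is, by
construction, a subsampling of the base acquisition. All thresholds are
design choices (defaults `q_low = 0.80`, `q_high = 0.95`, factor 2,
window 5, cooldown 5, bounds 30 s–15 min): the underlying idea — reduce
the step when tracking is poor, increase it when it is needlessly good —
does not prescribe a particular metric.

## The synthetic-data generator

Real experiments of this kind are not publicly deposited, so the package
ships a ground-truthed simulator whose defaults emulate the four study
conditions: HT1080 under uniform serum (unbiased walk, 26 cells),
HT1080 under a serum gradient at the south edge (0.4 µm/min southward
drift, 60 cells — the densest scene), and two keratinocyte conditions
(20 and 23 cells, no drift, 0.5 µm/min). All use 1.61 µm/px, 30 s base
interval, and by default 480 frames (4 h) — a desk-scale stand-in for the
full 2880-frame/24 h acquisitions, which remain available via
`frame_count`. HT1080 random-walk speed defaults to 0.8 µm/min; the
source experiments state only "under 1 µm/min", so 0.8 (HT1080) and 0.5
(nHEK) are calibration choices.

Motion is a Gaussian-step random walk with constant drift. The per-axis
step s.d. is `s_c * dt / sqrt(pi/2)` so the expected step length equals
the cell's speed times the interval; per-cell speeds are
`N(speed_mean, speed_sd)` truncated at zero. Initial positions are
uniform with a hard-core minimum separation (default 20 px in the
presets): adherent cells occupy space and do not stack at seeding.
Motion afterwards is interaction-free, so cells can still meet — touching
halos merging into one object, with the attendant track breaks and
identity ambiguity, are the simulator's main realistic error source.
With open boundaries cells leave (and may re-enter) the view plane and
are absent from the ground truth while outside.

Rendering draws each cell as an interior disk with intensity resampled
per frame from a dark–bright range (emulating phase flips) inside a
bright halo annulus, adds Gaussian noise, and quantises to the bit
depth. Rendering consumes its own RNG sub-stream so the motion draw is
invariant to render settings. Filopodia and shape change are only
approximated (optional radius jitter); the rendered cells are rigid
disks.

What passing tests on this simulator do **not** show about real data:
disk-rendered cells have sub-pixel-stable centroids, so per-link error
does not grow with the interval the way it does for morphologically
plastic real cells; segmentation on real halos is harsher; and cell
division/collision dynamics are absent. Conversely the simulator's
diffusive slow cells are *harder* on the temporal-mode background than
persistent real cells, because they vacate their footprint more slowly.

In the zero-drift scenarios, identity errors during transient cell
contacts are time-localised: a coarse sampling grid skips many of them,
while the strict rule catches every one at 30 s. Strict accuracy in the
sweep declines with the interval mainly because the growing `D` lets a
track whose own cell went undetected grab a neighbour, and the count of
accepted trajectories declines mainly through duration quantisation: at
interval `k x 30 s` the inclusive 15% duration threshold effectively
rounds up to the next multiple of the interval and loses up to two
intervals of observed lifetime at the track ends.

The adaptive-controller demonstration (`make_speed_mix_dataset()`) mixes
15 slow drifting cells with 40 fast amoeboid-class cells (10 µm/min, the
speed the field quotes for immune cells). Against a fixed 12 px
threshold the fast subpopulation's diffusive step loss gives link ratios
of ≈0.93 at 2 min, ≈0.83 at 4 min and ≈0.63 at 8 min, so with
`q_low = 0.5`, `q_high = 0.75` exactly one reachable interval (8 min) is
stable, and the controller converges there and holds.

## Problem sizes and numerical notes

The bundled analyses and tests run at desk scale by choice: 256² px
frames, 480-frame acquisitions, 5 seeds for directionality studies and
10 for trend studies; the demonstration scenes for the controller use
400² px. Results quoted in the README were produced by these sizes.
Degenerate inputs are handled explicitly: empty masks yield empty object
sets, empty object sets yield empty link sets, a single-frame sequence
has no defined background mode (error), an empty frame scores link
quality 1, and zero accepted tracks report percentages as `NA`. All
stochastic entry points accept seeds; identical seeds reproduce datasets
bit for bit.

## Known limitations

* The linker is greedy; an optimal assignment, motion models, gap closing
  and division handling are out of scope by design.
* Trajectory-based re-segmentation (feeding tracks back into
  segmentation) is not implemented.
* The contour backend's global two-phase formulation can swallow isolated
  dim debris attached to edges; the area filter is the only guard.
* The controller emulates acquisition by subsampling a stored sequence;
  it does not drive hardware.
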