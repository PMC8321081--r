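# phasetrack

Fully-automated cell tracking for phase-contrast time-lapse microscopy,
built to study how the **time step interval** of image acquisition — the
time between consecutive frames — shapes tracking quality, and to close
the loop by adapting that interval to the tracking quality observed on
the fly.

The package is aimed at quantitative cell-migration work with
slow-moving adherent cells (HT1080 fibrosarcoma, normal human
keratinocytes and similar mesenchymal migrators at < 1 µm/min), imaged
label-free at low magnification (e.g. 4×, 1.61 µm/px) every 30 s for up
to a day. Typical questions: is a cell population chemotaxing toward a
gradient placed at one edge of the view plane, and how infrequently can
one afford to image while still answering that reliably?

## What is inside

* **Two segmentation backends.** (1) Edge detection (Gaussian-derivative
  gradients, hysteresis thresholds) followed by a two-phase
  piecewise-constant active-contour evolution — robust to the dark/bright
  interior flips of phase contrast but merges near-touching cells
  (under-detection). (2) Temporal-mode background reconstruction — the
  per-pixel mode of intensity over all frames — with absolute-difference
  thresholding; simple and sharp but fragments elongated cells
  (over-detection).
* **Greedy global-minimum linking.** With centroid sets `C_A = {C_A,i}`
  and `C_B = {C_B,j}` of consecutive frames, the distance array
  `d_ij = |C_A,i − C_B,j|` is consumed recursively: link the globally
  smallest `d_i*j*`, delete row `i*` and column `j*`, stop when the
  minimum exceeds a plausibility threshold `D` (10 px at 30 s rising to
  50 px at 15 min). Deliberately not a Hungarian solver: a cell is
  assumed to move to the closest target in its vicinity.
* **Trajectory assembly and filtering.** Link chains become tracks; no
  gap closing; tracks shorter than 15 % of the experiment duration
  (3.6 h of a 24 h acquisition) are rejected.
* **Migration statistics.** South/east-moving counts and percentages
  (strict inequalities on net displacement), star plots, per-frame
  confluence, and strict accuracy against ground truth (one identity
  switch fails the whole track).
* **Interval sweep.** Re-runs the pipeline at 30 s, 1, 2, 3, 5, 7.5, 10
  and 15 min by subsampling the base acquisition, one summary row per
  interval.
* **Adaptive controller.** Halves the interval when the windowed link
  ratio drops below `q_low`, doubles it above `q_high`, with hysteresis
  and cooldown; replayed against a stored 30 s acquisition as a virtual
  microscope.
* **A ground-truthed simulator** of phase-contrast time-lapse (biased or
  unbiased Gaussian-walk motion, disk-plus-halo rendering) with presets
  emulating four study conditions (directed vs random HT1080, two nHEK
  conditions).

## Worked example

Simulate a 4 h directed-migration experiment (60 cells drifting
0.4 µm/min toward the south edge, 30 s interval) and sweep four
intervals:

```r
library(phasetrack)
ds <- make_dataset("directed_HT1080", seed = 42, frame_count = 480)
sw <- interval_sweep(ds$sequence, ds$ground_truth,
                     run_config(intervals_to_sweep = c(30, 120, 300, 900)))
print(sw)
```

```
Time-step-interval sweep
  confluence 14.89-22.33% at base interval
  interval tracks  south   %south   east    %east  accuracy 
      30 s     66     66      100     34     51.5      69.7
     2 min     62     62      100     33     53.2        79
     5 min     62     61     98.4     30     48.4      75.8
    15 min     59     58     98.3     23       39      79.7
```

Reading the row for 30 s: 66 trajectories survived the 15 % duration
filter; all 66 ended south of where they started (the chemotactic
signature — an unbiased walk would sit near 50 %), east-moving stayed
near 50 % as expected perpendicular to the gradient, and 69.7 % of
tracks followed a single ground-truth cell without any identity switch
under strict scoring. The trajectory count falls as the interval grows.

A shell front end for the five pipeline stages lives at
`inst/cli/phasetrack.R`:

```sh
Rscript inst/cli/phasetrack.R simulate --scenario directed_HT1080 \
    --frames 480 --seed 1 --out demo
Rscript inst/cli/phasetrack.R sweep --in demo/stack.tif \
    --gt demo/ground_truth.csv --out report.csv
```

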