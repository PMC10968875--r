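---
title: "Quantifying phagocytosis and migration from phase-contrast time-lapse recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phagocytosis and migration from phase-contrast time-lapse recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadphage)
```

## The assay and its imaging constraints

Uncoated 4.5 µm polymer beads (Dynabeads M-450) are added to adherent
phagocyte cultures at about 20 beads per cell and the flask is recorded
in an incubator microscope: one frame per 3.5 min for 24 h through a 4×
objective at roughly 1.15 µm per pixel. Both constants are configurable
(`acquisitionMeta()`), but they shape every default in this package.

Two facts about these images drive the whole design:

* **Beads are the only reliable signal.** At 4× the cells are dim,
  low-contrast smudges; segmenting them directly is hopeless. The beads
  are small, very dark, high-contrast disks.
* **An ingested conglomerate is a cell proxy.** Once a cell engulfs
  beads, the bead cluster rides along with it, so tracking conglomerates
  gives cell trajectories — for the phagocytosing cells only.
  Non-phagocytosing cells are invisible to this approach, a limitation
  we state openly rather than work around with unreliable segmentation.

## Detection

A frame is thresholded for dark objects. The default cutoff sits halfway
between a *dark anchor* — the median of the darkest 0.2% of pixels
(floored at 25 pixels, about two bead footprints), which lands in the
bead tone whenever any beads are present — and the background median.
We deliberately do not use a global Otsu split here: when dim cell
bodies cover more area than beads, Otsu separates background from
*everything else* and pulls entire cells into the bead mask, merging an
ingested conglomerate with its host cell into one giant component. The
anchor-midpoint rule isolates the truly dark bead pixels regardless of
how much area cells occupy. Degenerate frames (no dark tail) yield an
empty detection list with a warning.

Connected components are then filtered by area. The bounds are anchored
to physics, not pixels: one bead of diameter 4.5 µm at 1.15 µm/px has a
raster area of ~12 px²; components below 40% of that are noise
specks, components above 60 bead areas are debris or clumped junk.
Each surviving component carries its pixel-mean centroid (0-based x, y,
origin top-left), area, mean brightness, and a *local contrast*: the
standard deviation of intensities in a 2-px-wide annulus starting
`neighborhoodRadius` (default 3) px outside the component, normalized by
the frame's intensity range. The annulus is computed against the
component's boundary pixels in compiled code; it is zero on constant
neighborhoods.

## Free versus ingested

Two criteria, combined by OR (the union errs toward sensitivity and the
two signals are complementary):

* **coincidence** — the centroid lies inside the *cell mask*, the union
  of disks (default radius 15 px ≈ 17 µm, a macrophage radius) around
  each estimated cell position at that frame;
* **surrounding contrast** — the annulus contrast reaches
  `ingestionContrastThreshold` (default 0.08). Cell borders contrast
  against the substrate; a free bead on empty substrate has quiet
  surroundings.

The cell mask comes from the movement analysis. All detections are
tracked first; then `cellTracks()` selects, per track, the motile
segment that behaves like a migrating cell. This selection earns its
complexity honestly — every rule corresponds to a concrete confusion
observed on synthetic scenes with ground truth:

* A window of a track counts as *moving* when the median per-frame step
  sustains `minCellStep` (default 0.5 px) **and** either the window
  translates as a whole (≥ 3× that) or the median is stride-sized
  (≥ 2×). Centroid quantization lets resting-bead jitter fluke past a
  bare median test; a cell turning in place strides at full speed
  without translating. Both cases must land on the correct side.
* The stationary prefix is trimmed iteratively. A track may begin as a
  resting bead that an ingestion event converts into a carried
  conglomerate — the linker bridges one large jump from anchor to cell —
  and a track orphaned by a displaced bead can chain through several
  such jumps. A stitch jump is recognized as a step far above its
  window's median and motion starts at its destination.
* The surviving segment must last `minSegment` (15) observations, reach
  a maximum excursion of `minCellDisplacement` (5) px from its start
  (*excursion*, not end-to-end displacement: migrating cells loop back;
  oscillating beads never leave their anchor's neighbourhood), and
  sustain the median step.

The per-frame cell count defaults to the number of selected segments
covering the frame and is reported alongside the series so manual counts
can be substituted, exactly as an operator would.

## Counting beads: the size–brightness diagram

Plotting area against mean brightness for all detections across the
recording produces density hotspots at the 1-, 2-, 3-, … bead areas.
`fitSizeBrightness()` finds the dominant peak of a 2-D histogram
(64 area × 16 brightness bins), requires the ±25% area neighbourhood of
the modal area to hold at least 10% of all points (otherwise it errors
and asks for an explicit single-bead area `a1`), refines `a1` as the
mean area in that neighbourhood, and confirms hotspots near `k·a1`
while enough points support them. A detection within ±25% of `a1` of a
hotspot takes that hotspot's index; larger outliers with bead-like
brightness are counted by area division, `max(1, round(area / a1))`.
The tolerance reflects rasterization: a 2-px-radius disk covers 9–13
pixels depending on its subpixel position.

## Ingestion kinetics

Free-labelled bead counts are summed per frame. Assuming the recording
starts before any ingestion, the cumulative ingested count is
`free[0] − free[t]`; detection noise occasionally pushes `free[t]`
above `free[0]`, and those negatives are clamped to zero with a
message. The curve is smoothed by a centered moving window (default 5
frames, mean; median selectable; the window shrinks at the series
ends), then normalized per cell (`smoothed / cells[t]`) and per
available bead (`smoothed / free[0]`, clamped to [0, 1]). Both
normalizations are always emitted since either may be wanted downstream.
Per-cell tallies are banded as capacity classes: 0 = none, 1–10 = low,
>10 = high.

## Tracking

Per frame, active tracks and new detections are matched by a globally
optimal one-to-one assignment (shortest augmenting path on the gated
bipartite graph, solved exactly per connected component — almost all
components are singletons, which is what makes 200-object fields
tractable). The cost of a feasible link is the *squared per-frame
displacement*, `d²/(gap+1)²`, gated at `maxLinkDistance × (gap+1)`
(defaults 20 px, gap ≤ 2); not linking costs `maxLinkDistance²` on
either side. Normalizing by the gap matters: with raw squared distance
and gap-scaled no-link costs, a track returning after a gap outbids the
true continuation of a newly appearing object — we observed dead
free-bead tracks capturing freshly formed conglomerates on ground-truth
scenes. Tracks unseen beyond the gap terminate; tracks shorter than
`minTrackLength` (10) observations are dropped as erroneous detections.
Determinism: detections are processed sorted by (frame, y, x) and the
solver scans candidates in fixed order, so ties always resolve the same
way. No motion model is used; at one frame per 3.5 min, cells move
~1–2 px per frame, far below the gate.

Operator review is supported through YAML correction files
(`readCorrections()` / `applyCorrections()`): `split`, `merge`,
`delete`, `relabel` directives applied in file order, each validated
against the track invariants, with an edit log attached to the result.

## Migration metrics

Three path models per cell (`pathSet()`):

* **raw** — the centroid sequence;
* **smoothed** — for each frame, a robust line of position versus frame
  is fitted over a centered window of up to 20 frames (shrinking near
  the ends, never below 5 points) and evaluated at that frame. The loss
  is Tukey bisquare via iteratively reweighted least squares (≤ 50
  iterations, 1e-8 coefficient tolerance) with **one weight per
  observation from the bivariate residual norm**. Per-axis reweighting
  (two independent robust regressions) is subtly wrong here: it is not
  equivariant under rotation of the image plane, so the same trajectory
  smoothed in a rotated coordinate frame would give different speeds.
  The shared-weight fit is exactly rotation- and
  translation-equivariant, and collinear windows are a fixed point
  (ballistic paths pass through untouched).
* **Euclidean** — endpoint minus start, in µm; the chemokinesis readout
  (no gradient is applied, so directed-migration indices are
  meaningless here).

Mean speed along a path is the summed stepwise displacement divided by
elapsed time, in µm/min (px/frame also reported). At the instrument
constants, 2 px/frame is 2 × 1.15 / 3.5 ≈ 0.657 µm/min. Group summaries
are mean, sample sd, and a 95% confidence interval using the Student t
quantile on n−1 degrees of freedom (the t rather than normal quantile —
group sizes in this assay are often small).

## Statistics and cytometry

Two-group comparisons use the unpaired two-tailed t test, pooled
variance by default with a Welch toggle (the variant is recorded in the
result object); p < 0.05 is "significant", p < 0.001 "very
significant", and no multiple-testing correction is applied by default.
Both groups constant and equal yields p = 1 by convention, with a
message. Mean fluorescence intensities from quadrant summaries are
background-subtracted as
`%pos(marker)·mean(marker) − %pos(isotype)·mean(isotype)`; fractions
are carried as proportions in [0, 1] (using percentages consistently
would only rescale by a constant), and negative results are reported
as-is with a warning.

## The synthetic scene generator

`simulateScene()` is the package's test oracle: the original recordings
are not publicly available, so every quantitative claim is validated on
scenes with known ground truth. What it emulates, and what it does not:

* **Rendering.** Bright background (0.85), dim cell disks (0.6, radius
  13 px), dark bead disks (0.1, radius from 4.5 µm at the pixel scale),
  additive Gaussian noise (sd 0.01), quantized to the 16-bit intensity
  grid so a simulate/write/read cycle through the TIFF writer is
  bit-exact. Bead disks are hard-edged so the rendered pixel area
  matches the center-in-disk count (expectation πr² over subpixel
  positions); an ingested conglomerate of k beads is one disk of area
  k× the single-bead area at the cell position. Full phase-contrast
  optics (halo, shade-off) are *not* simulated — the analysis operators
  only require contrast polarity — so passing tests demonstrate
  correctness of the measurement chain, not robustness to real optics.
* **Motion.** Cells perform a persistent random walk (heading =
  normalized persistence-weighted previous heading plus a Gaussian
  turn; persistence 0 = direction redrawn each frame, 1 = ballistic) at
  constant speed (default 1.5 px/frame ≈ 0.5 µm/min), reflecting at the
  borders. Adherent cells do not stack: a cell whose step would bring
  it within contact range of a neighbour steers around it — the
  smallest heading rotation with a clear landing spot — rather than
  stopping. (An earlier design resolved overlaps by pushing positions
  apart, which could pin a crowded cell in place for tens of frames;
  its conglomerate then became motion-indistinguishable from free
  beads. Steering keeps the "carried conglomerates keep striding"
  property that the classifier relies on, and is also what crawling
  cells actually do.)
* **Beads.** Free beads oscillate around fixed anchors (sd 0.15 px);
  anchors are placed with spacing that keeps neighbours out of each
  other's contrast annulus. A free bead contacted by an advancing cell
  is swept aside in a single relocation to a clear spot: unscripted
  cell–bead coincidence would force the classifier to count a
  still-free bead as ingested, and physically a bead at the cell front
  is either displaced or eaten — and eating is scripted. The field is
  closed (free + ingested is constant), matching the subtraction
  method's assumption.
* **Ingestion.** A schedule of (cell, frame, n_beads) events; the
  nearest free beads flip owner and move with the cell thereafter.
  The default bead budget is 20 per cell, the assay's ratio.

`fixtureSuite()` provides named scenarios (static beads, a single
ballistic carrier, a staged multi-cell scene, a matched control /
drug-like pair with reduced speed and ingestion), and
`stagedIngestionConfig()` the full-scale benchmark: 256×256 px, 200
frames, 10 cells, 200 beads, events scripted between frames 20 and 150.
On that scene the pipeline reconstructs the cumulative ingestion curve
with zero error outside ±(smoothing window/2) of each scripted event
and recovers every per-cell tally exactly, across every seed we tried;
the acceptance script reruns this end to end. Problem sizes throughout
the tests (tens of beads, ≤ 200 frames) were chosen as the smallest
scenes that exercise each mechanism — crowding, gaps, stitches —
without redundancy.

## Numerical choices and degenerate inputs

* Smoothing windows shrink at series ends rather than padding;
  moving-window output never leaves the [min, max] of its input.
* The ingestion series clamps negative cumulative counts at zero and
  says so; per-bead normalization refuses a first frame with no free
  beads; frames with zero counted cells get `NA` per-cell values.
* `unpairedTTest` falls back to p = 1 for two equal constant groups.
* All tabular output is RFC-4180 CSV with doubles at 17 significant
  digits, so write/read cycles are lossless; 16-bit TIFF round-trips
  are bit-exact for sequences on that grid.
* Every stochastic draw in a simulation flows from the config seed
  through R's generator (saved and restored around the call): identical
  configs are bit-identical, and fixtures are regenerated rather than
  stored.

## Known limitations

* Non-phagocytosing cells are not detected, tracked, or counted; all
  per-cell normalizations refer to phagocytosing (motile-conglomerate)
  cells unless manual counts are supplied.
* The free/ingested classifier depends on the cell-proxy track
  selection; pathological recordings (a cell resting for an entire
  recording on top of free beads) will misclassify, which is exactly
  the situation the operator-review contract exists for.
* Bead counts for large conglomerates rest on the area-division rule;
  tight three-dimensional packing inside a cell is not modelled.
* The smoothing parameters (window, loss, tolerances) are documented
  defaults chosen for internal consistency; migration speeds are
  comparable within analyses using the same settings, not across
  different smoothing schemes.
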