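---
title: "Segmenting cells from leaky nuclear-dye fluorescence: methods and design notes"
author: "LeakySeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting cells from leaky nuclear-dye fluorescence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LeakySeg)
```

## The problem and the signal

Counting and outlining single adherent cells in fluorescence microscopy
usually needs a dedicated cell-body stain on top of the nuclear stain.
Far-red DNA dyes such as DRAQ5, however, do not gain fluorescence on DNA
binding; besides the strong nuclear signal they leave a weak but detectable
cytosolic "leak" that traces the whole cell body. LeakySeg exploits exactly
this: the nucleus provides one robust intensity maximum per cell (a
watershed seed), and the faint cytosolic halo provides the cell outline —
one dye, full instance segmentation, no training data.

The input is a confocal Z-stack with known lateral calibration (default
0.6 µm/px, 1.51 µm slice spacing). Every tunable parameter of the pipeline
is expressed in physical units so one parameter set transfers across
magnifications.

## The processing chain

`segmentCells()` composes the following steps.

1. **SD projection** (`sdProjection`). Each output pixel is the standard
   deviation of the voxel intensities along Z. Signal that varies through
   the stack (nuclei, cytosol under confocal sectioning) projects brightly;
   static structure (uneven illumination, offsets) projects to ≈ 0, which is
   precisely why this projection rather than a mean or maximum seeds the
   chain. The sample convention (denominator $n-1$) is the default and a
   population option (`"n"`) is provided; downstream thresholds are
   ratio-based, so the choice is immaterial in practice and configurable on
   principle.
2. **Background image** (`buildBackgroundImage`). The projection is capped
   at `capMultiplier` (default 3) times its global mean gray value — zeros
   included, deliberately, as this is a *global* mean — and blurred with
   `sigmaBackground` (default 100 µm). Capping stops nuclei from inflating
   the estimate; the heavy blur turns the capped image into a smooth
   illumination-plus-diffuse-signal surface that still carries the broad
   cytosolic component under each cell.
3. **Flattening and double subtraction** (`subtractBackground`). In
   parallel, the raw projection is flattened by a rolling ball of radius
   `rollingBallRadius` (default 100 µm, deliberately larger than a cell
   radius so cytosolic signal is untouched) and smoothed with `sigmaSmooth`
   (default 1 µm). The background image of step 2 is then subtracted and
   negative values are **clamped to zero**. The clamp is a design decision:
   integer-image pipelines clamp implicitly, and the fixed gray-value
   threshold of the next step is only well defined on a non-negative image.
4. **Cytosol mask** (`thresholdCytosol`). After the double subtraction the
   off-cell background is almost entirely below 1 gray value, so the mask is
   simply `pixels >= cytosolThreshold` (default 1). The comparison is
   inclusive (≥); with real-valued images the distinction to a strict
   threshold is a measure-zero set, but the convention is documented.
5. **Watershed split** (`segmentedParticles`). A copy blurred with
   `sigmaWatershed` (default 2 µm) is searched for intensity maxima with
   topographic prominence at least `noiseMultiplier` (default 3) times the
   mean of the *strictly positive* pixels of that copy (the asymmetry with
   the global mean of step 2 is intentional and follows the method's
   definition of its noise value). Each accepted maximum seeds a basin of a
   Meyer-type flooding watershed on the inverted image; basins tessellate
   the whole frame and the pixels where basins meet form one-pixel dividing
   lines. The returned mask is foreground everywhere except on these lines.
6. **Combination and size filter** (`combineAnd`, `sizeFilterLabel`). The
   pixel-wise AND of cytosol mask and watershed mask separates touching
   cells; 8-connected components **strictly bigger** than `minArea`
   (default 200 µm²) become labels 1..K in raster order. The strict
   inequality mirrors the "bigger than" debris rule, and the boundary case
   is tested at the 555/556-pixel cutoff implied by 0.6 µm pixels.

Edge-touching cells are kept by default; `excludeEdges = TRUE` (the
`--exclude-edges` CLI flag) removes them for comparisons against manual
counts that only consider cells completely contained in the image.

## Numerical and connectivity decisions

* **Connectivity.** Components are 8-connected. The watershed floods
  8-connected as well and marks a pixel as a line whenever two distinct
  basins appear among its 8 neighbours; consequently no two pixels of
  different basins are ever 8-adjacent, which is the weakest guarantee under
  which a one-pixel line separates objects under the component
  connectivity.
* **Maxima semantics.** The "noise tolerance" is interpreted as topographic
  prominence: a maximum is discarded if a higher peak can be reached without
  descending more than the tolerance. Equal-valued plateau maxima collapse
  into a single seed (ties broken toward the first raster position), which
  prevents spurious splits on flat-topped nuclei. The implementation is
  validated against an independent minimax-path (highest-saddle) oracle;
  note that below the saddle level the minimax partition is inherently
  ambiguous, so equivalence is asserted where the partition is defined.
* **Watershed ties.** Flooding pops pixels in ascending height with FIFO
  tie-breaking, so lines across flat valleys land midway between equal
  blobs and the whole pipeline is deterministic.
* **Gaussian blur.** Kernels are truncated at 3.5 σ and renormalised;
  boundaries use edge replication. Constants are therefore preserved
  exactly and the operator is exactly linear. For σ > 24 px the blur runs
  on a block-mean pyramid level and is restored bilinearly; each step is
  linear and constant-preserving, the added block variance
  ($(s^2-1)/12$ px²) is negligible against such σ, and only a band near the
  border differs visibly from direct convolution on noisy input.
* **Rolling ball.** Implemented as a grayscale opening with a true ball
  structuring function (intensity units treated 1:1 with pixels), not the
  paraboloid approximation common in interactive tools — small numerical
  differences to those tools are expected. Radii above 16 px roll on a
  block-minimum-reduced grid and restore bilinearly, the classical
  acceleration; the restored background is clipped to the image so the
  output stays non-negative. A radius below 1 px is an error (the ball
  degenerates).
* **Degenerate inputs.** An all-zero projection passes through every stage
  as all-zero and yields zero cells. An image with no positive pixels at
  the watershed stage produces a full-foreground mask without lines and a
  message.

## Shape descriptors

`measureAll()` reports, per cell: projected area (pixel count × pixel
area), perimeter, circularity, aspect ratio, centroid and a border flag.

* **Circularity** is $4\pi A / P^2$, clamped to at most 1. The $\pi$ is
  included — the defining property that a perfect circle scores exactly 1
  requires it — matching the convention of the standard image-analysis
  tools. A single-pixel region reports 1 (via the clamp).
* **Perimeter** uses a Crofton 4-direction estimator (transition counts
  along rows, columns and both diagonals with spacings 1 and $1/\sqrt2$).
  On disks of radius ≥ 10 px it is accurate to < 2%; naive edge counting
  (≈ 27% high on disks) was rejected. Like all 4-direction Crofton
  estimators it is a few percent low on axis-aligned squares; the analytic
  closed forms in the documentation use exact perimeters.
* **Aspect ratio** is the major/minor axis ratio of the ellipse matching
  the region's second-order central moments. Each pixel contributes the
  moment of a unit square (adding 1/12 px² per axis), which both removes a
  small bias and floors the minor axis of degenerate collinear regions at
  about one pixel, keeping the ratio finite.

## Evaluation protocol

The human-comparison categories are formalised with deterministic rules
(`categorizeMatches`): a ground-truth cell is *correctly segmented* when
more than 90% of its area lies inside its best-matching detection, the
match is mutual, and that detection holds no other cell's majority;
*missed* when nothing overlaps it; *under-segmented* when it shares a
detection frame holding more than one cell's majority (majority = more
than 50% of the cell's area — the computable stand-in for a human calling a
frame "containing" a cell) or when its frame is much larger than the cell;
*over-segmented* otherwise (splits and partial detections). One cell per
under-segmented multi-cell detection counts as a true positive and the
other members as false negatives; the largest fragment of an over-segmented
cell counts as its true positive; detections overlapping no cell are
debris/false positives. Accuracy is $100\,TP/(TP+FP+FN)$, sensitivity
$100\,TP/(TP+FN)$, percent-correct $100\,\text{correct}/\text{manual}$.
Every cell lands in exactly one category, so the counts always partition
the manual count — a property the test suite asserts on perfect, degraded
and pipeline-produced predictions.

Two rules deserve a flag. The "much larger than the actual cell" criterion
for a single-cell frame has no numeric definition in the protocol it
formalises; we use a configurable frame-to-cell area ratio (default 2×)
and label it a heuristic. Best matches maximise IoU with ties broken
toward the lower label ID; unmatched cells contribute IoU 0 to the mean
rather than being dropped (the conservative choice).

## The synthetic scene generator

`generateScene()` renders what the pipeline assumes about its data: bright
compact nuclei (default 220 gray at 8 bit) inside weak cytosolic plateaus
(default 20 gray) on elliptical cells (radius 15 ± 2 µm, nuclei 6 ±
0.7 µm), a smooth illumination gradient (amplitude 15 gray over a constant
8) that is static across Z, and per-slice shot-like noise (base SD 1.2
gray, variance growing with intensity). Signal is modulated along Z by a
smooth axial profile so that the SD projection recovers structure — a
constant-across-Z scene would project to pure noise, which is also why
noise is regenerated per slice. With these defaults the SD projection
separates the three intensity regimes by more than a factor 3 each
(nucleus > 3 × cytosol > 3 × background), so the pipeline's ratio-based
thresholds are exercised in the regime they were designed for; the suite
verifies this separation rather than assuming it. `clumping` controls the
fraction of cells placed touching an existing cell, producing the adjacent
pairs the watershed must split.

What the generator does **not** emulate: optical point-spread functions
(cell edges are hard), photobleaching, intracellular texture, irregular
(non-elliptical) cell outlines, and truly confluent monolayers. Passing the
synthetic benchmark therefore demonstrates that the implementation performs
the intended computation on data matching its assumptions — it does not
certify performance on real confocal data, where edge softness, texture and
crowding are harsher.

Default problem sizes used by the test suite and benchmark were chosen as
the package's own desk-scale conditions: 512 × 512 px fields at 0.6 µm/px,
7 slices, and an evaluation suite of 8 images × 17 cells = 136 ground-truth
cells with clumping 0.2, segmented and scored in a few seconds. The
benchmark quality bar (sensitivity ≥ 90%, accuracy ≥ 85%, percent-correct
≥ 80%, mean IoU ≥ 0.75) is intentionally below what the method reports on
real data, reflecting that synthetic scenes are a stand-in, not a
reproduction.

## Known limitations

* Fully confluent layers defeat the watershed-from-nuclei idea when the
  cytosol mask has no valleys left; the method is designed for sub-confluent
  adherent cultures.
* All segmentation is 2-D after projection; overlapping cells in Z are
  merged by construction.
* The TIFF writer cannot embed resolution tags, so calibration travels in
  the JSON run manifest; the reader honours X-resolution tags on input and
  an explicit calibration always wins.
* The rolling ball is a true ball; pipelines built on the common paraboloid
  approximation will differ by a few gray levels on strongly curved
  backgrounds.
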