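# LeakySeg

Unsupervised 2-D segmentation of adherent mammalian cells from confocal
stacks of a **single nuclear DNA dye**. Far-red dyes such as DRAQ5 show no
fluorescence enhancement on DNA binding, so besides the bright nucleus they
leave a weak, "leaky" cytosolic signal that outlines the whole cell body.
LeakySeg turns that by-product into a full instance segmentation: the
nucleus supplies one robust watershed seed per cell, the cytosolic halo
supplies the outline — no cell-body stain, no training data. The package is
aimed at cell-biology and bioprocess labs that want automated per-cell
morphometry (spreading area, circularity, elongation) from images they
already acquire for counting.

## Method

For a calibrated Z-stack (default 0.6 µm/px, 1.51 µm slices), with all
parameters in physical units:

1. **SD projection** — pixel value = standard deviation of intensities
   along Z; static background projects to ≈ 0, signal survives.
2. **Double background subtraction** — subtract from the rolling-ball
   flattened (*r* = 100 µm) and lightly smoothed (σ = 1 µm) projection a
   background image built by capping the projection at 3× its global mean
   and blurring with σ = 100 µm; clamp negatives to 0.
3. **Cytosol mask** — threshold at gray value 1.
4. **Watershed split** — on a σ = 2 µm blurred copy, find intensity maxima
   with prominence ≥ 3× the mean of positive pixels, flood a seeded
   watershed, keep everything except the one-pixel dividing lines.
5. **AND + size filter** — combine masks, keep 8-connected components
   strictly bigger than 200 µm², label 1..K.

Per cell, the shape module reports projected area *A*, perimeter *P*
(Crofton estimator), circularity 4π*A*/*P*² (1 for a perfect circle) and
aspect ratio (major/minor axis of the moment-fitted ellipse). The
evaluation module scores a segmentation against a ground-truth label mask
using the human-comparison protocol: correctly segmented (> 90 % of the
cell inside its detection), missed, under-/over-segmented, debris;
accuracy = 100·TP/(TP+FP+FN), sensitivity = 100·TP/(TP+FN),
percent-correct = 100·correct/manual, plus mean best-match IoU.

A synthetic confocal scene generator (bright nuclei, weak cytosolic
plateaus, static illumination gradient, per-slice shot-like noise, exact
ground-truth labels) makes the whole pipeline testable without microscope
data. See the methods vignette (`vignettes/leakyseg-methods.Rmd`) for every
numerical decision and the generator's scope.

## Worked example

```r
library(LeakySeg)

sc    <- generateScene(sceneParams(nCells = 5, fieldSize = c(384, 384), seed = 7))
cells <- segmentCells(sc$stack)            # full pipeline, default parameters
cells
#> LabelMask: 384 x 384 px, 5 objects

head(measureAll(cells), 3)
#>   label area_um2 perimeter_um circularity aspect_ratio centroid_row centroid_col touches_edge
#> 1     1      540         82.8       0.989         1.15         87.1        151.9        FALSE
#> 2     2      672         94.8       0.940         1.48        134.2         58.4        FALSE
#> 3     3      627         91.6       0.940         1.53        191.4        285.3        FALSE

evaluateSegmentation(sc$truth, cells)
#> EvalReport:
#>   manually counted    5
#>   correctly segmented 5
#>   ...
#>   accuracy            100.0%
#>   sensitivity         100.0%
#>   percent correct     100.0%
#>   mean IoU            0.934
```

All five simulated cells are recovered as five labels; the per-cell table
gives areas in µm² (here ~540–1260 µm², set by the generator's 15 ± 2 µm
cell radii), circularities near 1 (the cells are near-elliptical) and
aspect ratios matching the generated elongations. The evaluation report
confirms every cell is correctly segmented with a mean IoU of 0.93 against
the exact ground truth.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/leakyseg simulate -o sim --images 8 --cells 17 --seed 1
Rscript inst/cli/leakyseg segment  -i sim/stacks -o seg --rois
Rscript inst/cli/leakyseg eval     --truth sim/truth --pred pred -o report
```

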