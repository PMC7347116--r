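---
title: "Methods: automated MNG detection in histological sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated MNG detection in histological sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mngdetect)
```

## The problem

Multinucleated germ cells (MNGs) — germ cells containing two or more
nuclei — are induced in the fetal rat testis by phthalate exposure and are
a reproducible, quantitative histopathological endpoint. Counting them by
hand on hematoxylin-stained thin sections is slow and requires specialist
training, and even trained scorers disagree on a fraction of cells because
cross-sections only partially sample 3-D cells. This package implements a
fully automated detector: grayscale section images at 1 micron/pixel go
through a convolutional network that produces a per-pixel MNG-likelihood
heatmap, which is then reduced to discrete detections and scored at the
object level against human annotations.

## Pipeline model and assumptions

The pipeline has five stages, each exposed as ordinary functions:

1. **Images and annotations.** Slide images are single-channel 8-bit
   matrices at a known resolution (`slide_image()`); color inputs are
   reduced with ITU-R BT.601 luma weights (0.299, 0.587, 0.114), and
   resolution changes use an area-averaging box filter before integer
   quantization. Annotations are center points plus filled simple
   polygons. Rasterization (`rasterize_annotations()`) marks a pixel when
   its center lies inside or on the boundary of any polygon, by the
   even-odd rule; training targets are therefore *filled* cell areas, not
   outlines, which is what makes the downstream blob analysis meaningful.
   The package-wide coordinate convention is 0-based `(x = column,
   y = row)` with pixel centers at integer coordinates.

2. **Panels and augmentation.** Training panels are sampled *around
   annotated MNGs only*: for each MNG, `panels_per_mng` windows (study
   value 500, default here too) with the MNG center uniformly placed
   within the window. Random placement doubles as translation augmentation
   and enlarges the negative background area seen in training. Each panel
   is expanded by the 8 symmetries of the square (`dihedral_expand()`).
   Near image edges the window is shifted back inside (`clip_shift`);
   mirror padding is available for images smaller than a panel. Whole
   images are predicted by tiling (`tile_for_inference()`) with the final
   tile shifted inward, and overlapping tile predictions are averaged
   (`stitch()`); the default inference stride of half a panel trades a 4x
   prediction cost for smoother seams.

3. **Network.** A compact U-Net (`build_unet()`): paired 3x3 same-padding
   convolutions + ReLU, 2x2 max pooling with filter doubling per level,
   nearest-neighbor up-sampling followed by a 3x3 convolution, skip
   concatenations, and a 1x1 sigmoid head. Same-size convolutions keep
   output shape equal to input shape so heatmaps align with panels.
   Forward, backpropagation and Adam are implemented in the package's
   compiled code (single precision, im2col + BLAS); no external learning
   framework is involved. The loss is pixel-wise binary cross-entropy on
   the filled-area masks. Probabilities are reported as integer
   brightness `round(255 p)`.

4. **Post-processing.** `detect()` composes a brightness cutoff (keep
   pixels `>= cutoff`), connected components (8-connected by default,
   configurable to 4), Moore-neighbor boundary tracing with Jacob's
   stopping criterion, and an area filter. Areas are *Green's-theorem
   (shoelace) areas* of the boundary polygon traced through pixel
   centers — slightly smaller than the literal pixel count; a solid
   `w x h` rectangle gives exactly `(w-1)(h-1)` and 1-pixel-wide regions
   give 0. Interior holes are ignored, which is adequate because heat
   blobs are effectively solid. Keeping `>= cutoff` for both thresholds
   reflects the rule that pixels/regions *below* the cutoff are removed.

5. **Evaluation and model selection.** Detections match annotations
   one-to-one, greedily by descending pixel overlap, with a
   centroid-inside-polygon fallback; a detection covering two annotations
   counts as one true positive plus one false negative. Precision, recall
   and F1 follow the standard definitions; fold-level F1 is computed on
   counts pooled across a fold's images, not averaged per image, matching
   how the benchmark tables report single count triples per fold.
   Slides are assigned to 5 folds by batch stratification: sort by MNG
   count, chunk into groups of `n_folds`, assign each group's slides to
   distinct folds minimizing the variance of per-fold totals (exhaustive
   with pruning up to 6 groups, sequential-greedy beyond). Each fold
   serves once as holdout; the test fold is the next fold cyclically; the
   remaining three train. The grid search over (epoch, brightness cutoff,
   area cutoff) maximizes test-fold F1 and the selected triple is applied
   unchanged to the holdout fold.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `panels_per_mng` | panels | 500 | study value; desk-scale runs use far fewer |
| `panel_size` / `input_size` | px | 512 | canonical U-Net tile |
| `depth`, `base_filters` | – | 4, 64 | canonical architecture; 3, 8 for CPU desk scale |
| `epochs` | – | 15 | study value |
| `learning_rate` | – | 1e-3 | standard Adam default |
| brightness grid | gray levels | 100–254 step 2 | published optima include 246, implying a fine grid |
| area grid | µm² | 10–1000 (11 values) | covers all published optima (20–700) |
| connectivity | – | 8 | common default in the lineage tooling; 4 available |

## Design choices made where the design was open

* **Matching rule.** The benchmark publication reports counts without
  defining "successfully identified". The overlap-or-centroid greedy
  one-to-one rule used here is this package's own; every published-count
  statistic recomputed in the acceptance checks is independent of it.
* **Tie-breaking.** Grid-search ties resolve to lowest epoch, then
  highest brightness, then highest area: the cheapest model and the most
  conservative detector.
* **Boundary rule.** Moore-neighbor tracing over the outer boundary
  anchors the area definition; the rectangle identity `(w-1)(h-1)` and
  the "slightly below pixel count" property pin down the convention.
* **Loss/optimizer.** Binary cross-entropy + Adam, the de-facto defaults
  of the U-Net implementation family this architecture descends from;
  both configurable.
* **Edge policy.** Windows are shifted inside the image rather than
  padded; padding behavior near edges is otherwise unspecified upstream.
* **`90/180 degree` augmentation set.** The eight dihedral symmetries are
  the only consistent reading of "all eight unique combinations" of flips
  and rotations.

## The synthetic-histology generator

Real annotated slides are not distributable, so the package generates
test material with known ground truth (`generate_scene()`): a light
background (hematoxylin-like contrast inverted to grayscale), dark
mononucleated cells (single nucleus disk with a cytoplasm rim, not
annotated), and rarer MNGs rendered as 2–4 touching dark nuclei inside
one cytoplasm boundary whose annotation polygon is the convex hull of the
nuclei dilated by the cell margin. Intensities are Gaussian per
compartment (background 205±4, cytoplasm 150±6, nuclei 70±6, global noise
sd 4 by default on the 0–255 scale), radii 3.5–5 µm at 1 µm/px. Object
placement is rejection-sampled to avoid overlap and fails loudly when a
scene is too crowded. Identical seeds give bit-identical scenes.

What the generator deliberately does **not** emulate: dense seminiferous
cord packing with touching cells, staining gradients and batch effects,
sectioning artifacts, faintly visible second nuclei, and the ambiguity
that makes human scorers disagree. Passing the synthetic end-to-end check
therefore demonstrates that the machinery (sampling, training,
prediction, post-processing, selection) is correct and can learn an easy
version of the task — it does not certify accuracy on real tissue.

`oracle_heatmap()` produces idealized network outputs (optionally blurred
and noisy) directly from a truth mask so post-processing is testable in
isolation; with zero blur and noise, detection recovers the annotations
with F1 exactly 1.

## Numerical choices and degenerate inputs

* Heatmaps are integers 0–255; model outputs scale as `round(255 p)`,
  and stitched overlaps average before rounding.
* Thresholds are inclusive (`>=`) for both brightness and area.
* Single-pixel and 1-pixel-wide regions trace to degenerate polygons with
  area 0 and are removed by any positive area cutoff.
* F1 is 0 when `tp = 0` with `fp + fn > 0`; all-zero counts and
  `fn = 0` FP:FN ratios raise explicit errors rather than silently
  returning 0.
* Training uses single-precision arithmetic; run-to-run determinism holds
  for a fixed seed on a given platform (parameter initialization and
  shuffling are seeded), and save/load round-trips reproduce predictions
  bit-identically.
* Reported F1 values mirror the benchmark tables at 3 decimals; raw
  values are retained in all returned objects.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script exercise the full protocol at
desk scale, chosen so a laptop CPU reproduces them comfortably: 40
generated scenes of 192x192 px with 2 MNGs each, 128 px panels, a
depth-3 / 8-filter network, 2 epochs, 1 sampled window per MNG before the
8-fold dihedral expansion (so 384 training panels per fold
configuration), a 4x4 coarse cutoff grid over both epochs, and the full
five-configuration protocol. The geometric and statistical primitives are
checked at full fidelity (e.g. 1,000 random blobs against an independent
area oracle); only the learning problem is scaled down.

## Known limitations

* The detector is trained and validated per laboratory; the benchmark
  itself cautions that images from other groups may not transfer without
  retraining.
* Object-level scoring only; no pixel-level IoU/Dice, and no serial
  section (pseudo-3D) reasoning.
* The compiled network targets CPU desk scale. Training the canonical
  512-px, depth-4, 64-filter configuration for 15 epochs on hundreds of
  thousands of augmented panels is out of reach without a GPU framework,
  and no attempt is made to reuse externally trained weights.
* Holes inside detected regions are ignored by the area rule; regions
  with genuine holes would be slightly over-measured.
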