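---
title: "Automatic Cobb-angle measurement: models, parameters and design notes"
author: "spinecobb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic Cobb-angle measurement: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Scoliosis severity is quantified by the Cobb angle: the angle between the
upper endplate of the most-tilted upper vertebra and the lower endplate of
the most-tilted lower vertebra on a standing anterior-posterior (AP)
radiograph.  Manual measurement is slow and shows substantial inter- and
intra-observer variation, which motivates an automatic pipeline.
`spinecobb` implements such a pipeline in four stages:

1. **Spine ROI isolation.**  The radiograph is reduced to a quarter of its
   size by 4x4 block averaging.  The lateral extent of the spine is taken
   from the vertical projection profile (column sums): the contiguous run
   of columns around the profile maximum whose values stay above
   `mean + c * sd` (population sd, `c = 1` by default).  The vertical
   extent comes from the horizontal projection: the deepest local minimum
   in the upper half (the dim band between skull and T1) and the largest
   discontinuity in the lower half (the onset of the bright pelvis).

2. **Vertebra detection.**  A 51 x 13 window slides along the top of the
   ROI; the maximum-intensity-sum window seeds a chain of reference points
   stepped down 12 rows with a +/-10-column search, six points per central
   line segment (degree-2 fit).  11 x 5 sibling windows slide up to 40
   pixels along the local normals to find the left/right spine boundaries
   (each side fitted with a degree-3 polynomial); midpoints form the
   central spinal curve (CSC).  The spine foreground is split lengthwise
   into thirds, and the outer thirds are thresholded with the progressive
   ladder `gamma_t = 16 t`, `t = 1..15`.  Pixels surviving each threshold
   are projected along the CSC normal into histograms `p_t`; the
   binarised complements `f_t(y) = [p_t(y) == 0]` accumulate into the vote
   histogram `P(y) = sum_t f_t(y)`, which is near zero on vertebrae and
   high on intervertebral discs.  A rise of at least `theta = 8` votes
   from a sustained vertebra-level run opens a 15-bin sub-histogram whose
   first global maximum places a horizontal cut; consecutive cuts bound
   the 17 per-vertebra boxes, each rescaled to a 256 x 128 chip.

3. **Vertebra segmentation.**  Either a training-free classical
   segmenter (Otsu threshold restricted to the chip's central band, hole
   filling, largest component), or one of three encoder-decoder
   convolutional networks: a plain variant (two 3x3 conv/ReLU/batch-norm
   units per level), a residual variant (pre-activation residual blocks
   `x + F(x)` with a 1x1 projection when channel counts change), and a
   dense variant (dense blocks whose layers consume the concatenation of
   all previous outputs, `l` layers of growth `k` emitting `l * k` maps,
   then a 1x1 transition).  All variants share the topology: per encoder
   level a feature block then 2x2 max-pooling; per decoder level 2x2
   transposed-convolution upsampling, a 3x3 convolution halving the
   channels, concatenation with the matching encoder map (no cropping),
   and a feature block; a 1x1 head squashed logistically to a [0, 1]
   probability map, thresholded at 0.5.  Training minimises the mean
   squared (L2) loss with Adam at learning rate 0.01, batch size 10, 100
   epochs by default, with augmentation (rotation within 5 degrees,
   translation within 5 pixels, intensity scale 0.9-1.1) inflating each
   training fold, of which 10% is held out for validation tracking.

4. **Cobb angle.**  Each segmented mask is reconstructed in ROI
   coordinates and its minimum-area bounding rectangle computed by a
   rotating-calipers search over convex-hull edge directions.  The
   rectangle edges closest to horizontal stand in for the endplates; with
   per-vertebra slopes `m_i` the angle is

   `phi = max over (a, b), b - a >= 2 of atan | (m_a - m_b) / (1 + m_a m_b) |`

   i.e. the maximum angle between the upper border of an upper vertebra
   and the lower border of a lower vertebra at least one vertebra apart.
   The sign is negative for right-bending curves (maximising upper slope
   below the lower one).  Severity grades: below 10 degrees "spinal
   curve", 10-20 mild, 20-40 moderate, above 40 severe (lower-inclusive
   bands).

## The phantom model

No clinical images ship with the package; every stage is exercised on
synthetic AP phantoms with analytically known geometry
(`phantom_spec()` / `generate_phantom()`):

* 17 vertebrae (12 thoracic + 5 lumbar) drawn as axis-tilted rectangles
  (192 x 176 px at full scale, 32 px gaps) on a 4736 x 1200 canvas,
  matching the pixel scale the published window parameters (H = 51,
  W = 13, ...) were chosen for after quarter downscaling.
* An S-shaped centerline whose tangent carries two opposite Gaussian
  bumps (width one vertebra period) of amplitude `tan(cobb/2)`, so the
  ground-truth Cobb angle is exact by construction; each vertebra is
  tilted to the local tangent, as vertebral bodies are in a scoliotic
  spine.
* Intensities: soft-tissue background 50, intervertebral gap 75 (1.5 x
  background), vertebrae ramping 215 (T1) to 250 (L5) — the lumbar
  region is brighter, as on real AP films; bright head and hip blobs
  bound the spine so ROI isolation has structures to exclude; additive
  Gaussian noise (sd 5) clipped to 0-255, applied after the noise-free
  masks are stored.

What the phantom does *not* model: vertebral texture (pedicles,
processes, endplate curvature), ribs and soft-tissue gradients,
projection effects, exposure variation, and pathology such as wedged or
fused vertebrae.  Passing tests therefore demonstrate the geometric and
statistical machinery — ROI logic, vote-histogram separation, rectangle
geometry, network training mechanics — not clinical readiness.

## Numerical and design choices

Choices the underlying method leaves open, decided here:

* **Column-band rule.**  The printed "mean plus or minus one standard
  deviation" is ambiguous; we use the threshold-crossing reading
  anchored at the profile maximum, with the multiplier `c` exposed.  The
  band is padded laterally by 60 quarter-scale pixels — the boundary
  search range `r = 40` plus the spine half-width — so a displaced curve
  apex keeps its edges inside the crop.
* **Central line fits** are degree 2 per six-point segment (six points
  cannot support more); boundary fits are degree 3 as specified.  A
  single global cubic cannot follow a strongly S-shaped spine, so the
  working CSC is built from the traced boundary midpoints with a running
  median (width 17, rejecting the short runs of unreliable points that
  occur across dim intervertebral gaps) and a 9-row moving average;
  boundary tracing is confined to rows anchored by reference points,
  because extrapolated normals are meaningless.
* **Starting points** are rises of `theta = 8` (a majority of the 15
  votes) within three bins, required to start from a vertebra-level run
  of at least 4 bins — this rejects bright structures bleeding across
  the ROI border.  The first global maximum of a sub-histogram is the
  leftmost bin attaining the maximum.  Cuts beyond the expected 17 are
  dropped with a warning; fewer than 3 boxes is a hard failure (the
  angle is undefined).
* **Vote projection** assigns pixels to CSC bins by the perpendicular
  foot point linearised at the pixel's row, keeping `p_t` integer
  counts.
* **Anisotropy.**  The 256 x 128 chip rescale does not preserve right
  angles, so masks are mapped back through the box transform and the
  minimum bounding rectangle is fitted in image coordinates.
* **Network details** unstated in the source method: probability
  threshold 0.5; logistic squashing before the L2 loss; 1x1 projection
  on residual skips when channels change; dense-block transition as a
  1x1 convolution back to the level's nominal width; channel widths
  configurable with doubling per level.  Batch normalisation uses batch
  statistics in training and running averages (momentum 0.1) at
  inference.
* **Agreement statistics.**  Group descriptives use the population
  (n-denominator) standard deviation, which is what the published
  summary table contains.  Manual observers contribute session 1 by
  default (the published ranges match only that session); the session is
  a parameter.  The intraclass correlation defaults to the two-way
  random-effects absolute-agreement single-measure form ICC(2,1).  The
  rank correlation uses the rank-difference closed form, falling back to
  Pearson-of-ranks under ties.  "No scoliosis" entries count as 0, not
  as missing.  The ICC band printed as "good (0.0-0.74)" in the source
  is implemented as 0.60-0.74 (an evident misprint).

## Problem sizes used by the packaged experiments

The package's own experiments are sized for a single CPU:

* *Cobb recovery*: 50 phantoms with true |Cobb| uniform in 5-45 degrees.
  Feeding ground-truth masks into the rectangle stage isolates the MBR +
  maximum-pair geometry (every case within 2 degrees in our runs); the
  full classical pipeline adds ROI, detection and Otsu segmentation
  (at least 80% within 5 degrees is the acceptance bar; runs reach
  100%).
* *Segmentation cross-validation*
  (`segmentation_cv_experiment()`): the defaults describe the full-size
  experiment (40 phantoms = 680 chips, 5 folds, 256 x 128 chips, base
  width 8, 20 epochs, augmentation to 200).  The packaged tests and the
  acceptance script run a reduced configuration — 9 phantoms (153
  chips), 3 folds, 128 x 64 chips, base width 4, 6 epochs, augmentation
  to 160 — chosen so the whole experiment trains all three variants in
  about ten minutes on one core.  The phantom chips are nearly bimodal,
  so held-out Dice coefficients reach 0.99 for every variant at this
  scale; the comparison across variants (means within 0.05) is the
  meaningful check, not the absolute level, which real radiographs
  would lower substantially.

## Known limitations

* The detector assumes an upright, single, complete T1-L5 spine; the
  optional principal-axis pre-rotation is a crude stand-in for the
  alignment step of a clinical system.
* Sub-histogram cuts sit at the first disc bin rather than the disc
  centre, so each box carries its trailing disc; the classical
  segmenter's largest-component rule and the MBR absorb this.
* At severe curvature (above roughly 30 degrees) the vote contrast at
  the apex occasionally merges two vertebrae into one box; the
  maximum-pair angle is usually unaffected (the merged rectangle's
  borders still track the end vertebrae), which is why angle recovery
  holds even when the box count slips to 16.
* The networks are plain R + compiled primitives on one CPU; they are
  meant for method study and desk-scale experiments, not for training on
  clinical volumes.
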