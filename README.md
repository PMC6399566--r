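# spinecobb

Automatic measurement of spinal curvature (the Cobb angle) from
anterior-posterior (AP) view spine radiographs, for researchers studying
scoliosis assessment pipelines and for method development without access
to clinical images.

The Cobb angle is the clinical standard for grading scoliosis: the angle
between the upper endplate of the most-tilted upper vertebra *a* and the
lower endplate of the most-tilted lower vertebra *b*.  With per-vertebra
endplate slopes *m*, the package computes

    phi = max_{(a,b), b-a>=2}  atan | (m_a - m_b) / (1 + m_a m_b) |

signed negative for right-bending curves, and grades it (&lt;10° spinal
curve, 10–20° mild, 20–40° moderate, &gt;40° severe).

The pipeline:

1. **ROI isolation** — quarter-scale block averaging, then projection
   profiles: the column band around the profile maximum above
   mean + sd, and the row band between the skull/T1 intensity dip and
   the pelvis discontinuity.
2. **Vertebra detection** — maximum-intensity sliding windows trace the
   central line; sibling windows find the left/right spine boundaries;
   a progressive threshold ladder (16, 32, …, 240) projected along the
   spine midline accumulates a vote histogram that separates vertebrae
   (few votes) from intervertebral discs (many votes), yielding 17
   vertebra boxes rescaled to 256×128 chips.
3. **Segmentation** — a training-free classical segmenter (Otsu +
   morphology), or encoder-decoder convolutional networks (plain,
   residual and dense variants) implemented natively with compiled
   primitives and trained with Adam on the mean-squared loss.
4. **Cobb geometry** — minimum-area bounding rectangles (rotating
   calipers) on the masks reconstructed in image coordinates; rectangle
   top/bottom edges stand in for the endplates; maximum-pair angle as
   above.

A synthetic phantom generator renders AP-like radiographs (17 tilted
vertebral bodies on an S-shaped centerline, intensity ramp, head/hip
blobs, noise) with analytically known endplate slopes and Cobb angle, so
every stage is testable end to end.  The package also ships a
35-radiograph clinical measurement table (expert, novice and automatic
readings) and the observer-agreement battery — descriptives, one-way
ANOVA, Pearson, Spearman and intraclass correlation — that reproduces
the published agreement analysis.

## Worked example

```r
library(spinecobb)

# a severe-ish right-bending phantom with known geometry
spec   <- phantom_spec(cobb_deg = 25, direction = "right", seed = 42)
sample <- generate_phantom(spec)
sample$true_cobb_deg        # -25  (negative: curves to the right)

m <- measure_spine(sample$image)   # classical (training-free) segmenter
m$cobb
#> Cobb angle: -25.1 deg (|phi| = 25.1, moderate scoliosis)
#> End vertebrae: T5 to T11 (of 17)
```

The measured −25.1° recovers the ground truth within 0.1°; the selected
end vertebrae (T5, T11) are the apex vertebrae of the generated curve.

Observer agreement on the packaged measurement table:

```r
rpt <- agreement_report(load_table4(), session = 1)
sprintf("expert mean %.3f sd %.3f", rpt$groups$expert$mean, rpt$groups$expert$sd)
#> "expert mean -0.703 sd 12.552"
rpt$pairs
#>            pair pearson spearman   icc  icc_band
#> 1 expert-novice   0.929    0.889 0.927 excellent
#> 2    expert-mbr   0.953    0.894 0.954 excellent
#> 3    novice-mbr   0.948    0.925 0.943 excellent
rpt$anova[c("F", "p")]        # F = 0.024, p = 0.976
```

The automatic (MBR) readings agree with both observers at ICC and
Pearson above 0.94 ("excellent"), and the ANOVA finds no significant
difference among the three measurement sources — manual and automatic
measurements are statistically interchangeable on this table.

Training a network instead of the classical segmenter:

```r
ds  <- make_dataset(6, seed = 1, chip_shape = c(128, 64))
net <- build_network(network_spec("residual", input_shape = c(128, 64),
                                  base_channels = 4))
net <- train_network(net, ds$chips, ds$masks,
                     training_config(epochs = 6, augment_to = 160))
mask <- predict_mask(net, ds$chips[, , 1])
```

A command-line wrapper is installed at `inst/cli/spinecobb`
(`simulate`, `roi`, `detect`, `measure`, `evaluate`, `stats`).

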