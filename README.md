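# marrowmeter

Automated assessment of **bone marrow cellularity** from H&E histology
images. Cellularity — the percentage of marrow occupied by hematopoietic
(blood-forming) tissue as opposed to adipose (fat) tissue — is a key
diagnostic feature in Ph-negative myeloproliferative neoplasms, and visual
estimates through the microscope vary between observers. `marrowmeter`
segments every pixel of a scanned biopsy image as hematopoietic or adipose
with a fully convolutional network and computes

```
cellularity = A_hemato / (A_hemato + A_adipose) × 100%
```

together with the agreement statistics used to compare automated and human
readings: **Lin's concordance correlation coefficient** (population-variance
estimator `2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`, Fisher-z confidence
intervals, Altman grading: > 0.8 optimal, 0.6–0.8 substantial) and
**Bland–Altman limits of agreement** (`d̄ ± 1.96·S_d`).

The package is written for digital-pathology method developers: it contains
the full training/inference workflow (QuPath-style colour-coded label masks,
ignore-class-masked cross-entropy, slide tiling/stitching, overlay
rendering) plus a seeded **synthetic histology generator** with known ground
truth, so the entire pipeline is testable without clinical material. The CNN
engine (convolutions, transposed convolutions, Adam) is implemented in the
package with RcppArmadillo and verified against numeric gradients.

## Worked example

The end-to-end demo generates a synthetic training set, trains the compact
FCN, scores 10 pseudo-slides with known ground truth, simulates a panel of
human raters, and writes every artifact (config snapshot, manifest, history,
checkpoint, cellularity CSV, agreement tables, Bland–Altman plot, overlay):

```r
library(marrowmeter)
report <- run_end_to_end("demo_out", seed = 1)
#> ...
#> epoch 10/10  loss 0.0353  acc 0.9858  val_loss 0.0319  val_acc 0.9875
#> [segment] scoring 10 pseudo-slides
#> [agree] agreement statistics
#> model vs truth: CCC 0.9995 (optimal), MAE 0.59 pp
```

The per-slide table (`demo_out/cellularity.csv`) compares the mask-derived
true cellularity with the model's estimate:

```
   true_cellularity cellularity
1             10.27       10.54
2             20.14       20.18
3             29.18       29.22
...
10            94.76       92.84
```

and the agreement table (`demo_out/agreement_vs_mean.csv`) grades the model
and three simulated expert raters against the panel mean, e.g. the model
reaches CCC 0.988 (95% CI 0.953–0.997, optimal). A training loss of ~0.035
and masked validation accuracy of ~0.99 indicate the fixture network has
essentially learned the two-tissue texture; the 0.59 pp mean absolute error
shows the tiling/stitching/ratio pipeline recovers slide-level truth.

Individual pieces are exported directly, for example:

```r
tile  <- generate_tile(tile_spec(tile_size = 64, target_cellularity = 70, seed = 1))
model <- load_model("demo_out/model.rds")
res   <- segment_slide(model, read_image("slide.png"))
res$cellularity
lin_ccc(c(60, 35, 80, 50), c(55, 40, 85, 45))
```

A command-line wrapper with subcommands `synth`, `manifest`, `train`,
`segment`, `agree`, `demo` is installed at
`system.file("scripts/marrowmeter", package = "marrowmeter")`; YAML configs
hold the spec fields of the corresponding R functions, and exit codes are 0
(success), 2 (validation error), 1 (runtime failure).

## Scope

Slides are consumed as single plain raster images (PNG/TIFF) at native
resolution. Pyramidal/proprietary scanner formats, stain normalization, and
multi-class cell-lineage segmentation are out of scope. See the methods
vignette (`vignettes/marrowmeter-methods.Rmd`) for the model, the synthetic
data design and its limits, and all numerical conventions.
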