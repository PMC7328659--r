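# fernmask

Binary plant-tissue masks for digitized herbarium sheets.

Herbarium sheet photographs mix the specimen with rulers, color bars,
barcodes, stamps, labels and decades of dust. Models trained on whole
sheets can end up learning these collection-specific cues instead of the
plant. `fernmask` implements a complete, reproducible workflow for
separating plant pixels from everything else:

1. **Automatic thresholding** — Otsu's method on the grayscale histogram:
   the threshold `t` maximizes the between-class variance
   σ²_b(t) = ω₀ω₁(μ₀ − μ₁)², and dark pixels (plants on off-white paper)
   become the white foreground mask of a complementary
   foreground/background pair.
2. **Post-processing** — re-binarization of (possibly hand-edited) masks
   followed by a median-filter despeckle sweep that removes dust specks
   mislabeled as plant; all sweep candidates are written and a human picks
   the best one.
3. **Segmentation network** — a U-Net-style encoder–decoder (stride-2
   encoder, mirrored decoder with skip concatenation, per-pixel sigmoid
   scores), implemented in pure R matrix algebra, trained with paired
   image/mask augmentation (horizontal flip p = 0.5; rotation ≤ 10°, zoom
   ≤ 1.1, perspective warp ≤ 0.2, lighting ≤ 0.2, each at p = 0.75) under
   the one-cycle learning-rate policy.
4. **Evaluation** — Sørensen–Dice (2|A∩B| / (|A|+|B|)) and pixel accuracy
   per image, aggregated per family and overall, at model resolution
   (65,536 pixel predictions per 256 × 256 mask).
5. **Synthetic sheets** — a seeded generator of herbarium-sheet scenes
   (aging paper, branching fern silhouettes, label/color bar/ruler/
   barcode/stamp, debris) with pixel-perfect ground truth, so the whole
   pipeline runs and is tested without downloading any imagery.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(fernmask)

# a synthetic sheet with ground truth
sp <- generate_sheet(sheet_config(seed = 7))
sp
#> Synthetic herbarium sheet 910 x 680 px, Nanofolium tenuis (Nanofoliaceae), plant fraction 0.124

# stage 1: automatic masks
am <- auto_mask(sp$image)
am$otsu
#> Otsu threshold: 112 (between-class variance 3022.4881)
dice(am$pair$foreground, sp$truth)
#> [1] 0.9678

# stage 2: despeckle the polluted auto-mask
cleaned <- despeckle(am$pair$foreground, kernel = 5)
dice(cleaned, sp$truth)
#> [1] 0.9861

# stages 3-4: train on a small synthetic dataset and inspect the history
sheets <- lapply(1:40, function(i) {
  s <- generate_sheet(sheet_config(seed = i))
  list(image = s$image, mask = s$truth)
})
cfg <- train_config(image_size = 128, epochs = 10, encoder_depth = 3,
                    base_channels = 8, batch_size = 4, lr_max = 0.01,
                    loss = "dice", seed = 1)
fit <- fit_segnet(NULL, sheets, cfg)
glance(fit$history)
#> # A tibble: 1 × 6
#>   epochs train_loss val_loss val_dice n_train n_val
#>    <int>      <dbl>    <dbl>    <dbl>   <int> <int>
#> 1     10      0.139    0.146    0.881      32     8

pred <- predict_mask(fit$model, sp$image)   # 128 x 128 binary mask
mean(pred == 255)
#> [1] 0.1968
```

The numbers read as follows: Otsu alone reaches Dice ≈ 0.97 against the
ground truth (the shortfall is thin dark elements — barcode bars, ruler
ticks, label text, debris — mislabeled as plant); despeckling removes
them and lifts the mask to ≈ 0.99. Training on just 32 sheets reaches
validation Dice 0.88; the reference benchmark below, with 160 training
sheets, reaches ≈ 0.96. The predicted foreground fraction (0.197) exceeds
the whole-sheet plant fraction (0.124) because prediction happens on the
center square crop, which concentrates on the specimen.

The pipeline is also scriptable stage by stage:

```sh
Rscript inst/cli/fernmask.R synth    --n 25 --out data/ --seed 1
Rscript inst/cli/fernmask.R automask --in data/ --out masks/
Rscript inst/cli/fernmask.R postprocess --in masks/ --out final/
Rscript inst/cli/fernmask.R train    --manifest data/metadata.csv --out run/ \
        --size 128 --depth 3 --epochs 10
Rscript inst/cli/fernmask.R evaluate --checkpoint run/checkpoint.rds \
        --manifest data/metadata.csv --out run/
Rscript inst/cli/fernmask.R predict  --checkpoint run/checkpoint.rds \
        --out preds/ data/sheet_0001.png
```

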