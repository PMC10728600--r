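# dcsanet

Lightweight encoder–decoder semantic segmentation of soybean-field imagery:
per-pixel classification into soil background, soybean, graminoid weed
(grasses such as *Digitaria*, *Setaria*) and broadleaf weed (*Chenopodium*,
*Amaranthus*, …). Separating the two weed families matters because they are
treated with different herbicides; doing it with a ~0.5 M-parameter model
matters because the consumers are drones and unmanned weeders, not servers.

The core is **DCSAnet**: a 3×3 stride-2 stem, three stages of **DCA blocks**,
and a guided-aggregation decoder. A DCA block is an inverted-residual
bottleneck that expands channels fourfold with a 1×1 convolution, splits the
expanded map into two halves filtered by asymmetric depthwise pairs (`N×1`
then `1×N`; kernel 3 on one branch, `N ∈ {5,7,9}` on the other), projects
back with a 1×1 convolution, and mixes the branch halves with a channel
shuffle (reshape `g×n` → transpose → flatten). Mode A preserves shape and
adds a residual; mode B halves the resolution with stride-2 filtering plus a
max-pooled skip, doubling the channels. The encoder emits `feat1/feat2/feat3`
at 1/4, 1/8, 1/32 scale; the decoder upsamples stepwise and, in the guided
variants, modulates `feat1` by a transformed deep map via elementwise
multiplication before fusion (optionally with a residual).

Cost accounting follows the closed forms for an `H×W` output map:
standard convolution `H·W·N²·C1·C2` MACs; depthwise-separable
`H·W·N²·C1 + H·W·C1·C2` (a fraction `1/C2 + 1/N²` of standard); asymmetric
`2·H·W·N·C1·C2` (a fraction `2/N`). Training uses mean pixelwise
cross-entropy `−(1/N)Σᵢ Σ_c y_ic log p_ic` with Adam; evaluation reports
per-class IoU `TP/(TP+FP+FN)` and its unweighted mean (MIoU) over all
classes, accumulated at the dataset level.

Everything runs in plain R on a bundled reverse-mode autodiff engine (BLAS
matrix ops; no deep-learning framework needed). A synthetic field-scene
generator with exact ground-truth masks makes the whole pipeline testable
without the original (non-public) dataset.

## Worked example

Build the full calibrated model and read off its analytic cost:

```r
library(dcsanet)
model <- dcsanet(dcsa_config(), seed = 1)
summary(model)
#> DCSAnet cost report (input 512x512)
#>   parameters: 556,770  (0.5568 M)
#>   FLOPs:      18.039 G  (2 x MACs, conv/dense layers)
```

0.557 M parameters and 18.04 GFLOPs at 512×512 for the feat3-guided residual
decoder; the plain-decoder variant
(`dcsa_config(decoder_variant = "plain")`) comes to 0.463 M and 17.02 G.

Train a small variant on eight synthetic 128×128 scenes and score it:

```r
scenes <- generate_dataset(8, scene_spec(size = 128), seed = 11)
small <- dcsanet(dcsa_config(stem_channels = 4,
                             decoder_widths = c(16, 16, 16, 12, 12)), seed = 5)
fit <- train_dcsanet(small, scenes,
                     config = train_config(initial_lr = 0.003, epochs = 300,
                                           batch_size = 4, seed = 3,
                                           miou_every = 10, target_miou = 0.90))
evaluate_model(fit, scenes)
#> MIoU: 0.9055
#> per-class IoU: 0: 0.9612  1: 0.8741  2: 0.8800  3: 0.9067
```

Training stops early (epoch 130 here) once training MIoU crosses 0.90: the
classes are drawn with distinct shape signatures — grass strokes share the
soybean hue on purpose — so a correctly wired model must and does learn
shape. `plot(fit)` draws the loss history; `predict(fit, image)` returns
label masks.

The decoder ablation grid reproduces the cost columns of the five variants:

```r
run_ablation(seed = 1)
#>                   model  flops_g  param_m miou_pct
#> 1                 plain 17.01966 0.463242       NA
#> 2          feat2_guided 17.14706 0.471090       NA
#> 3          feat3_guided 18.03888 0.556770       NA
#> 4 feat2_guided_residual 17.14706 0.471090       NA
#> 5 feat3_guided_residual 18.03888 0.556770       NA
```

(pass `train =` / `eval =` sample lists to fill the MIoU column).

The data pipeline mirrors the original preprocessing recipe: LabelMe JSON polygons
are rasterized to 4-class index masks (`rasterize_annotation()`), 512×512
windows are cropped at random (`random_crop()`), every sample is expanded
exactly fivefold — rotation, flip, Gaussian noise, contrast —
(`augment_dataset()`), and `split_dataset()` cuts 6:3:1 train/val/test. A
thin CLI (`inst/cli/dcsanet.R`) exposes `synth`, `prepare`, `train`, `eval`,
`summary` and `ablate` over YAML run configs with provenance records.

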