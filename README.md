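# fundusseg

Joint segmentation of the optic disc (OD) and optic cup (OC) in retinal
fundus photographs, for cup-to-disc-ratio based glaucoma screening. The
package implements the full method as reusable R components:

- **MSRCR enhancement** — multi-scale Retinex with colour restoration:
  per channel, `R_σ = log(I + ε) − log(G_σ * I + ε)` averaged over surround
  scales (default 15/80/250 px) and multiplied by the colour-restoration
  factor `C_i = β [log(α I_i + ε) − log(I_R + I_G + I_B + ε)]`, then
  percentile-clipped and rescaled to [0, 255]. Sharpens the faint disc/cup
  boundaries while normalising illumination and colour casts.
- **Polar warping** — pixel-wise resampling about the disc centre
  (`x = r cos θ`, `y = r sin θ`), turning nested disc/cup ellipses into
  stacked horizontal bands and rebalancing class frequencies, with an exact
  inverse for mapping predictions back to image space.
- **RSAP-Net** — a U-shaped residual encoder–decoder whose skip connections
  are replaced by three residual spatial-attention paths (channel-max +
  channel-mean maps → 3×3 conv → LeakyReLU gate), with a bottleneck context
  extractor combining cascaded dilated convolutions (rates 1/2/5) and a
  global information coding block. Trained with three-class softmax
  cross-entropy by SGD (lr 0.001, momentum 0.9, weight decay 5e-4). The
  network, its gradients and the optimiser are implemented in the package on
  RcppArmadillo kernels — no external deep-learning framework is required.
- **Evaluation** — F1 / accuracy / specificity / sensitivity per structure,
  the radial boundary localization error `BLE = mean_θ |d_g^θ − d_0^θ|` over
  24 equidistant directions from the disc centre, and the vertical
  cup-to-disc ratio VCD/VDD.
- **Synthetic fundus generator** — seeded, ground-truthed images (reddish
  vascularised background, uneven illumination, bright elliptical disc,
  blurrier nested cup with controllable vertical CDR) so the entire pipeline
  is testable end to end without clinical data.

## Worked example

```r
library(fundusseg)

# a seeded synthetic fundus image with ground truth
g <- generate_synthetic_fundus(synthetic_fundus_params(image_size = 128), seed = 7)
vertical_cdr(g$mask)
#> [1] 0.425

# enhance, then warp to polar coordinates about the disc centre
enh  <- msrcr(g$image)
grid <- polar_grid(g$center, max_radius = 48, n_radii = 128, n_angles = 128)
px   <- to_polar(enh, grid, "bilinear")
pm   <- matrix(as.integer(to_polar(g$mask, grid, "nearest")), 128, 128)

# a quick single-image training demo (400 SGD steps; a real run needs a
# cohort and more updates -- see the desk-scale experiment below)
model <- rsap_net(model_config(input_size = 128, base_channels = 8), seed = 1)
train_model(model, list(px), list(pm), epochs = 400, lr = 0.001, momentum = 0.9)
pred  <- from_polar(predict_mask(model, px), grid, dim(g$mask), "nearest")
evaluate_masks(matrix(as.integer(pred), 128, 128), g$mask)[, c("F1_OD", "F1_OC", "BLE_OD", "BLE_OC")]
#>       F1_OD     F1_OC   BLE_OD  BLE_OC
#> 1 0.8018555 0.7366972 8.853186 27.0318
```

The desk-scale reference experiment (200 train / 50 test synthetic images,
10 epochs, full MSRCR + polar + RSAP-Net pipeline, ~10 min on one CPU):

```r
r <- run_desk_experiment(seed = 1)
print(r$report)
#> Segmentation metrics over 50 images
#>       F1_OD ACC_OD SPC_OD SEN_OD BLE_OD  F1_OC ACC_OC SPC_OC SEN_OC BLE_OC CDR_pred CDR_gt
#> mean 0.9802 0.9920 0.9974 0.9731 0.5428 0.9707 0.9967 0.9992 0.9633 0.4548   0.5471 0.5449
#> sd   0.0075 0.0034 0.0032 0.0190 0.2424 0.0121 0.0017 0.0006 0.0223 0.1541   0.1337 0.1415
```

F1 is the overlap quality per structure (1 = perfect), BLE the mean radial
boundary error in pixels (lower is better; here sub-pixel), and the CDR
columns show the clinically relevant ratio recovered from predictions versus
ground truth.

A thin command-line front end wraps the same functions
(`inst/cli/fundusseg`): `generate-synthetic`, `preprocess msrcr|polar|msrcr-pt`,
`train`, `predict`, `evaluate`, `ablate`.

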