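---
title: "Joint optic disc and cup segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint optic disc and cup segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundusseg)
```

## The problem

Glaucoma screening from fundus photographs hinges on the vertical cup-to-disc
ratio (CDR): the vertical extent of the optic cup (OC) divided by that of the
optic disc (OD), with values above about 0.5 indicating elevated risk.
Measuring it automatically requires segmenting both structures, which is hard
because the cup boundary is faint, the cup occupies few pixels (class
imbalance), and illumination and colour vary strongly between images. The
package addresses this with three cooperating pieces: a colour-restoring
Retinex enhancer, a polar re-parameterisation of the image about the disc
centre, and a U-shaped attention network trained with three-class
cross-entropy (background / disc / cup, encoded 0/1/2).

## MSRCR enhancement

Single-scale Retinex compares each pixel to a Gaussian surround in log space,

$$R_\sigma(x, y) = \log(I + \epsilon) - \log(G_\sigma * I + \epsilon),$$

compressing illumination gradients while amplifying local edges. The
multi-scale form (MSR) averages several surrounds, and MSRCR multiplies MSR by
a per-channel colour-restoration factor
$C_i = \beta\,[\log(\alpha I_i + \epsilon) - \log(I_R + I_G + I_B + \epsilon)]$
so that strongly red fundus images keep their chromatic balance. Defaults are
the standard constants for this family: surround scales 15/80/250 px with
equal weights, $\alpha = 125$, $\beta = 46$, percentile clip (1, 99) and a
per-channel rescale to [0, 255]. All are overridable through
`retinex_params()`. Numerical choices worth knowing:

* the surround is a separable Gaussian truncated at $3\sigma$ with symmetric
  (edge-included) reflection at borders, so results are reproducible to the
  bit across platforms;
* natural logarithms throughout ($\epsilon = 1$ guards zeros; with
  $\epsilon = 0$ the operator is exactly invariant to global intensity
  scaling, which the tests assert);
* a channel with no dynamic range after clipping (constant or all-zero
  images) maps to the mid-range constant 127.5 rather than erroring, so batch
  pipelines never stop on degenerate frames.

## Polar warping

`to_polar()` resamples the image onto a (radius, angle) grid centred on the
disc: radii $r_i = R\,i/(n_r - 1)$ along rows, angles
$\theta_j = 2\pi j / n_\theta$ along columns, sampling the source at
$(c_x + r\cos\theta,\; c_y + r\sin\theta)$. Axes follow the raster
convention (x = column rightward, y = row downward, $\theta$ clockwise on
screen from +x, half-open $[0, 2\pi)$). The nested disc/cup geometry becomes
stacked horizontal bands, which both balances class frequencies and turns the
roughly circular boundaries into roughly straight ones. `from_polar()` is the
exact inverse sampler used to map predictions back before scoring; masks
always use nearest-neighbour interpolation so labels stay in {0, 1, 2}, and
pixels beyond the sampled radius take background. Intensities use bilinear
interpolation with angular wrap-around at the $\theta = 0$ seam. A 256×256
polar grid round-trips a 101×101 radial gradient with a mean absolute error
below 0.1 intensity units and recovers 100% of mask labels inside the radius
(the test suite asserts <2 and ≥99%).

The disc centre comes from the ground-truth mask centroid during training and
from the user (or the image centre) at inference; bundling a trained disc
detector is out of scope. The default polar size equals the network input
size so warped images feed the model directly, and the default radius is the
largest circle inscribable about the centre.

## RSAP-Net

The network is a U-shaped encoder–decoder:

* **Encoder** — a stem 3×3 convolution, then four residual stages (two 3×3
  convolutions with normalization and LeakyReLU, additive identity with a 1×1
  projection when widths change), each scale transition via 2×2 max pooling.
  Five feature scales result: S/2 … S/32 (256/128/64/32/16 at the standard
  input S = 512). Stage widths default to base_channels × (1, 2, 4, 8, 16).
* **Bottleneck** — a multi-branch dilated-convolution block (MDC): an
  identity branch plus cascaded 3×3 branches with dilation rates 1, 1→2 and
  1→2→5 (receptive field 17 px), each closed by a linear 1×1 convolution, all
  summed; then a global information coding block (GIC): 2×2-stride-2 and
  3×3-stride-3 convolution branches plus 5×5 and 6×6 max-pool branches, each
  reduced to one channel by a 1×1 convolution and bilinearly upsampled back,
  concatenated with the input (channels grow by exactly 4).
* **Bridges** — three residual spatial-attention paths (RSAP) connect the
  three shallowest encoder scales to the decoder. Each applies a few residual
  blocks, then modulates the result by a spatial attention map: channel-wise
  max and mean maps are concatenated, convolved 3×3 to one channel and passed
  through LeakyReLU; the modulated features are added to the upsampled
  decoder features. Depths default to (3, 2, 1), shallowest first, because
  the encoder–decoder feature gap is largest at shallow scales; depth 0
  degrades a bridge to a plain additive skip, which is exactly the ablation
  baseline.
* **Decoder** — four blocks of two 1×1 convolutions and a 3×3 transposed
  convolution with stride 2, a final 2× transposed-convolution head and a
  linear 1×1 projection to three logits at full resolution.

The loss is the standard three-class softmax cross-entropy per pixel,
averaged over pixels; training uses SGD with learning rate 0.001, momentum
0.9 and weight decay 0.0005 (the reference protocol), with gradients
accumulated over `batch_size` images between updates.

Implementation notes:

* All tensors are H×W×C arrays; convolutions run through im2col + GEMM
  kernels in compiled code, and a small reverse-mode tape provides exact
  gradients (verified against finite differences in the test suite, to
  ~1e-8 relative error with a 1e-5 step).
* Normalization statistics are per-image spatial moments (instance-style) in
  both training and inference. Training processes one image at a time, so
  this is identical to batch normalization at batch size one while keeping
  inference deterministic with no running averages.
* Weights are He fan-in initialised under a user seed; identical config and
  seed give bit-identical models, forwards and training runs on one machine.
* Inputs are mapped from [0, 255] to [−1, 1] before the stem.
* When the bottleneck is smaller than the nominal GIC windows (input sizes
  below 192), the branch windows shrink to the bottleneck size so the block
  stays well-defined; the standalone `gic_block()` keeps the strict ≥6
  contract.

## Synthetic data

`generate_synthetic_fundus()` emulates the structure of disc-centred fundus
photographs: a reddish background (RGB ≈ 175/78/52) with a random linear
illumination ramp (default peak-to-peak 40 intensity units) and smooth
texture noise; 2–8 dark curved vessel strokes; a bright yellowish elliptical
disc (vertical semi-axis 26–40 px on the default 128 px canvas,
eccentricity 0.85–1.15) with a Gaussian-blurred rim (σ = 2 px); and a
brighter, blurrier (σ = 3.5 px) cup strictly inside the disc. The target
vertical CDR is drawn uniformly from `cdr_range` (default 0.3–0.8) and the
cup's vertical semi-axis is solved against the rasterised disc extent so the
measured `vertical_cdr()` of the mask lands within ±0.02 of the target. The
ground-truth mask comes from the analytic ellipse geometry, not from the
rendered intensities. Everything is a deterministic function of the seed.

What the generator does *not* emulate: pathology (hemorrhages, exudates,
peripapillary atrophy), vessel occlusion of the cup boundary, camera vignetting,
inter-expert annotation ambiguity, or photorealistic texture. Passing the
end-to-end tests therefore demonstrates that the pipeline's machinery —
enhancement, warping, optimisation, inverse mapping, scoring — is correct and
trainable, not that clinical-grade accuracy would be reached on real fundus
datasets, where boundaries are far more ambiguous.

## Evaluation

For each structure (disc: labels {1, 2}, since the cup is anatomically part
of the disc; cup: label {2}) the suite reports F1/precision/recall,
specificity TN/N, sensitivity TP/P and accuracy, where the decomposition
ACC = SPC·N/(P+N) + SEN·P/(P+N) = (TP+TN)/(P+N) holds to machine precision.
The boundary localization error (BLE) averages, over 24 equidistant
directions from the disc centre, the absolute radial distance between the
predicted and reference boundaries. Boundary radii are found by exact
cell-by-cell ray traversal to the far edge of the outermost positive pixel —
a fixed-step march can skip pixels whose cells the ray merely clips, which
is why the implementation is exact; the tests cross-check it against a
brute-force fine-step marching oracle. The degenerate conventions: 0/0 rates
are 0 for F1 and `NA` (flagged) for SPC/SEN; a missing structure makes BLE
the full radial extent of whichever boundary exists, flagged. The printed
per-direction form $\sqrt{d_g^2 - d_0^2}$ is available behind
`form = "signed_sqrt"` but errors whenever the prediction overshoots the
reference, which is why the absolute-difference form is the default.

## Desk-scale experiment

`run_desk_experiment()` is the package's end-to-end reference run, sized for
a single CPU: 200 training and 50 held-out synthetic 128×128 images, MSRCR
enhancement, polar warping at 128×128, a width-reduced network (stage widths
8/16/32/64/128, ≈1.6 M parameters), 10 epochs of SGD at the reference
optimiser settings with batch size 1, prediction, inverse polar mapping and
Cartesian scoring. With seed 1 it reaches disc F1 ≈ 0.98, cup F1 ≈ 0.97 and
sub-pixel BLE in about 10 minutes; `scripts/acceptance.R` re-runs it from
scratch. At these sizes one SGD step costs ≈0.3 s; the full 512-px
configuration (≈25 M parameters) forwards in ≈25 s and is exercised
shape-wise in the tests, while full-scale training is a GPU-class workload
outside the package's scope.

A note on optimisation speed: at learning rate 0.001 with momentum 0.9 the
loss on a single polar-warped synthetic image crosses 0.05 after roughly
1.2–1.5 k steps (a 10× learning rate gets there in under 200 steps). The
trainability test therefore allows 1800 steps at the reference settings.

## Limitations

* The disc centre must be supplied (or taken from masks) — no detector is
  bundled, and polar warping degrades if the centre is badly off.
* Per-image normalization statistics mean very small inputs (below ~32 px)
  are poorly conditioned.
* Training is single-threaded CPU; the package is sized for method study and
  testing, not large-scale benchmarking.
* The augmentation-equivalence of pointwise enhancement and polar warping
  holds exactly only for pointwise operators; MSRCR is spatially varying, so
  the pipeline always enhances before warping rather than relying on
  commutativity.
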