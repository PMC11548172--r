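---
title: "Zero-shot denoising of light-sheet microscopy frames: methods and design"
author: "ZSDenoise authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot denoising: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ZSDenoise)
```

## The problem

Light-sheet microscopy of living 3-D cell aggregates (spheroids) often
operates in a low-light regime: elastic (Rayleigh) scattering channels are
read-noise limited, inelastic (Raman) channels are weak enough that impulse
("salt-and-pepper") outliers and heavy read noise dominate, and fluorescence
channels are photon limited. Classical supervised denoisers need clean/noisy
training pairs, which a live microscopy experiment cannot provide.

ZSDenoise implements a *zero-shot*, self-supervised restoration scheme: the
denoiser is a small convolutional encoder–decoder trained **on the single
input frame itself**, with no external dataset, no pre-trained weights, and
no clean reference. The package also provides the quality instrumentation —
PSNR, SSIM, RMSE and Fourier ring correlation (FRC) with a resolution-cutoff
estimate — and a synthetic spheroid phantom so the whole pipeline can be
exercised and validated without microscope data.

## The training scheme

From a normalized noisy frame $I$ two corrupted renditions are built with a
seeded zero-mean Gaussian field $n$ of standard deviation $\sigma_p$:

$$A = I + n, \qquad B = I - n .$$

No clipping is applied at this stage, so $\tfrac{1}{2}(A + B) = I$ holds
exactly (to the last floating-point ulp) — this algebraic identity is used
throughout the test suite as the correctness oracle for pair construction.
Both renditions are then median filtered with a $3\times3$ kernel
(edge-replicated borders), which suppresses high-intensity impulse outliers
while preserving edges. The filtered renditions are the actual training
input and target.

The network $f_\theta$ is trained to predict the filtered $B$ from the
filtered $A$ by minimizing

$$L(\theta) = \operatorname{mean}\big(f_\theta(A) - B\big)^2
  + \lambda \, \operatorname{mean}\big(|\partial_x f_\theta(A)| +
  |\partial_y f_\theta(A)|\big),$$

i.e. a pixel-wise MSE data term plus an optional anisotropic
total-variation penalty with weight $\lambda$. Because the noise in $B$ is
the sign-flipped noise of $A$, it is unpredictable from $A$; the
minimum-risk prediction is the underlying structure, which is why training
between two corrupted renditions denoises without ever seeing a clean
image (the noise2noise principle).

Two readings of the data term are possible: the one above (rendition
$A \to B$, matching the training-workflow description) and a raw-anchored
variant in which the network reconstructs the raw frame directly. The
pair-based form is the default; `dataTarget = "raw"` selects the variant.

### Discretization choices

* $\nabla$ is realized as **forward finite differences with edge
  replication** (the difference across the last row/column is zero) and the
  $\ell_1$ magnitude, i.e. anisotropic total variation. No discretization
  is canonical here; this one makes the penalty exactly decomposable and
  cheap to differentiate (the subgradient uses $\mathrm{sign}$, with
  $\mathrm{sign}(0)=0$).
* $\lambda$ defaults to **0**: the published training recipe lists a pure
  MSE objective. The penalty is implemented and switched on via
  `lambdaReg` / `--lambda-reg` for fidelity to the printed objective.

## The network

A fully convolutional U-Net-style encoder–decoder:

* **Encoder** (default `depth = 3` levels): each level applies two
  $3\times3$ convolution → spatial batch normalization → ReLU blocks, then
  $2\times2$ max pooling; channels start at `baseChannels = 32` and double
  per level.
* **Bottleneck**: one more two-conv block at $2^{\mathrm{depth}}\times$
  base channels.
* **Decoder**: nearest-neighbour $2\times$ upsampling, a single conv block,
  concatenation of the matching encoder features (skip connections), then a
  two-conv block.
* **Head**: a $1\times1$ convolution with a sigmoid, so every output pixel
  lies strictly in $(0, 1)$ — this is why the whole pipeline operates on
  frames normalized to $[0, 1]$.

Weights are He-normal, fully determined by the seed. Optimization is Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$) at learning rate $10^{-3}$, batch size
1 (the training set *is* the single pair), 100 epochs by default. Batch
normalization uses per-channel statistics over the spatial axes during
training and **running statistics at inference** — with batch size 1,
training-mode statistics would make the output depend on the input batch,
breaking inference determinism.

Inputs whose sides are not multiples of $2^{\mathrm{depth}}$ are
mirror-padded and cropped back after the forward pass; training on such
inputs evaluates the loss on the padded domain, whose reflected margin is
at most $2^{\mathrm{depth}} - 1$ pixels wide.

### Which frame is denoised at inference?

The trained network is applied, by default, to the **median-filtered**
normalized frame — the same domain it was trained on. Applying it to the
raw unfiltered frame is supported (`inferenceInput = "raw"`) but is a
train/test domain shift: the network has only ever seen median-filtered
statistics, and in our benchmarks raw-frame inference loses several dB of
PSNR and degrades with longer training, while filtered-frame inference
tracks the training objective. The choice is recorded in every run's
`config.json`.

## Quality metrics

* **RMSE** $=\sqrt{\operatorname{mean}(x-y)^2}$, in normalized intensity
  units.
* **PSNR** $=10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ dB, peak 1 on
  normalized frames (the source-dtype maximum can be passed instead).
* **SSIM** with the canonical parameters: $11\times11$ Gaussian window,
  $\sigma=1.5$, $C_1=(0.01\,\mathrm{peak})^2$, $C_2=(0.03\,\mathrm{peak})^2$,
  averaged over windows fully inside the frame.
* **FRC**: per-ring correlation of the two discrete Fourier spectra over
  single-bin annuli up to Nyquist (0.5 cycles/pixel); the **resolution
  cutoff** is the first downward crossing of the fixed $1/7$ threshold,
  linearly interpolated (the threshold is a convention, exposed as
  `frcThreshold`; the curve of an image with itself is identically 1, and
  a curve that never crosses reports the Nyquist frequency).

**Metric regimes.** On real microscope data there is no ground truth, so
metrics can only compare the denoised frame against the raw input
("reference-free") — such values measure how far the output moved from its
input, *not* fidelity to the truth, and every report is labelled with its
regime. On synthetic benchmarks the clean phantom is available and metrics
are computed against it ("reference").

## Post-processing

In the order: optional ROI masking (Otsu threshold on a 256-bin histogram,
largest connected component kept; parameter-free, hence the default —
`--roi-threshold` substitutes a fixed value), a $3\times3$ median filter,
then a percentile contrast stretch (defaults 1–99) computed inside the ROI
and clipped to $[0,1]$. "Enhancing contrast" is realized as a percentile
stretch because it is monotone, robust to outliers, and parameterized by
two interpretable numbers. A Canny edge map (Gaussian $\sigma=1$, Sobel
gradients, non-maximum suppression with a strict tie-break on one side so
plateau ties yield single-pixel ridges, double-threshold hysteresis via
connected components) is an optional output layer and is never fed back
into the metrics. Metrics are computed on the pre-post-processing output.

## The synthetic phantom

`makePhantom()` renders a centered bright disk — a 2-D section through a
spheroid — with seeded, Gaussian-smoothed internal texture (correlation
length `textureScale`, standard deviation `textureAmplitude`, centered to
zero mean over the disk so the core level is exact), a 3-pixel
cosine-tapered rim, and uniform background. `corruptImage()` applies, in
order, Poisson shot noise, additive Gaussian read noise, and impulse noise,
then clips to $[0,1]$. Three presets ("rayleigh", "raman", "fluorescence")
bundle plausible levels for the three imaging channels without claiming
physical accuracy.

What the phantom does **not** emulate: optical blur (no point-spread
function anywhere in this method — the restoration is purely statistical),
depth-dependent light-sheet artifacts (stripes, attenuation), correlated
sCMOS read-out noise, and real biological texture. Tests passing on the
phantom therefore demonstrate the pipeline's statistical correctness and
its behaviour under the modelled noise, not performance on any particular
instrument.

### Benchmark conditions

The repository's end-to-end benchmark (test suite and
`scripts/acceptance.R`) uses a $128\times128$ phantom — large enough for
three pooling levels and stable FRC rings, small enough to train in tens of
seconds on one CPU — with core 0.7, background 0.1, texture amplitude 0.05,
read noise $\sigma = 0.1$, pair noise $\sigma_p = 0.05$, and 50 training
epochs. Under these conditions the zero-shot pipeline gains roughly 4–10 dB
PSNR over the noisy frame (seed-dependent), and the salt-and-pepper variant
(5% impulses) gains even more because the median pre-filter removes
impulses outright.

The FRC cutoff against the clean frame behaves more delicately: at 50
epochs the network still slightly over-smooths, so the denoised cutoff sits
near the noisy frame's cutoff and the comparison can go either way with the
noise seed; at the default 100 epochs the denoised cutoff exceeds the noisy
one consistently in our runs. We report this as-is rather than presenting
the FRC gain as unconditional.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `noiseSigma` ($\sigma_p$) | 0.05 | normalized intensity | pair-generation noise; not stated in the source recipe, chosen as a moderate corruption for $[0,1]$ frames |
| `medianKernel` | 3 | px | stated by the recipe |
| `epochs` / `learningRate` / `batchSize` | 100 / 0.001 / 1 | — | stated by the recipe (Adam) |
| `lambdaReg` | 0 | — | smoothness weight; recipe lists pure MSE |
| `depth` / `baseChannels` | 3 / 32 | — | architecture; unstated, chosen as the smallest stack that restores fine structure at $128^2$–$1024^2$ |
| `frcThreshold` | 1/7 | — | fixed-threshold FRC criterion |
| `pLow` / `pHigh` | 1 / 99 | percentile | contrast stretch |

## Numerical and degenerate-input conventions

* Normalization is per-frame min–max; the raw range and dtype are kept in
  metadata so outputs can be mapped back. Frames with zero dynamic range
  normalize to all zeros (keeps the pipeline total). Float frames already
  in $[0,1]$ pass through unchanged — min–max stretching them would
  silently rescale comparisons between files written by this package.
* NaN/Inf pixels are an error everywhere, never silently clamped.
* Constant frames: FRC is undefined (error), Otsu has no separable classes
  (error), Canny returns an empty edge map, the median filter is a fixed
  point.
* A degenerate contrast-stretch window returns the median-filtered frame
  with a warning instead of dividing by zero.
* All randomness — noise fields, phantom texture, weight initialization —
  is seeded explicitly; two runs with one configuration produce
  bit-identical artifacts on one machine.

## Known limitations

* Zero-shot means **per-image**: weights are not intended to transfer
  between frames, and batch processing trains each frame independently.
* There is no physical deconvolution: no PSF model, so no true optical
  super-resolution — "resolution" statements are FRC-based, relative, and
  threshold-dependent.
* The reference-free metric regime cannot detect hallucinated structure;
  only the synthetic-reference regime measures fidelity to truth.
* SSIM variants (multi-scale), half-bit FRC criteria and
  decorrelation-analysis resolution estimates are out of scope.
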