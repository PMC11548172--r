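# ZSDenoise

Zero-shot, self-supervised denoising and resolution assessment for
single-channel light-sheet microscopy frames, in R.

Low-light microscopy channels — elastic (Rayleigh) scattering, weak Raman
signals, photon-limited fluorescence — produce frames dominated by read
noise, shot noise and salt-and-pepper impulses, and live experiments offer
no clean reference to train a supervised denoiser on. ZSDenoise restores
each frame **using only that frame**: it is aimed at microscopists and
image-analysis developers who need per-frame denoising plus quantitative
quality reporting (PSNR / SSIM / RMSE / Fourier ring correlation) without
any training corpus.

## The method

From the normalized noisy frame $I$, a seeded zero-mean Gaussian field $n$
builds two corrupted renditions

$$A = I + n, \qquad B = I - n,$$

whose average recovers $I$ exactly. Both are median filtered ($3\times3$,
edge-replicated). A U-Net-style convolutional encoder–decoder $f_\theta$
(two conv+batch-norm+ReLU blocks per level, $2\times2$ max pooling, skip
connections, sigmoid head) is then trained per image with Adam
(lr $10^{-3}$, batch 1) on

$$L(\theta) = \operatorname{mean}\big(f_\theta(A) - B\big)^2 +
  \lambda\,\operatorname{mean}\big(|\partial_x f_\theta(A)| +
  |\partial_y f_\theta(A)|\big),$$

the noise2noise pairing: since the noise in $B$ is the sign-flipped noise
of $A$, it cannot be predicted from $A$, and the risk minimizer is the
underlying structure. The trained network is applied to the (median
filtered) frame; quality is reported as PSNR, SSIM, RMSE and an FRC curve
with a 1/7-threshold resolution cutoff. A synthetic spheroid phantom
(bright textured disk, cosine-tapered rim) with Gaussian / Poisson /
impulse noise models provides ground truth for benchmarking. See the
methods vignette (`vignettes/zero-shot-denoising.Rmd`) for assumptions,
parameter choices and limitations.

## Worked example

Denoise a synthetic benchmark frame end to end:

```r
library(ZSDenoise)

clean <- makePhantom(PhantomSpec(size = 128L, seed = 1L))          # ground truth
noisy <- corruptImage(clean, NoiseSpec(gaussianSigma = 0.1, seed = 2L))
pair  <- medianPrefilter(makeNoisePair(noisy, sigma = 0.05, seed = 3L))
fit   <- trainZeroShot(pair, TrainingConfig(epochs = 50L, seed = 4L))
filtered <- MicroscopyImage(medianFilter2D(pixels(noisy)),
                            sourceRange = c(0, 1), normalized = TRUE)
denoised <- denoise(fit$model, filtered)

qualityReport(noisy, denoised, reference = clean)
#> QualityReport (reference)
#>   PSNR: 28.817 dB   SSIM: 0.8594   RMSE: 0.03624
#>   FRC cutoff: 0.2878 cycles/pixel (threshold 0.143)

qualityReport(noisy, noisy, reference = clean)   # the noisy baseline
#> QualityReport (reference)
#>   PSNR: 20.746 dB   SSIM: 0.2062   RMSE: 0.09177
#>   FRC cutoff: 0.299 cycles/pixel (threshold 0.143)
```

Training raised PSNR against the clean frame from 20.7 dB to 28.8 dB
(+8.1 dB) and SSIM from 0.21 to 0.86: most of the read noise is gone while
the disk texture survives. RMSE (normalized intensity units) drops from
0.092 to 0.036. The FRC cutoff — the spatial frequency, in cycles/pixel,
where the spectral correlation with the clean frame falls below 1/7 —
stays essentially unchanged at this short 50-epoch training (0.288 vs
0.299; it exceeds the noisy baseline at the default 100 epochs). The
training loss fell from 0.2223 (epoch 1) to 0.0024 (epoch 50).

On real microscope frames there is no `reference`; `qualityReport(raw,
denoised)` then compares the output against the raw input and labels the
report `reference-free` — those numbers measure change from the input, not
fidelity to truth.

## Command line

A thin CLI over the same functions lives in `inst/cli/zsdenoise.R`:

```sh
Rscript inst/cli/zsdenoise.R simulate --out sim --size 256 --gaussian-sigma 0.1 --seed 7
Rscript inst/cli/zsdenoise.R denoise  --input sim/noisy.tif --reference sim/clean.tif \
        --out run --epochs 100 --seed 7
Rscript inst/cli/zsdenoise.R evaluate --image-a sim/clean.tif --image-b run/denoised.tif \
        --out eval --frc
```

`denoise` writes `denoised.tif`, `postprocessed.tif`, `metrics.json`,
`frc.csv`, `history.csv` and `config.json` (full configuration + seeds for
reproducibility); identical configuration and seed give bit-identical
outputs.

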