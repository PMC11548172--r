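#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib ZSDenoise, .registration = TRUE
NULL

#' Single-channel microscopy frame
#'
#' Container for one 2-D single-channel intensity raster together with the
#' metadata needed to map intensities back to the source scale: the storage
#' type of the file it came from and the raw minimum/maximum observed there.
#' All downstream stages (pair generation, training, metrics) operate on
#' frames normalized to \eqn{[0, 1]}, which matches the sigmoid-activated
#' output layer of the denoising network.
#'
#' @slot pixels numeric matrix of intensities (rows = image rows).
#' @slot sourceDtype one of \code{"uint8"}, \code{"uint16"}, \code{"float"}.
#' @slot sourceRange numeric length-2, the raw (min, max) of the source data.
#' @slot normalized logical; \code{TRUE} once the frame has been min-max
#'   rescaled to \eqn{[0, 1]}.
#'
#' @seealso [readFrame()], [normalizeFrame()], [writeFrame()]
#' @export
setClass("MicroscopyImage",
  representation(
    pixels = "matrix",
    sourceDtype = "character",
    sourceRange = "numeric",
    normalized = "logical"
  ),
  prototype(
    sourceDtype = "float",
    sourceRange = c(0, 1),
    normalized = FALSE
  )
)

setValidity("MicroscopyImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 8L || ncol(p) < 8L)
    return("frames must be at least 8 x 8 pixels")
  if (!object@sourceDtype %in% c("uint8", "uint16", "float"))
    return("sourceDtype must be one of 'uint8', 'uint16', 'float'")
  if (length(object@sourceRange) != 2L)
    return("sourceRange must have length 2")
  if (object@sourceRange[1] > object@sourceRange[2])
    return("sourceRange must satisfy min <= max")
  if (object@normalized && all(is.finite(p))) {
    if (min(p) < 0 || max(p) > 1)
      return("a normalized frame must have all pixels in [0, 1]")
  }
  TRUE
})

#' Inverted-noise training pair
#'
#' The two corrupted renditions of one frame used for self-supervised
#' training: \code{A = frame + n} and \code{B = frame - n}, where \code{n} is
#' a seeded zero-mean Gaussian noise field. Before any filtering,
#' \code{(A + B) / 2} recovers the source frame exactly; this identity is the
#' principal correctness oracle for pair construction. After
#' [medianPrefilter()] both renditions are kernel-median filtered and
#' \code{filtered} is set.
#'
#' @slot a,b [MicroscopyImage-class] renditions (plus / minus noise).
#' @slot noise the injected noise field, same shape as the frame.
#' @slot sigma standard deviation of the noise, in normalized units.
#' @slot seed integer seed the field was drawn with.
#' @slot filtered logical, whether [medianPrefilter()] was applied.
#' @export
setClass("NoisePair",
  representation(
    a = "MicroscopyImage",
    b = "MicroscopyImage",
    noise = "matrix",
    sigma = "numeric",
    seed = "integer",
    filtered = "logical"
  )
)

setValidity("NoisePair", function(object) {
  da <- dim(object@a@pixels); db <- dim(object@b@pixels)
  if (!identical(da, db) || !identical(da, dim(object@noise)))
    return("renditions and noise field must share one shape")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' Convolutional encoder-decoder denoiser
#'
#' Holds the trainable parameters of the per-image denoising network and the
#' architectural hyperparameters needed to rebuild its layer stack: the number
#' of down/up-sampling levels and the channel count of the first level. The
#' network is fully convolutional, so it can be applied to any frame whose
#' sides are at least \code{2^depth}; \code{inputShape} records the shape it
#' was built (and usually trained) for.
#'
#' @slot weights named list of parameter arrays (convolution kernels, biases,
#'   batch-norm scale/shift and running statistics).
#' @slot depth integer, number of pooling levels.
#' @slot baseChannels integer, feature maps at the first level.
#' @slot inputShape integer length-2 (height, width).
#' @slot seed integer initialization seed.
#' @slot trained logical.
#' @export
setClass("DenoiserModel",
  representation(
    weights = "list",
    depth = "integer",
    baseChannels = "integer",
    inputShape = "integer",
    seed = "integer",
    trained = "logical"
  )
)

setValidity("DenoiserModel", function(object) {
  if (object@depth < 1L) return("depth must be >= 1")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (length(object@inputShape) != 2L)
    return("inputShape must be (height, width)")
  if (any(object@inputShape < 2^object@depth))
    return("inputShape must be at least 2^depth in both axes")
  TRUE
})

#' Optimizer settings for zero-shot training
#'
#' Defaults follow the published training recipe: Adam, 100 epochs, batch
#' size 1 (the training set is the single image pair), learning rate 0.001,
#' and a pure mean-squared-error objective (\code{lambdaReg = 0}). The
#' gradient-smoothness weight \code{lambdaReg} switches on the anisotropic
#' total-variation penalty when positive.
#'
#' @slot learningRate positive step size for Adam.
#' @slot epochs integer \eqn{\ge 0}; 0 returns the initialized model untouched.
#' @slot batchSize integer \eqn{\ge 1}; with a single training pair only 1 is
#'   meaningful.
#' @slot lambdaReg smoothness weight \eqn{\lambda \ge 0}.
#' @slot seed integer controlling weight initialization.
#' @slot dataTarget \code{"pair"} trains \code{f(A) -> B};
#'   \code{"raw"} anchors the data term to the raw frame instead.
#' @export
setClass("TrainingConfig",
  representation(
    learningRate = "numeric",
    epochs = "integer",
    batchSize = "integer",
    lambdaReg = "numeric",
    seed = "integer",
    dataTarget = "character"
  ),
  prototype(
    learningRate = 0.001,
    epochs = 100L,
    batchSize = 1L,
    lambdaReg = 0,
    seed = 1L,
    dataTarget = "pair"
  )
)

setValidity("TrainingConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@lambdaReg < 0) return("lambdaReg must be >= 0")
  if (!object@dataTarget %in% c("pair", "raw"))
    return("dataTarget must be 'pair' or 'raw'")
  TRUE
})

#' Per-epoch training trace
#'
#' One entry per epoch of the total objective and its two components; the
#' identity \code{loss = mse + lambdaReg * reg} holds elementwise.
#'
#' @slot loss,mse,reg numeric traces of equal length.
#' @slot lambdaReg the smoothness weight the run used.
#' @export
setClass("TrainingHistory",
  representation(
    loss = "numeric",
    mse = "numeric",
    reg = "numeric",
    lambdaReg = "numeric"
  )
)

setValidity("TrainingHistory", function(object) {
  n <- length(object@loss)
  if (length(object@mse) != n || length(object@reg) != n)
    return("loss, mse and reg traces must have equal length")
  if (n > 0) {
    recon <- object@mse + object@lambdaReg * object@reg
    if (max(abs(object@loss - recon)) > 1e-8 * max(1, max(abs(object@loss))))
      return("loss trace must equal mse + lambdaReg * reg")
  }
  TRUE
})

#' Fourier ring correlation curve
#'
#' Per-ring correlation of two images' discrete Fourier spectra over
#' single-bin annuli, with the first crossing of a fixed threshold
#' (conventionally 1/7) taken as the effective resolution cutoff.
#'
#' @slot ringRadii spatial frequencies in cycles/pixel, strictly increasing,
#'   bounded by Nyquist (0.5).
#' @slot correlation real per-ring correlations.
#' @slot threshold scalar cutoff criterion.
#' @slot cutoffFrequency first threshold crossing (cycles/pixel), linearly
#'   interpolated; equals the Nyquist frequency when the curve never drops
#'   below the threshold.
#' @export
setClass("FRCCurve",
  representation(
    ringRadii = "numeric",
    correlation = "numeric",
    threshold = "numeric",
    cutoffFrequency = "numeric"
  )
)

setValidity("FRCCurve", function(object) {
  if (length(object@ringRadii) != length(object@correlation))
    return("ringRadii and correlation must have equal length")
  if (any(diff(object@ringRadii) <= 0))
    return("ringRadii must be strictly increasing")
  if (max(object@ringRadii) > 0.5 + 1e-12)
    return("ring radii must not exceed the Nyquist frequency 0.5")
  TRUE
})

#' Scalar image-quality report
#'
#' PSNR/SSIM/RMSE bundle, optionally with an [FRCCurve-class], plus the
#' comparison regime: \code{"reference"} when a clean ground-truth frame was
#' available (synthetic benchmarks) or \code{"reference-free"} when the
#' denoised frame was compared against the raw input, the only option on
#' real microscope data without ground truth. Reference-free values measure
#' fidelity to the noisy input, not fidelity to the truth.
#'
#' @slot psnrDb peak signal-to-noise ratio, decibels (\code{Inf} for
#'   identical images).
#' @slot ssim structural similarity index in \eqn{[-1, 1]}.
#' @slot rmse root-mean-square error, normalized intensity units.
#' @slot peak reference peak used by PSNR.
#' @slot regime \code{"reference"} or \code{"reference-free"}.
#' @slot frc an [FRCCurve-class] or \code{NULL}.
#' @export
setClass("QualityReport",
  representation(
    psnrDb = "numeric",
    ssim = "numeric",
    rmse = "numeric",
    peak = "numeric",
    regime = "character",
    frc = "ANY"
  )
)

setValidity("QualityReport", function(object) {
  if (object@rmse < 0) return("rmse must be >= 0")
  if (!object@regime %in% c("reference", "reference-free"))
    return("regime must be 'reference' or 'reference-free'")
  if (!is.null(object@frc) && !is(object@frc, "FRCCurve"))
    return("frc must be NULL or an FRCCurve")
  TRUE
})

#' Spheroid phantom specification
#'
#' Geometry and texture of the synthetic ground-truth frame: a centered
#' bright disk (a 2-D section through a multicellular spheroid) with
#' smoothed random internal texture and a 3-pixel cosine-tapered rim on a
#' dark background.
#'
#' @slot size side length in pixels (square frame).
#' @slot radiusFraction disk radius as a fraction of the half-size, in (0,1).
#' @slot coreIntensity mean in-disk level, in (0, 1].
#' @slot backgroundIntensity background level, in \code{[0, coreIntensity)}.
#' @slot textureScale correlation length of the internal texture, pixels.
#' @slot textureAmplitude standard deviation of the texture, intensity units.
#' @slot seed integer texture seed.
#' @export
setClass("PhantomSpec",
  representation(
    size = "integer",
    radiusFraction = "numeric",
    coreIntensity = "numeric",
    backgroundIntensity = "numeric",
    textureScale = "numeric",
    textureAmplitude = "numeric",
    seed = "integer"
  ),
  prototype(
    size = 256L,
    radiusFraction = 0.6,
    coreIntensity = 0.7,
    backgroundIntensity = 0.1,
    textureScale = 8,
    textureAmplitude = 0.05,
    seed = 1L
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@size < 16L) return("size must be >= 16 pixels")
  if (object@radiusFraction <= 0 || object@radiusFraction >= 1)
    return("radiusFraction must lie in (0, 1)")
  if (object@coreIntensity <= 0 || object@coreIntensity > 1)
    return("coreIntensity must lie in (0, 1]")
  if (object@backgroundIntensity < 0 ||
      object@backgroundIntensity >= object@coreIntensity)
    return("backgroundIntensity must lie in [0, coreIntensity)")
  if (object@textureScale <= 0) return("textureScale must be > 0")
  if (object@textureAmplitude < 0) return("textureAmplitude must be >= 0")
  TRUE
})

#' Camera noise specification
#'
#' Three independent corruption components applied in order to a clean frame:
#' signal-dependent Poisson shot noise (\code{poissonScale} photons at
#' intensity 1; 0 disables it), additive Gaussian read noise, and impulse
#' ("salt-and-pepper") noise replacing a fraction of pixels with 0 or 1
#' equiprobably. The result is clipped to \eqn{[0, 1]}.
#'
#' @slot gaussianSigma read-noise standard deviation, normalized units.
#' @slot poissonScale photons corresponding to intensity 1; 0 disables.
#' @slot impulseFraction fraction of pixels hit by impulses, \eqn{\le 0.5}.
#' @slot seed integer noise seed.
#' @export
setClass("NoiseSpec",
  representation(
    gaussianSigma = "numeric",
    poissonScale = "numeric",
    impulseFraction = "numeric",
    seed = "integer"
  ),
  prototype(
    gaussianSigma = 0.05,
    poissonScale = 0,
    impulseFraction = 0,
    seed = 1L
  )
)

setValidity("NoiseSpec", function(object) {
  if (object@gaussianSigma < 0) return("gaussianSigma must be >= 0")
  if (object@poissonScale < 0) return("poissonScale must be >= 0")
  if (object@impulseFraction < 0 || object@impulseFraction > 0.5)
    return("impulseFraction must lie in [0, 0.5]")
  TRUE
})
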