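#' Root-mean-square error
#'
#' \eqn{\sqrt{\mathrm{mean}((x - y)^2)}} between two intensity rasters of
#' one shape, in the units of the inputs (normalized intensity throughout
#' this package).
#'
#' @param x,y numeric matrices or \linkS4class{MicroscopyImage}s.
#' @return a non-negative scalar.
#' @export
rmse <- function(x, y) {
  px <- .as_pixels(x); py <- .as_pixels(y)
  .check_same_shape(px, py)
  sqrt(mean((px - py)^2))
}

.check_same_shape <- function(px, py) {
  if (!identical(dim(px), dim(py)))
    .stopf("image shapes differ: %d x %d vs %d x %d",
           nrow(px), ncol(px), nrow(py), ncol(py))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(\mathrm{peak}^2 / \mathrm{MSE})} in decibels. On
#' normalized frames \code{peak = 1}; pass the source dtype maximum to
#' evaluate on the raw scale. Identical images give \code{Inf}.
#'
#' @inheritParams rmse
#' @param peak reference peak intensity, > 0.
#' @return decibels (possibly \code{Inf}).
#' @examples
#' x <- matrix(0.5, 16, 16)
#' psnr(x, x + 0.1)  # 10*log10(1/0.01) = 20 dB
#' @export
psnr <- function(x, y, peak = 1.0) {
  if (length(peak) != 1L || !is.finite(peak) || peak <= 0)
    stop("peak must be a single positive value", call. = FALSE)
  px <- .as_pixels(x); py <- .as_pixels(y)
  .check_same_shape(px, py)
  mse <- mean((px - py)^2)
  if (mse == 0) Inf else 10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with the canonical parameters: an 11 x 11 Gaussian
#' window (\eqn{\sigma = 1.5}) and stabilizers
#' \eqn{C_1 = (0.01\,\mathrm{peak})^2}, \eqn{C_2 = (0.03\,\mathrm{peak})^2}.
#' Local means, variances and covariance are window-weighted moments; the
#' SSIM map is averaged over all window positions that fit fully inside the
#' image, so frames must be at least 11 pixels on each side. Symmetric in
#' its arguments; equals 1 exactly when \code{x == y}.
#'
#' @inheritParams psnr
#' @return a scalar in \eqn{[-1, 1]}.
#' @export
ssim <- function(x, y, peak = 1.0) {
  px <- .as_pixels(x); py <- .as_pixels(y)
  .check_same_shape(px, py)
  win <- 11L
  if (nrow(px) < win || ncol(px) < win)
    .stopf(paste0("image %d x %d is smaller than the %d x %d SSIM window; ",
                  "use a larger image or a smaller window"),
           nrow(px), ncol(px), win, win)
  g <- stats::dnorm(seq(-5L, 5L), sd = 1.5)
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  f <- function(m) matrix(as.numeric(
    EBImage::filter2(m, w, boundary = "circular")), nrow(m), ncol(m))
  mu1 <- f(px); mu2 <- f(py)
  s11 <- f(px * px) - mu1^2
  s22 <- f(py * py) - mu2^2
  s12 <- f(px * py) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  # keep only windows fully inside the frame (circular wrap reaches 5 px in)
  r <- 5L
  mean(map[(r + 1L):(nrow(map) - r), (r + 1L):(ncol(map) - r)])
}

#' Fourier ring correlation
#'
#' Correlates the discrete Fourier spectra of two images over concentric
#' single-bin annuli:
#' \deqn{\mathrm{FRC}(r) = \frac{\mathrm{Re}\sum_{r} F_1 \bar F_2}
#'   {\sqrt{\sum_r |F_1|^2 \sum_r |F_2|^2}}}
#' and estimates the effective resolution as the first frequency where the
#' curve drops below \code{threshold} (the fixed-threshold criterion,
#' default 1/7), linearly interpolated between rings. Rings run from DC to
#' the Nyquist frequency (0.5 cycles/pixel); rings where both spectra are
#' empty are assigned correlation 0. Non-square inputs are center-cropped
#' to the largest common square; constant images have no off-DC spectrum
#' and are an error.
#'
#' @inheritParams rmse
#' @param threshold cutoff criterion (default \code{1/7}).
#' @param ringWidth annulus width in frequency bins (default 1).
#' @return an \linkS4class{FRCCurve}.
#' @export
frc <- function(x, y, threshold = 1 / 7, ringWidth = 1) {
  px <- .as_pixels(x); py <- .as_pixels(y)
  .check_same_shape(px, py)
  if (ringWidth <= 0) stop("ringWidth must be > 0", call. = FALSE)
  n <- min(dim(px))
  if (nrow(px) != ncol(px)) {
    r0 <- floor((nrow(px) - n) / 2); c0 <- floor((ncol(px) - n) / 2)
    px <- px[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)]
    py <- py[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)]
  }
  if (diff(range(px)) == 0 || diff(range(py)) == 0)
    stop("constant image: off-DC spectrum is zero, FRC is undefined",
         call. = FALSE)
  F1 <- stats::fft(px); F2 <- stats::fft(py)
  # signed frequency index of each DFT bin
  fr <- function(k) ifelse(k <= n / 2, k, k - n)
  fy <- fr(0:(n - 1)); fx <- fr(0:(n - 1))
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  ring <- as.integer(round(rad / ringWidth))
  kmax <- as.integer(floor((n / 2) / ringWidth))
  keep <- ring <= kmax
  rid <- factor(ring[keep], levels = 0:kmax)
  num <- rowsum(as.numeric(Re(F1[keep] * Conj(F2[keep]))), rid)
  d1 <- rowsum(as.numeric(abs(F1[keep])^2), rid)
  d2 <- rowsum(as.numeric(abs(F2[keep])^2), rid)
  den <- sqrt(d1 * d2)
  corr <- as.numeric(ifelse(den > 0, num / den, 0))
  radii <- (0:kmax) * ringWidth / n
  new("FRCCurve", ringRadii = radii, correlation = corr,
      threshold = threshold,
      cutoffFrequency = .frc_cutoff(radii, corr, threshold))
}

# first downward crossing of the threshold, linearly interpolated;
# Nyquist when the curve never drops below it
.frc_cutoff <- function(radii, corr, threshold) {
  below <- which(corr < threshold)
  below <- below[below > 1L]
  if (length(below) == 0L) return(max(radii))
  k <- below[1L]
  c0 <- corr[k - 1L]; c1 <- corr[k]
  r0 <- radii[k - 1L]; r1 <- radii[k]
  if (c0 <= threshold) return(r0)
  r0 + (c0 - threshold) / (c0 - c1) * (r1 - r0)
}

#' @rdname FRCCurve-class
#' @export
setMethod("frcCutoff", "FRCCurve", function(object) object@cutoffFrequency)

#' @rdname FRCCurve-class
#' @param x an \linkS4class{FRCCurve}
#' @param ... unused
#' @export
setMethod("as.data.frame", "FRCCurve", function(x, ...) {
  data.frame(ring_radius = x@ringRadii, correlation = x@correlation)
})

setMethod("show", "FRCCurve", function(object) {
  cat(sprintf("FRCCurve: %d rings, threshold %.4g, cutoff %.4g cycles/pixel\n",
              length(object@ringRadii), object@threshold,
              object@cutoffFrequency))
})

#' Bundle the quality metrics for a denoising run
#'
#' With a clean \code{reference} (synthetic benchmarks) both the raw and
#' denoised frames are judged against it and the report is labelled
#' \code{"reference"}. Without one — the only regime available on real
#' microscope frames — the denoised frame is compared against the raw
#' input and the report is labelled \code{"reference-free"}; such values
#' quantify how far the output moved from its input, not closeness to any
#' ground truth, and must be read accordingly.
#'
#' @param raw the noisy input frame.
#' @param denoised the network output.
#' @param reference optional clean ground truth.
#' @param peak PSNR peak (default 1 for normalized frames).
#' @param withFrc compute the FRC curve as well?
#' @param frcThreshold cutoff criterion for [frc()].
#' @return a \linkS4class{QualityReport}.
#' @export
qualityReport <- function(raw, denoised, reference = NULL, peak = 1.0,
                          withFrc = TRUE, frcThreshold = 1 / 7) {
  cmp <- if (is.null(reference)) raw else reference
  regime <- if (is.null(reference)) "reference-free" else "reference"
  curve <- if (withFrc) frc(denoised, cmp, threshold = frcThreshold) else NULL
  new("QualityReport",
      psnrDb = psnr(denoised, cmp, peak = peak),
      ssim = ssim(denoised, cmp, peak = peak),
      rmse = rmse(denoised, cmp),
      peak = peak, regime = regime, frc = curve)
}

#' @rdname QualityReport-class
#' @export
setMethod("reportMetrics", "QualityReport", function(object) {
  out <- list(psnr_db = object@psnrDb, ssim = object@ssim,
              rmse = object@rmse, peak = object@peak,
              regime = object@regime)
  if (!is.null(object@frc))
    out$frc_cutoff_cycles_per_pixel <- object@frc@cutoffFrequency
  out
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport (%s)\n", object@regime))
  cat(sprintf("  PSNR: %.3f dB   SSIM: %.4f   RMSE: %.5f\n",
              object@psnrDb, object@ssim, object@rmse))
  if (!is.null(object@frc))
    cat(sprintf("  FRC cutoff: %.4g cycles/pixel (threshold %.3g)\n",
                object@frc@cutoffFrequency, object@frc@threshold))
})
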