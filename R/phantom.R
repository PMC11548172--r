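#' @rdname PhantomSpec-class
#' @param size,radiusFraction,coreIntensity,backgroundIntensity,textureScale,textureAmplitude,seed
#'   see the class slots.
#' @export
PhantomSpec <- function(size = 256L, radiusFraction = 0.6,
                        coreIntensity = 0.7, backgroundIntensity = 0.1,
                        textureScale = 8, textureAmplitude = 0.05,
                        seed = 1L) {
  new("PhantomSpec", size = as.integer(size),
      radiusFraction = radiusFraction, coreIntensity = coreIntensity,
      backgroundIntensity = backgroundIntensity,
      textureScale = textureScale, textureAmplitude = textureAmplitude,
      seed = as.integer(seed))
}

#' @rdname NoiseSpec-class
#' @param gaussianSigma,poissonScale,impulseFraction,seed see the class
#'   slots.
#' @export
NoiseSpec <- function(gaussianSigma = 0.05, poissonScale = 0,
                      impulseFraction = 0, seed = 1L) {
  new("NoiseSpec", gaussianSigma = gaussianSigma,
      poissonScale = poissonScale, impulseFraction = impulseFraction,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %d x %d: disk r = %.2f x half-size, ",
                     "core %.2f, bg %.2f, texture (scale %g, amp %g), ",
                     "seed %d\n"),
              object@size, object@size, object@radiusFraction,
              object@coreIntensity, object@backgroundIntensity,
              object@textureScale, object@textureAmplitude, object@seed))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: gaussian sigma %g, poisson scale %g, impulse %g, seed %d\n",
              object@gaussianSigma, object@poissonScale,
              object@impulseFraction, object@seed))
})

#' Generate a clean spheroid phantom
#'
#' Renders the ground-truth frame the synthetic benchmark is built on: a
#' centered disk of radius \code{radiusFraction * size / 2} at
#' \code{coreIntensity}, a 3-pixel cosine-tapered rim, and background at
#' \code{backgroundIntensity}. Internal texture is seeded Gaussian noise
#' smoothed to the requested correlation length, centered to zero mean over
#' the disk, scaled to \code{textureAmplitude}, and faded out with the rim
#' taper — so every pixel farther than radius + 3 px from the center equals
#' the background level exactly. Deterministic per seed.
#'
#' A flat 2-D disk section stands in for the 3-D spheroid because the
#' denoiser operates on individual 2-D frames; ground truth therefore only
#' needs to be 2-D.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a normalized \linkS4class{MicroscopyImage}.
#' @examples
#' ph <- makePhantom(PhantomSpec(size = 64L, seed = 3))
#' range(pixels(ph))
#' @export
makePhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@size
  ctr <- (n + 1) / 2
  R <- spec@radiusFraction * n / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  taper <- 3
  w <- ifelse(d <= R, 1,
              ifelse(d >= R + taper, 0,
                     0.5 * (1 + cos(pi * (d - R) / taper))))
  img <- spec@backgroundIntensity +
    (spec@coreIntensity - spec@backgroundIntensity) * w
  if (spec@textureAmplitude > 0) {
    tex <- .with_seed(spec@seed, matrix(stats::rnorm(n * n), n, n))
    tex <- .gauss_smooth(tex, spec@textureScale)
    disk <- d <= R
    tex <- tex - mean(tex[disk])
    tex <- tex / stats::sd(tex[disk]) * spec@textureAmplitude
    img <- img + tex * w
  }
  MicroscopyImage(pmin(pmax(img, 0), 1), sourceDtype = "float",
                  sourceRange = c(0, 1), normalized = TRUE)
}

#' Corrupt a clean frame with camera-style noise
#'
#' Applies, in order: Poisson shot noise (pixel intensities scaled to
#' \code{poissonScale} photons, resampled, scaled back; skipped when the
#' scale is 0), additive Gaussian read noise, and impulse
#' ("salt-and-pepper") noise setting a random fraction of pixels to 0 or 1
#' equiprobably. The result is clipped to \eqn{[0, 1]}. All three stages
#' draw from one seeded stream, so a (frame, spec) pair is fully
#' reproducible.
#'
#' @param img a normalized \linkS4class{MicroscopyImage}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @return the corrupted \linkS4class{MicroscopyImage}.
#' @export
corruptImage <- function(img, noise = NoiseSpec()) {
  stopifnot(is(img, "MicroscopyImage"), is(noise, "NoiseSpec"))
  validObject(noise)
  p <- img@pixels
  if (min(p) < 0 || max(p) > 1)
    stop("corruptImage expects pixels in [0, 1]", call. = FALSE)
  h <- nrow(p); w <- ncol(p)
  p <- .with_seed(noise@seed, {
    q <- p
    if (noise@poissonScale > 0)
      q <- matrix(stats::rpois(h * w, q * noise@poissonScale) /
                    noise@poissonScale, h, w)
    if (noise@gaussianSigma > 0)
      q <- q + matrix(stats::rnorm(h * w, 0, noise@gaussianSigma), h, w)
    if (noise@impulseFraction > 0) {
      k <- round(noise@impulseFraction * h * w)
      at <- sample.int(h * w, k)
      q[at] <- stats::rbinom(k, 1L, 0.5)
    }
    q
  })
  new("MicroscopyImage", pixels = pmin(pmax(p, 0), 1),
      sourceDtype = img@sourceDtype, sourceRange = img@sourceRange,
      normalized = TRUE)
}

#' Modality-flavoured noise presets
#'
#' Convenience [NoiseSpec()] bundles loosely emulating the three imaging
#' channels of a Raman light-sheet instrument, without claiming physical
#' accuracy: \code{"rayleigh"} — strong elastic-scattering signal, low read
#' noise, no impulses; \code{"raman"} — weak inelastic signal, high read
#' noise plus salt-and-pepper impulses; \code{"fluorescence"} —
#' photon-limited, shot-noise dominant.
#'
#' @param modality one of \code{"rayleigh"}, \code{"raman"},
#'   \code{"fluorescence"}.
#' @param seed integer noise seed.
#' @return a \linkS4class{NoiseSpec}.
#' @export
noisePreset <- function(modality = c("rayleigh", "raman", "fluorescence"),
                        seed = 1L) {
  switch(match.arg(modality),
    rayleigh = NoiseSpec(gaussianSigma = 0.05, poissonScale = 0,
                         impulseFraction = 0, seed = seed),
    raman = NoiseSpec(gaussianSigma = 0.15, poissonScale = 0,
                      impulseFraction = 0.02, seed = seed),
    fluorescence = NoiseSpec(gaussianSigma = 0.01, poissonScale = 100,
                             impulseFraction = 0, seed = seed))
}

#' Round-trip a phantom/noise specification through JSON
#'
#' @param phantom a \linkS4class{PhantomSpec}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param path JSON file to write.
#' @return \code{writeSpecJSON}: \code{path} invisibly;
#'   \code{readSpecJSON}: list with elements \code{phantom} and
#'   \code{noise}.
#' @export
writeSpecJSON <- function(phantom, noise, path) {
  jsonlite::write_json(list(
    phantom = list(size = phantom@size,
                   radius_fraction = phantom@radiusFraction,
                   core_intensity = phantom@coreIntensity,
                   background_intensity = phantom@backgroundIntensity,
                   texture_scale = phantom@textureScale,
                   texture_amplitude = phantom@textureAmplitude,
                   seed = phantom@seed),
    noise = list(gaussian_sigma = noise@gaussianSigma,
                 poisson_scale = noise@poissonScale,
                 impulse_fraction = noise@impulseFraction,
                 seed = noise@seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSpecJSON
#' @export
readSpecJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    phantom = PhantomSpec(size = j$phantom$size,
                          radiusFraction = j$phantom$radius_fraction,
                          coreIntensity = j$phantom$core_intensity,
                          backgroundIntensity = j$phantom$background_intensity,
                          textureScale = j$phantom$texture_scale,
                          textureAmplitude = j$phantom$texture_amplitude,
                          seed = j$phantom$seed),
    noise = NoiseSpec(gaussianSigma = j$noise$gaussian_sigma,
                      poissonScale = j$noise$poisson_scale,
                      impulseFraction = j$noise$impulse_fraction,
                      seed = j$noise$seed))
}
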