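#' Build the inverted-noise training pair
#'
#' Draws a seeded zero-mean Gaussian noise field \code{n} with standard
#' deviation \code{sigma} and forms the two corrupted renditions
#' \code{A = img + n} and \code{B = img - n}. No clipping is applied, so the
#' identity \code{(A + B) / 2 == img} holds exactly (the renditions may
#' leave \eqn{[0, 1]}); values are clamped only when a tensor is fed to the
#' sigmoid-output network. The same \code{(img, sigma, seed)} triple always
#' yields a bit-identical pair.
#'
#' @param img a normalized \linkS4class{MicroscopyImage}.
#' @param sigma noise standard deviation in normalized-intensity units
#'   (\eqn{\ge 0}). The default 0.05 is a moderate corruption level for
#'   frames spanning \eqn{[0, 1]}.
#' @param seed integer RNG seed, mandatory for reproducibility.
#' @return a \linkS4class{NoisePair} with \code{filtered = FALSE}.
#' @examples
#' img <- normalizeFrame(MicroscopyImage(matrix(runif(256), 16, 16)))
#' pr <- makeNoisePair(img, sigma = 0.1, seed = 7)
#' max(abs((pixels(pairA(pr)) + pixels(pairB(pr))) / 2 - pixels(img)))
#' @export
makeNoisePair <- function(img, sigma = 0.05, seed) {
  stopifnot(is(img, "MicroscopyImage"))
  if (!isNormalized(img))
    stop("makeNoisePair needs a normalized frame; call normalizeFrame first",
         call. = FALSE)
  if (length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single value >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  seed <- as.integer(seed)
  p <- img@pixels
  n <- .with_seed(seed,
    matrix(stats::rnorm(length(p), 0, sigma), nrow(p), ncol(p)))
  mk <- function(px) new("MicroscopyImage", pixels = px,
                         sourceDtype = img@sourceDtype,
                         sourceRange = img@sourceRange, normalized = FALSE)
  new("NoisePair", a = mk(p + n), b = mk(p - n), noise = n,
      sigma = as.numeric(sigma), seed = seed, filtered = FALSE)
}

#' @rdname NoisePair-class
#' @export
setMethod("pairA", "NoisePair", function(object) object@a)

#' @rdname NoisePair-class
#' @export
setMethod("pairB", "NoisePair", function(object) object@b)

#' @rdname NoisePair-class
#' @export
setMethod("noiseField", "NoisePair", function(object) object@noise)

#' @rdname NoisePair-class
#' @export
setMethod("isFiltered", "NoisePair", function(object) object@filtered)

setMethod("show", "NoisePair", function(object) {
  d <- dim(object@noise)
  cat(sprintf("NoisePair %d x %d  sigma = %g  seed = %d  filtered: %s\n",
              d[1], d[2], object@sigma, object@seed, object@filtered))
})

#' 2-D median filter
#'
#' Square-kernel median with edge-replicated borders. Makes no assumption
#' about the value range, so it can be applied to the unclipped noise-pair
#' renditions. The filter commutes with global intensity shifts and never
#' widens the value range of its input.
#'
#' @param mat numeric matrix (or \linkS4class{MicroscopyImage}).
#' @param kernel odd integer \eqn{\ge 3}, the side length of the window.
#' @return a filtered matrix of the same shape.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 100, 6, 7, 8, 9), 3, 3, byrow = TRUE)
#' medianFilter2D(m)[2, 2]  # 6: the impulse is suppressed
#' @export
medianFilter2D <- function(mat, kernel = 3L) {
  if (length(kernel) != 1L || kernel < 3 || kernel %% 2 == 0)
    stop("kernel must be a single odd integer >= 3", call. = FALSE)
  .median_filter(.as_pixels(mat), as.integer(kernel))
}

#' Median pre-filter a training pair
#'
#' Applies a kernel-by-kernel median filter to both renditions of a
#' \linkS4class{NoisePair}. The filtered renditions are the actual training
#' input and target of the zero-shot learner: the median suppresses
#' high-intensity salt-and-pepper outliers while preserving edges, so the
#' network trains on structurally cleaner views of the same frame.
#'
#' @param pair a \linkS4class{NoisePair}.
#' @param kernel odd integer \eqn{\ge 3}; the published pipeline uses 3.
#' @return the pair with both renditions filtered and \code{filtered = TRUE}.
#' @export
medianPrefilter <- function(pair, kernel = 3L) {
  stopifnot(is(pair, "NoisePair"))
  if (length(kernel) != 1L || kernel < 3 || kernel %% 2 == 0)
    stop("kernel must be a single odd integer >= 3", call. = FALSE)
  flt <- function(im) {
    new("MicroscopyImage",
        pixels = .median_filter(im@pixels, as.integer(kernel)),
        sourceDtype = im@sourceDtype, sourceRange = im@sourceRange,
        normalized = im@normalized)
  }
  initialize(pair, a = flt(pair@a), b = flt(pair@b), filtered = TRUE)
}
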