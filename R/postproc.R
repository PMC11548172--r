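#' Region-of-interest mask
#'
#' Thresholds a normalized frame and keeps the largest connected foreground
#' component, isolating the main structure (the spheroid) from background.
#' The default threshold maximizes the inter-class variance of a 256-bin
#' histogram on \eqn{[0, 1]} (Otsu's criterion); a fixed threshold can be
#' supplied instead. Constant frames have no separable classes and are an
#' error.
#'
#' @param img normalized \linkS4class{MicroscopyImage} or matrix in
#'   \eqn{[0, 1]}.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold required when \code{method = "fixed"}.
#' @return a list with \code{mask} (logical matrix), \code{threshold} and
#'   \code{method}.
#' @export
roiMask <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  p <- .as_pixels(img)
  if (diff(range(p)) == 0)
    stop("constant image: no separable intensity classes for an ROI",
         call. = FALSE)
  thr <- if (method == "otsu") otsuThreshold(p)
  else {
    if (is.null(threshold)) stop("method = 'fixed' needs a threshold",
                                 call. = FALSE)
    threshold
  }
  mask <- p >= thr
  if (any(mask) && !all(mask)) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(p), ncol(p)))
    lab <- matrix(as.integer(lab), nrow(p), ncol(p))
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
  }
  list(mask = mask, threshold = thr, method = method)
}

#' Otsu threshold on a 256-bin histogram
#'
#' Exhaustively scans the 255 interior bin boundaries of a 256-bin histogram
#' on \eqn{[0, 1]} and returns the boundary maximizing the between-class
#' variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. Pixels equal to a
#' boundary fall in the upper class, matching the \code{>= threshold}
#' masking convention.
#'
#' @param p numeric matrix or vector with values in \eqn{[0, 1]}.
#' @return the threshold, a value in \eqn{(0, 1)}.
#' @export
otsuThreshold <- function(p) {
  v <- pmin(pmax(as.numeric(p), 0), 1)
  bins <- 256L
  idx <- pmin(floor(v * bins), bins - 1L)    # bin 0..255
  counts <- tabulate(idx + 1L, nbins = bins)
  mids <- (seq_len(bins) - 0.5) / bins
  w <- cumsum(counts)
  s <- cumsum(counts * mids)
  tot <- w[bins]; stot <- s[bins]
  k <- seq_len(bins - 1L)                    # split after bin k
  w0 <- w[k]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s[k] / w0; mu1 <- (stot - s[k]) / w1
  sb <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  which.max(sb) / bins
}

#' Post-process a denoised frame
#'
#' The refinement chain applied after denoising, in order: optional ROI
#' masking (background zeroed), a square median filter, then a percentile
#' contrast stretch to \eqn{[0, 1]} with the percentiles computed inside
#' the ROI (or over the whole frame when no mask is given), clipped to
#' \eqn{[0, 1]}. If the percentile window is degenerate (the two
#' percentiles coincide) the median-filtered image is returned unchanged
#' with a warning.
#'
#' @param img normalized frame.
#' @param mask optional ROI as returned by [roiMask()] (or a logical
#'   matrix).
#' @param pLow,pHigh stretch percentiles, \code{pLow < pHigh}; defaults 1
#'   and 99.
#' @param kernel median kernel size (odd, default 3).
#' @return a \linkS4class{MicroscopyImage} in \eqn{[0, 1]}.
#' @export
applyPostprocessing <- function(img, mask = NULL, pLow = 1, pHigh = 99,
                                kernel = 3L) {
  if (pLow >= pHigh) stop("pLow must be < pHigh", call. = FALSE)
  p <- .as_pixels(img)
  m <- NULL
  if (!is.null(mask)) {
    m <- if (is.list(mask)) mask$mask else mask
    if (!identical(dim(m), dim(p)))
      stop("mask shape does not match the image", call. = FALSE)
    p <- p * m
  }
  p <- medianFilter2D(p, kernel)
  sel <- if (is.null(m)) p else p[m]
  q <- stats::quantile(sel, c(pLow, pHigh) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("degenerate percentile window; returning the median-filtered ",
            "image without contrast stretch", call. = FALSE)
    out <- pmin(pmax(p, 0), 1)
  } else {
    out <- pmin(pmax((p - q[1]) / (q[2] - q[1]), 0), 1)
  }
  if (is(img, "MicroscopyImage"))
    new("MicroscopyImage", pixels = out, sourceDtype = img@sourceDtype,
        sourceRange = img@sourceRange, normalized = TRUE)
  else MicroscopyImage(out, sourceRange = c(0, 1), normalized = TRUE)
}

#' Canny edge map
#'
#' Classical Canny detector: Gaussian smoothing (\eqn{\sigma = 1} by
#' default), Sobel gradients, non-maximum suppression along the quantized
#' gradient direction, and double-threshold hysteresis — weak edge pixels
#' survive only when 8-connected to a strong one. Thresholds are expressed
#' as fractions of the maximum gradient magnitude. The edge map is an
#' optional output layer; it is never fed back into the quality metrics.
#'
#' @param img normalized frame.
#' @param low,high hysteresis thresholds with
#'   \eqn{0 \le low < high \le 1}, relative to the maximum gradient
#'   magnitude.
#' @param sigma Gaussian pre-smoothing scale in pixels.
#' @return a logical matrix marking edge pixels.
#' @export
cannyEdges <- function(img, low = 0.1, high = 0.3, sigma = 1) {
  if (low < 0 || low >= high || high > 1)
    stop("need 0 <= low < high <= 1", call. = FALSE)
  p <- .as_pixels(img)
  sm <- .gauss_smooth(p, sigma)
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3,
                byrow = TRUE)                             # d/dy (along rows)
  gy <- matrix(as.numeric(EBImage::filter2(sm, sob, boundary = "replicate")),
               nrow(p), ncol(p))
  gx <- matrix(as.numeric(EBImage::filter2(sm, t(sob), boundary = "replicate")),
               nrow(p), ncol(p))
  mag <- sqrt(gx^2 + gy^2)
  # FFT filtering leaves ~1e-16 residues on flat fields; that is no gradient
  if (max(mag) < 1e-8) return(matrix(FALSE, nrow(p), ncol(p)))
  mag <- mag / max(mag)
  keep <- .non_max_suppress(mag, gx, gy)
  mag <- mag * keep
  strong <- mag >= high
  weak <- mag >= low
  if (!any(strong)) return(matrix(FALSE, nrow(p), ncol(p)))
  lab <- EBImage::bwlabel(matrix(as.numeric(weak), nrow(p), ncol(p)))
  lab <- matrix(as.integer(lab), nrow(p), ncol(p))
  good <- sort(unique(lab[strong]))
  good <- good[good > 0L]
  weak & (lab %in% good)
}

# suppress pixels that are not local maxima of `mag` along the gradient
# direction, quantized to the 4 canonical orientations
.non_max_suppress <- function(mag, gx, gy) {
  h <- nrow(mag); w <- ncol(mag)
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: horizontal gradient -> compare left/right (columns)
  # sector 1: diagonal (+45); sector 2: vertical -> up/down; sector 3: -45
  shift <- function(m, dy, dx) {
    out <- matrix(0, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, h, w)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    n1 <- shift(mag, d[1], d[2])
    n2 <- shift(mag, -d[1], -d[2])
    # strict on one side so plateau ties yield a single-pixel ridge
    keep <- keep | (sector == s & mag > n1 & mag >= n2)
  }
  keep
}
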