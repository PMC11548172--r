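# internal helpers shared across modules

# extract a pixel matrix from a MicroscopyImage or plain numeric matrix
.as_pixels <- function(x) {
  if (is(x, "MicroscopyImage")) return(x@pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a MicroscopyImage or a numeric matrix, got ",
       class(x)[1], call. = FALSE)
}

# run code with a locally seeded RNG, leaving the global stream untouched
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# mirror-reflected index into 1..n (period 2n - 2), for border padding
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - p - 1L)
}

# pad a matrix at the bottom/right by mirror reflection so both sides are
# multiples of `m`; returns the padded matrix plus the original dims
.pad_to_multiple <- function(mat, m) {
  h <- nrow(mat); w <- ncol(mat)
  hp <- as.integer(ceiling(h / m) * m)
  wp <- as.integer(ceiling(w / m) * m)
  if (hp == h && wp == w) return(list(pixels = mat, h = h, w = w))
  ri <- .reflect_index(seq_len(hp), h)
  ci <- .reflect_index(seq_len(wp), w)
  list(pixels = mat[ri, ci, drop = FALSE], h = h, w = w)
}

# normalized 1-D Gaussian kernel, radius chosen to cover +-3 sigma
.gauss_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing with replicated borders (via EBImage::filter2);
# the kernel radius is capped so it never exceeds the image
.gauss_smooth <- function(mat, sigma) {
  rmax <- (min(dim(mat)) - 1L) %/% 2L
  k <- .gauss_kernel(sigma, radius = min(max(1L, ceiling(3 * sigma)), rmax))
  w <- outer(k, k)
  out <- EBImage::filter2(mat, w, boundary = "replicate")
  matrix(as.numeric(out), nrow(mat), ncol(mat))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# bring a frame onto the normalized [0, 1] scale: float sources already in
# [0, 1] are canonical normalized intensities and pass through unchanged
# (min-max stretching them would silently rescale comparisons); everything
# else is min-max normalized
.as_normalized <- function(img) {
  if (isNormalized(img)) return(img)
  p <- img@pixels
  if (sourceDtype(img) == "float" && all(is.finite(p)) &&
      min(p) >= 0 && max(p) <= 1)
    return(new("MicroscopyImage", pixels = p, sourceDtype = "float",
               sourceRange = img@sourceRange, normalized = TRUE))
  normalizeFrame(img)
}
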