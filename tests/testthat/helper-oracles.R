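# Independent brute-force metric implementations used as oracles. These are
# deliberately literal (double loops, explicit sums) and share no code with
# the package's vectorized/FFT paths.

oracle_rmse <- function(x, y) {
  s <- 0
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      s <- s + (x[i, j] - y[i, j])^2
  sqrt(s / (nrow(x) * ncol(x)))
}

oracle_psnr <- function(x, y, peak = 1) {
  s <- 0
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      s <- s + (x[i, j] - y[i, j])^2
  mse <- s / (nrow(x) * ncol(x))
  if (mse == 0) Inf else 10 * log10(peak^2 / mse)
}

# windowed SSIM over all 11x11 windows fully inside the frame
oracle_ssim <- function(x, y, peak = 1) {
  g <- stats::dnorm(-5:5, sd = 1.5)
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  vals <- c()
  for (i in 6:(nrow(x) - 5)) {
    for (j in 6:(ncol(x) - 5)) {
      px <- x[(i - 5):(i + 5), (j - 5):(j + 5)]
      py <- y[(i - 5):(i + 5), (j - 5):(j + 5)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2
      vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# per-ring spectral correlation accumulated entry by entry
oracle_frc <- function(x, y) {
  n <- nrow(x)
  F1 <- stats::fft(x); F2 <- stats::fft(y)
  kmax <- floor(n / 2)
  num <- den1 <- den2 <- numeric(kmax + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      fy <- if (i - 1 <= n / 2) i - 1 else i - 1 - n
      fx <- if (j - 1 <= n / 2) j - 1 else j - 1 - n
      k <- round(sqrt(fy^2 + fx^2))
      if (k <= kmax) {
        num[k + 1] <- num[k + 1] + Re(F1[i, j] * Conj(F2[i, j]))
        den1[k + 1] <- den1[k + 1] + abs(F1[i, j])^2
        den2[k + 1] <- den2[k + 1] + abs(F2[i, j])^2
      }
    }
  }
  den <- sqrt(den1 * den2)
  list(radii = (0:kmax) / n,
       correlation = ifelse(den > 0, num / den, 0))
}

# between-class variance scan computed from the raw pixel values (exact
# class means, no histogram) over the same 255 candidate boundaries
oracle_otsu <- function(p) {
  v <- as.numeric(p)
  cand <- (1:255) / 256
  best <- -Inf; thr <- NA
  for (t in cand) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; thr <- t }
  }
  thr
}

# fixtures -------------------------------------------------------------------

rand_image <- function(n, m = n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * m), n, m))
}

norm_frame <- function(mat) {
  MicroscopyImage(mat, sourceRange = c(0, 1), normalized = TRUE)
}

# standard benchmark frames used by the training tests
bench_fixture <- function(size = 128L, sigma = 0.1, impulse = 0,
                          phantomSeed = 11L, noiseSeed = 12L) {
  clean <- makePhantom(PhantomSpec(size = size, coreIntensity = 0.7,
                                   backgroundIntensity = 0.1,
                                   textureAmplitude = 0.05,
                                   seed = phantomSeed))
  noisy <- corruptImage(clean, NoiseSpec(gaussianSigma = sigma,
                                         impulseFraction = impulse,
                                         seed = noiseSeed))
  list(clean = clean, noisy = noisy)
}
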