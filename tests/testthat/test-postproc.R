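test_that("Otsu matches an exhaustive inter-class variance scan", {
  # clearly bimodal mixture
  p <- withr::with_seed(40, matrix(
    c(rnorm(600, 0.25, 0.05), rnorm(424, 0.75, 0.05)), 32, 32))
  p <- pmin(pmax(p, 0), 1)
  thr <- otsuThreshold(p)
  expect_lt(abs(thr - oracle_otsu(p)), 1 / 256 + 1e-12)
  # independent route: EBImage's Otsu may land elsewhere on the tie plateau
  # (any threshold separating the two modes scores identically), so compare
  # the between-class variance achieved, not the threshold itself
  eb <- EBImage::otsu(p, range = c(0, 1), levels = 256)
  bcv <- function(t) {
    v <- as.numeric(p); lo <- v[v < t]; hi <- v[v >= t]
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  expect_equal(bcv(thr), bcv(eb), tolerance = 1e-6)
})

test_that("the ROI of a two-level image is exactly the bright region", {
  img <- matrix(0.1, 32, 32)
  disk <- sqrt(outer((1:32 - 16.5)^2, (1:32 - 16.5)^2, "+")) <= 10
  img[disk] <- 0.9
  m <- roiMask(img)
  expect_identical(m$mask, disk)
  expect_true(all((img * m$mask)[!m$mask] == 0))   # masking zeroes background
  expect_error(roiMask(matrix(0.5, 16, 16)), "constant")
})

test_that("the ROI recovers the phantom disk at moderate noise", {
  # SNR = (core - background) / sigma = 5
  fx <- bench_fixture(size = 96L, sigma = 0.12)
  n <- 96; ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  truedisk <- d <= 0.6 * n / 2
  m <- roiMask(medianFilter2D(pixels(fx$noisy)))
  expect_gte(mean(m$mask[truedisk]), 0.95)
  expect_lte(mean(m$mask[!truedisk & d > 0.6 * n / 2 + 3]), 0.05)
})

test_that("post-processing stretches contrast as an affine map onto [0, 1]", {
  # a constant-free field confined to [0.2, 0.4] maps linearly onto [0, 1]
  x <- 0.2 + 0.2 * rand_image(16, seed = 50)
  out <- pixels(applyPostprocessing(norm_frame(x), pLow = 0, pHigh = 100))
  med <- medianFilter2D(x)
  expect_equal(out, (med - min(med)) / (max(med) - min(med)),
               tolerance = 1e-12)
  # an image whose median-filtered version still spans [0, 1] passes through
  # the p = (0, 100) stretch unchanged: blocky extremes survive the filter
  y <- rand_image(16, seed = 51)
  y[1:3, 1:3] <- 0; y[6:8, 6:8] <- 1
  out2 <- pixels(applyPostprocessing(norm_frame(y), pLow = 0, pHigh = 100))
  expect_equal(out2, medianFilter2D(y), tolerance = 1e-12)
  expect_error(applyPostprocessing(norm_frame(y), pLow = 50, pHigh = 10),
               "pLow")
})

test_that("degenerate percentile windows fall back with a warning", {
  x <- matrix(0.4, 16, 16); x[8, 8] <- 0.9
  expect_warning(
    out <- applyPostprocessing(norm_frame(x), pLow = 1, pHigh = 99),
    "degenerate")
  expect_equal(pixels(out), medianFilter2D(x))
})

test_that("post-processing suppresses nearly all impulse pixels", {
  # census an impulse as a pixel spiking far above/below its local median;
  # counting exact 0/1 values would instead count the contrast stretch's
  # endpoint mapping
  census <- function(m) sum(abs(m - medianFilter2D(m)) > 0.25)
  fx <- bench_fixture(size = 128L, sigma = 0, impulse = 0.05)
  before <- census(pixels(fx$noisy))
  expect_gt(before, 300)
  out <- pixels(applyPostprocessing(fx$noisy, pLow = 0, pHigh = 100))
  expect_lt(census(out), 0.01 * before)
})

test_that("post-processing preserves shape and stays within [0, 1]", {
  fx <- bench_fixture(size = 64L, sigma = 0.15)
  m <- roiMask(pixels(fx$noisy))
  out <- applyPostprocessing(fx$noisy, mask = m)
  expect_equal(dim(out), c(64L, 64L))
  expect_gte(min(pixels(out)), 0)
  expect_lte(max(pixels(out)), 1)
})

test_that("Canny finds no edges in flat fields and a clean line at a step", {
  expect_false(any(cannyEdges(matrix(0.5, 32, 32), 0.1, 0.3)))
  step <- cbind(matrix(0.1, 32, 16), matrix(0.9, 32, 16))
  e <- cannyEdges(step, 0.2, 0.6)
  hit <- which(e, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  # all edge pixels hug the discontinuity between columns 16 and 17
  expect_true(all(hit[, 2] %in% 16:17))
  # one pixel per row on the marked side: a 1-px-wide vertical line
  expect_true(all(table(hit[, 1]) == 1))
  expect_error(cannyEdges(step, 0.5, 0.2), "low")
})

test_that("Canny traces the phantom rim", {
  ph <- makePhantom(PhantomSpec(size = 96L, textureAmplitude = 0, seed = 1))
  e <- cannyEdges(ph, 0.2, 0.5)
  n <- 96; ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  R <- 0.6 * n / 2 + 1.5         # taper midpoint of the rim
  hit <- d[e]
  expect_gt(length(hit), 50)
  expect_gte(mean(abs(hit - R) <= 2), 0.9)
})
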