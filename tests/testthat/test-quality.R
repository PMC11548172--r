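test_that("all four metrics agree with brute-force oracles on random pairs", {
  withr::with_seed(123, {
    sizes <- sample(11:32, 20, replace = TRUE)
  })
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    x <- rand_image(n, seed = 2 * k)
    y <- rand_image(n, seed = 2 * k + 1)
    expect_equal(rmse(x, y), oracle_rmse(x, y), tolerance = 1e-6)
    expect_equal(psnr(x, y), oracle_psnr(x, y), tolerance = 1e-6)
    expect_equal(ssim(x, y), oracle_ssim(x, y), tolerance = 1e-6)
    cv <- frc(x, y)
    ov <- oracle_frc(x, y)
    expect_equal(cv@ringRadii, ov$radii, tolerance = 1e-12)
    expect_equal(cv@correlation, ov$correlation, tolerance = 1e-6)
  }
})

test_that("metrics match their closed forms", {
  x <- rand_image(16, seed = 1)
  # PSNR of a known MSE
  expect_equal(psnr(x, x + 0.1), 20)
  expect_equal(psnr(x, x + 0.5), 10 * log10(4), tolerance = 1e-12)
  expect_identical(psnr(x, x), Inf)
  # RMSE of a constant offset is the offset
  expect_equal(rmse(x, x + 0.146), 0.146)
  expect_equal(rmse(x, x), 0)
  # SSIM self-similarity and symmetry
  expect_equal(ssim(x, x), 1)
  y <- rand_image(16, seed = 2)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # FRC self-correlation is 1 in every ring
  cv <- frc(x, x)
  expect_true(all(abs(cv@correlation - 1) < 1e-9))
  expect_error(psnr(x, y, peak = 0), "peak")
  expect_error(ssim(rand_image(8, seed = 1), rand_image(8, seed = 2)),
               "window")
})

test_that("PSNR decreases monotonically with added noise", {
  base <- makePhantom(PhantomSpec(size = 64L, seed = 4))
  vals <- vapply(c(0.05, 0.1, 0.2), function(s) {
    noisy <- corruptImage(base, NoiseSpec(gaussianSigma = s, seed = 5))
    psnr(noisy, base)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("independent white noise decorrelates at high frequency", {
  x <- withr::with_seed(10, matrix(rnorm(64^2), 64, 64))
  y <- withr::with_seed(20, matrix(rnorm(64^2), 64, 64))
  cv <- frc(x, y)
  hi <- cv@ringRadii > 0.25
  expect_lt(mean(abs(cv@correlation[hi])), 0.3)
})

test_that("a band-limited image yields a cutoff at or below its support edge", {
  n <- 64
  x <- withr::with_seed(30, matrix(rnorm(n * n), n, n))
  # zero every spectral component above 0.25 cycles/pixel
  f <- function(k) ifelse(k <= n / 2, k, k - n)
  rad <- sqrt(outer(f(0:(n - 1))^2, f(0:(n - 1))^2, "+")) / n
  F <- stats::fft(x)
  F[rad > 0.25] <- 0
  xb <- Re(stats::fft(F, inverse = TRUE)) / (n * n)
  yb <- xb + withr::with_seed(31, matrix(rnorm(n * n, 0, 0.5 * sd(xb)), n, n))
  cv <- frc(xb, yb)
  expect_lte(frcCutoff(cv), 0.3)
})

test_that("FRC validates its inputs and handles non-square frames", {
  x <- rand_image(16, seed = 1)
  expect_error(frc(matrix(1, 16, 16), x), "constant")
  # non-square input is center-cropped to square
  xr <- rand_image(16, 24, seed = 2)
  cv <- frc(xr, xr)
  expect_equal(max(cv@ringRadii), 0.5)
  expect_true(all(diff(cv@ringRadii) > 0))
})

test_that("the report switches regimes with the reference and serializes fully", {
  fx <- bench_fixture(size = 64L)
  den <- MicroscopyImage(medianFilter2D(pixels(fx$noisy)),
                         sourceRange = c(0, 1), normalized = TRUE)
  rfree <- qualityReport(fx$noisy, den)
  expect_equal(rfree@regime, "reference-free")
  expect_equal(rfree@rmse, rmse(den, fx$noisy))
  rref <- qualityReport(fx$noisy, den, reference = fx$clean)
  expect_equal(rref@regime, "reference")
  expect_equal(rref@psnrDb, psnr(den, fx$clean))
  # identical frames: zero error, perfect similarity
  same <- qualityReport(fx$noisy, fx$noisy, withFrc = FALSE)
  expect_equal(same@rmse, 0)
  expect_equal(same@ssim, 1)
  # JSON schema: all four metric fields present
  j <- jsonlite::fromJSON(jsonlite::toJSON(reportMetrics(rref),
                                           auto_unbox = TRUE))
  expect_true(all(c("psnr_db", "ssim", "rmse",
                    "frc_cutoff_cycles_per_pixel") %in% names(j)))
})
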