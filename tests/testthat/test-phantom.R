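test_that("phantom geometry is exact outside the tapered rim", {
  sp <- PhantomSpec(size = 64L, textureAmplitude = 0, seed = 1)
  ph <- pixels(makePhantom(sp))
  n <- 64; ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  R <- sp@radiusFraction * n / 2
  expect_true(all(ph[d >= R + 3] == sp@backgroundIntensity))
  expect_true(all(ph[d <= R] == sp@coreIntensity))
  # the taper is monotone between core and background
  rim <- ph[d > R & d < R + 3]
  expect_true(all(rim > sp@backgroundIntensity & rim < sp@coreIntensity))
})

test_that("phantom generation is deterministic and holds its mean level", {
  sp <- PhantomSpec(size = 96L, seed = 7)   # texture amplitude 0.05 default
  p1 <- makePhantom(sp); p2 <- makePhantom(sp)
  expect_identical(pixels(p1), pixels(p2))
  n <- 96; ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  inner <- d <= 0.5 * (0.6 * n / 2)
  expect_lt(abs(mean(pixels(p1)[inner]) - sp@coreIntensity), 0.02)
  # texture really is there
  expect_gt(sd(pixels(p1)[inner]), 0.01)
})

test_that("phantom and noise specifications validate their fields", {
  expect_error(PhantomSpec(radiusFraction = 1.2), "radiusFraction")
  expect_error(PhantomSpec(backgroundIntensity = 0.9, coreIntensity = 0.7),
               "backgroundIntensity")
  expect_error(NoiseSpec(gaussianSigma = -1), "gaussianSigma")
  expect_error(NoiseSpec(impulseFraction = 0.7), "impulseFraction")
})

test_that("an all-zero noise specification is the identity", {
  ph <- makePhantom(PhantomSpec(size = 32L, seed = 2))
  out <- corruptImage(ph, NoiseSpec(gaussianSigma = 0, poissonScale = 0,
                                    impulseFraction = 0))
  expect_identical(pixels(out), pixels(ph))
})

test_that("Gaussian corruption hits the closed-form PSNR", {
  # flat mid-gray field: far from the clip boundaries, PSNR ~ 10 log10(1/s^2)
  flat <- MicroscopyImage(matrix(0.5, 128, 128), sourceRange = c(0, 1),
                          normalized = TRUE)
  noisy <- corruptImage(flat, NoiseSpec(gaussianSigma = 0.1, seed = 3))
  expect_gte(psnr(noisy, flat), 19)
  expect_lte(psnr(noisy, flat), 21)
})

test_that("impulse corruption hits the requested pixel fraction", {
  ph <- makePhantom(PhantomSpec(size = 128L, seed = 4))
  noisy <- corruptImage(ph, NoiseSpec(gaussianSigma = 0,
                                      impulseFraction = 0.05, seed = 5))
  frac <- mean(pixels(noisy) %in% c(0, 1))
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.07)
})

test_that("corruption is reproducible and Poisson noise scales with intensity", {
  ph <- makePhantom(PhantomSpec(size = 64L, seed = 6))
  ns <- NoiseSpec(gaussianSigma = 0.02, poissonScale = 50,
                  impulseFraction = 0.01, seed = 9)
  expect_identical(pixels(corruptImage(ph, ns)), pixels(corruptImage(ph, ns)))
  # shot noise: variance grows with signal level
  lo <- MicroscopyImage(matrix(0.1, 64, 64), sourceRange = c(0, 1),
                        normalized = TRUE)
  hi <- MicroscopyImage(matrix(0.8, 64, 64), sourceRange = c(0, 1),
                        normalized = TRUE)
  pspec <- NoiseSpec(poissonScale = 100, seed = 10)
  expect_lt(sd(pixels(corruptImage(lo, pspec))),
            sd(pixels(corruptImage(hi, pspec))))
})

test_that("modality presets map onto their noise regimes", {
  ray <- noisePreset("rayleigh")
  ram <- noisePreset("raman")
  flu <- noisePreset("fluorescence")
  expect_lt(ray@gaussianSigma, ram@gaussianSigma)
  expect_equal(ray@impulseFraction, 0)
  expect_gt(ram@impulseFraction, 0)
  expect_gt(flu@poissonScale, 0)
})

test_that("specifications round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  ps <- PhantomSpec(size = 48L, radiusFraction = 0.55, seed = 12L)
  ns <- NoiseSpec(gaussianSigma = 0.07, impulseFraction = 0.03, seed = 13L)
  writeSpecJSON(ps, ns, f)
  back <- readSpecJSON(f)
  expect_equal(back$phantom, ps)
  expect_equal(back$noise, ns)
  expect_identical(pixels(makePhantom(back$phantom)), pixels(makePhantom(ps)))
})
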