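# closed-form count of trainable weights for the declared layer stack:
# per level two conv3x3+BN blocks, a bottleneck block, a single conv after
# each upsampling, two-conv blocks after skip concatenation, 1x1 output conv
expected_parameter_count <- function(depth, base) {
  conv <- function(cin, cout) 9 * cin * cout + cout
  bn <- function(c) 2 * c
  block2 <- function(cin, c) conv(cin, c) + bn(c) + conv(c, c) + bn(c)
  ch <- function(i) base * 2^i
  total <- 0
  for (i in seq_len(depth) - 1)
    total <- total + block2(if (i == 0) 1 else ch(i - 1), ch(i))
  total <- total + block2(ch(depth - 1), base * 2^depth)
  for (i in rev(seq_len(depth) - 1)) {
    cu <- if (i == depth - 1) base * 2^depth else ch(i + 1)
    total <- total + conv(cu, ch(i)) + bn(ch(i))   # up-conv
    total <- total + block2(2 * ch(i), ch(i))      # after concatenation
  }
  total + base * 1 + 1                             # final 1x1 conv
}

test_that("model construction is deterministic and matches the declared stack", {
  m1 <- buildDenoiser(c(64, 64), depth = 3, baseChannels = 8, seed = 21)
  m2 <- buildDenoiser(c(64, 64), depth = 3, baseChannels = 8, seed = 21)
  expect_identical(modelWeights(m1), modelWeights(m2))
  m3 <- buildDenoiser(c(64, 64), depth = 3, baseChannels = 8, seed = 22)
  expect_false(identical(modelWeights(m1), modelWeights(m3)))

  for (cfg in list(c(3, 32), c(2, 8), c(1, 4))) {
    m <- buildDenoiser(c(64, 64), depth = cfg[1], baseChannels = cfg[2],
                       seed = 1)
    expect_equal(nParameters(m), expected_parameter_count(cfg[1], cfg[2]))
  }
  expect_error(buildDenoiser(c(4, 64), depth = 3, seed = 1), "2\\^depth")
})

test_that("an untrained model already satisfies the shape and range contract", {
  m <- buildDenoiser(c(64, 64), depth = 3, baseChannels = 8, seed = 2)
  img <- norm_frame(rand_image(64, seed = 1))
  out <- denoise(m, img)
  expect_equal(dim(out), c(64L, 64L))
  expect_true(all(pixels(out) > 0 & pixels(out) < 1))
})

test_that("the loss decomposes into data and smoothness terms", {
  p <- matrix(0.5, 8, 8)
  expect_equal(denoiserLoss(p, p, 0)$total, 0)
  expect_equal(denoiserLoss(p, p + 0.1, 0)$total, 0.01)
  # a constant prediction has zero gradient energy
  expect_equal(denoiserLoss(p, rand_image(8, seed = 1), 5)$reg, 0)
  # decomposition identity on random tensors
  for (seed in 1:10) {
    pr <- rand_image(16, seed = seed)
    tg <- rand_image(16, seed = seed + 100)
    lam <- seed / 7
    l <- denoiserLoss(pr, tg, lam)
    expect_equal(l$total, l$mse + lam * l$reg, tolerance = 1e-6)
    expect_gte(l$reg, 0)
  }
  expect_error(denoiserLoss(matrix(0, 8, 8), matrix(0, 8, 9)), "differ")
})

test_that("the smoothness term is the mean absolute forward difference", {
  # horizontal ramp: |dx| = step everywhere except the replicated last column
  p <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)
  step <- 1 / 7
  expect_equal(denoiserLoss(p, p, 1)$reg, step * 7 / 8)
})

test_that("zero-epoch training returns the initialized model and empty traces", {
  img <- norm_frame(rand_image(32, seed = 3))
  pair <- medianPrefilter(makeNoisePair(img, sigma = 0.1, seed = 4))
  fit <- trainZeroShot(pair, TrainingConfig(epochs = 0L, seed = 5L),
                       depth = 2, baseChannels = 4)
  expect_false(fit$model@trained)
  expect_length(fit$history@loss, 0)
  ref <- buildDenoiser(c(32, 32), depth = 2, baseChannels = 4, seed = 5)
  expect_identical(modelWeights(fit$model), modelWeights(ref))
})

test_that("training reduces the loss and is exactly reproducible", {
  fx <- bench_fixture(size = 32L, sigma = 0.1)
  pair <- medianPrefilter(makeNoisePair(fx$noisy, sigma = 0.05, seed = 8))
  cfg <- TrainingConfig(epochs = 50L, learningRate = 0.001, seed = 9L)
  fit1 <- trainZeroShot(pair, cfg, depth = 2, baseChannels = 8)
  fit2 <- trainZeroShot(pair, cfg, depth = 2, baseChannels = 8)
  h <- lossTrace(fit1$history)
  expect_equal(nrow(h), 50L)
  expect_lt(h$loss[50], h$loss[1])
  # head-vs-tail: the last 10 epochs sit below the first 10 on average
  expect_lt(mean(tail(h$loss, 10)), mean(head(h$loss, 10)))
  # bit-identical traces and weights across runs
  expect_identical(fit1$history@loss, fit2$history@loss)
  expect_identical(modelWeights(fit1$model), modelWeights(fit2$model))
  # history identity holds with a nonzero smoothness weight too
  cfgl <- TrainingConfig(epochs = 5L, lambdaReg = 0.1, seed = 9L)
  fitl <- trainZeroShot(pair, cfgl, depth = 2, baseChannels = 8)
  expect_equal(fitl$history@loss,
               fitl$history@mse + 0.1 * fitl$history@reg, tolerance = 1e-10)
})

test_that("inference is deterministic and handles non-multiple-of-2^depth shapes", {
  m <- buildDenoiser(c(50, 70), depth = 3, baseChannels = 8, seed = 6)
  img <- norm_frame(rand_image(50, 70, seed = 7))
  o1 <- denoise(m, img)
  o2 <- denoise(m, img)
  expect_identical(pixels(o1), pixels(o2))
  expect_equal(dim(o1), c(50L, 70L))
  expect_error(denoise(m, matrix(0.5, 4, 4)), "too small")
})

test_that("full-resolution frames pass through the padding contract unchanged in shape", {
  # the camera's native 1024 x 1024 frame size, checked with a thin model
  m <- buildDenoiser(c(1024, 1024), depth = 2, baseChannels = 2, seed = 1)
  out <- denoise(m, rand_image(1024, seed = 2))
  expect_equal(dim(pixels(out)), c(1024L, 1024L))
})

test_that("checkpoints round-trip through save/load", {
  img <- norm_frame(rand_image(32, seed = 3))
  pair <- medianPrefilter(makeNoisePair(img, sigma = 0.1, seed = 4))
  fit <- trainZeroShot(pair, TrainingConfig(epochs = 3L, seed = 5L),
                       depth = 2, baseChannels = 4)
  d <- withr::local_tempdir()
  saveDenoiser(fit$model, d)
  back <- loadDenoiser(d)
  expect_equal(modelWeights(back), modelWeights(fit$model))
  expect_identical(pixels(denoise(back, img)),
                   pixels(denoise(fit$model, img)))
})

test_that("the raw-anchored objective variant trains against the raw frame", {
  img <- norm_frame(rand_image(32, seed = 13))
  pair <- medianPrefilter(makeNoisePair(img, sigma = 0.1, seed = 14))
  cfg <- TrainingConfig(epochs = 5L, seed = 15L, dataTarget = "raw")
  expect_error(trainZeroShot(pair, cfg, depth = 2, baseChannels = 4), "raw")
  fit <- trainZeroShot(pair, cfg, raw = img, depth = 2, baseChannels = 4)
  expect_length(fit$history@loss, 5L)
  # a different target changes the optimization trajectory
  fitp <- trainZeroShot(pair, TrainingConfig(epochs = 5L, seed = 15L),
                        depth = 2, baseChannels = 4)
  expect_false(identical(fit$history@loss, fitp$history@loss))
})
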