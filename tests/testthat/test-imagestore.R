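test_that("TIFF round trip preserves pixels for every supported dtype", {
  img <- rand_image(16, seed = 42)
  for (dt in c("uint8", "uint16", "float")) {
    f <- withr::local_tempfile(fileext = ".tif")
    writeFrame(img, f, dtype = dt)
    back <- readFrame(f)
    expect_equal(sourceDtype(back), dt)
    norm <- pixels(normalizeFrame(back))
    tol <- switch(dt, uint8 = 1 / 255, uint16 = 1 / 65535, float = 2^-22)
    # normalization rescales by the observed range; undo it for comparison
    r <- range(img)
    expect_lt(max(abs(norm * (r[2] - r[1]) + r[1] - img)), tol + 1e-12)
  }
})

test_that("float TIFFs written by the package are bit-stable and readable by libtiff", {
  img <- rand_image(12, 20, seed = 7)
  f <- withr::local_tempfile(fileext = ".tif")
  writeFrame(img, f, dtype = "float")
  # read through tiff (libtiff), not through any package code path
  raw1 <- tiff::readTIFF(f, info = TRUE)
  expect_identical(attr(raw1, "sample.format"), "float")
  expect_lt(max(abs(raw1 - img)), 2^-22)   # float32 quantization only
  # a second write/read cycle is exactly stable
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeFrame(readFrame(f)@pixels, f2, dtype = "float")
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("reading records source dtype and raw range", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(7 / 255, 8, 8), f, bits.per.sample = 8L)
  img <- readFrame(f)
  expect_equal(sourceDtype(img), "uint8")
  expect_equal(sourceRange(img), c(7, 7))
  expect_true(all(pixels(img) == 7))
})

test_that("multi-page stacks come back as lists in page order", {
  f <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(0.1, 8, 8), matrix(0.5, 8, 8), matrix(0.9, 8, 8))
  tiff::writeTIFF(pages, f, bits.per.sample = 16L)
  frames <- readFrame(f, stack = TRUE)
  expect_length(frames, 3L)
  means <- vapply(frames, function(x) mean(pixels(normalizeFrame(x))),
                  numeric(1))
  # constant pages normalize to 0; raw means must preserve order
  raw_means <- vapply(frames, function(x) mean(pixels(x)), numeric(1))
  expect_true(all(diff(raw_means) > 0))
  # without the stack flag only the first page is returned
  one <- readFrame(f)
  expect_equal(pixels(one), pixels(frames[[1]]))
})

test_that("RGB input is rejected instead of silently collapsed", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(8 * 8 * 3), c(8, 8, 3)), f,
                  bits.per.sample = 8L)
  expect_error(readFrame(f), "single-channel")
})

test_that("missing or unreadable files raise I/O errors naming the path", {
  expect_error(readFrame("/nonexistent/frame.tif"), "nonexistent")
  f <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", f)
  expect_error(readFrame(f), basename(f))
})

test_that("normalization is linear min-max with the degenerate-range convention", {
  m <- matrix(rep(c(10, 20, 30), length.out = 64), 8, 8)
  img <- MicroscopyImage(m)
  norm <- normalizeFrame(img)
  expect_equal(sort(unique(as.numeric(pixels(norm)))), c(0, 0.5, 1))
  # constant image maps to zeros, not NaN
  flat <- normalizeFrame(MicroscopyImage(matrix(7, 8, 8)))
  expect_true(all(pixels(flat) == 0))
  # full-range endpoints map to the endpoints
  full <- MicroscopyImage(matrix(c(0, 65535, runif(62) * 65535), 8, 8),
                          sourceDtype = "uint16")
  expect_equal(range(pixels(normalizeFrame(full))), c(0, 1))
})

test_that("normalize is idempotent and rejects non-finite pixels", {
  img <- norm_frame(rand_image(8, seed = 3))
  expect_identical(pixels(normalizeFrame(img)), pixels(img))
  bad <- MicroscopyImage(matrix(c(NaN, runif(63)), 8, 8))
  expect_error(normalizeFrame(bad), "NaN")
})

test_that("frame validity enforces the size and range invariants", {
  expect_error(MicroscopyImage(matrix(0.5, 4, 4)), "8 x 8")
  expect_error(new("MicroscopyImage", pixels = matrix(0.5, 8, 8),
                   sourceDtype = "float", sourceRange = c(2, 1),
                   normalized = FALSE), "min <= max")
  expect_error(writeFrame(matrix(1.5, 8, 8), tempfile()), "\\[0, 1\\]")
})
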