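test_that("a constant frame has zero detail levels and a constant residual", {
  p <- buildPyramid(matrix(7, 33, 47))
  expect_length(p@levels, 3)            # floor(log2(33)) - 2
  for (l in p@levels) expect_lt(max(abs(l)), 1e-12)
  expect_equal(max(abs(p@residual - 7)), 0, tolerance = 1e-12)
})

test_that("collapse(build(x)) reconstructs x on random images", {
  set.seed(30)
  for (rep in 1:10) {
    h <- sample(8:64, 1); w <- sample(8:64, 1)
    x <- matrix(stats::rnorm(h * w), h, w)
    err <- max(abs(collapsePyramid(buildPyramid(x)) - x)) / max(abs(x))
    expect_lt(err, 1e-6)
  }
})

test_that("a 60 x 80 patch yields 3 detail levels plus residual", {
  p <- buildPyramid(matrix(0, 60, 80))
  expect_length(p@levels, 3)
  # depth rule caps at maxLevels and floors at 1
  expect_length(buildPyramid(matrix(0, 60, 80), maxLevels = 2L)@levels, 2)
  expect_length(buildPyramid(matrix(0, 5, 5))@levels, 1)
  # 1-pixel degenerate input: residual only
  p1 <- buildPyramid(matrix(3, 1, 1))
  expect_length(p1@levels, 0)
  expect_equal(collapsePyramid(p1), matrix(3, 1, 1))
})

test_that("the pyramid transform is linear: scaling levels scales the output", {
  set.seed(31)
  x <- matrix(stats::rnorm(24 * 31), 24, 31)
  p <- buildPyramid(x)
  scaled <- new("Pyramid",
                levels = lapply(p@levels, function(l) 3 * l),
                residual = 3 * p@residual)
  expect_equal(collapsePyramid(scaled), 3 * x, tolerance = 1e-9)

  zeros <- new("Pyramid",
               levels = lapply(p@levels, function(l) 0 * l),
               residual = 0 * p@residual)
  expect_true(all(collapsePyramid(zeros) == 0))
})

test_that("inconsistent pyramid level shapes are rejected", {
  p <- buildPyramid(matrix(0, 32, 32))
  broken <- new("Pyramid", levels = p@levels, residual = matrix(0, 3, 3))
  expect_error(collapsePyramid(broken), "inconsistent")
})

test_that("the ideal bandpass passes in-band tones untouched and kills DC", {
  fps <- 30
  t <- (0:599) / fps                        # 20 s: integer periods of 2.2 Hz
  s <- sin(2 * pi * 2.2 * t)
  expect_lt(max(abs(idealBandpass(s, fps) - s)), 1e-9)
  expect_lt(max(abs(idealBandpass(rep(5, 600), fps))), 1e-12)

  mix <- sin(2 * pi * 1.0 * t) + sin(2 * pi * 2.2 * t)
  out <- idealBandpass(mix, fps)
  resid <- out - sin(2 * pi * 2.2 * t)
  expect_lt(sum(resid^2) / sum(sin(2 * pi * 1.0 * t)^2), 1e-6)

  expect_error(idealBandpass(s, fps, fLo = 10, fHi = 20), "Nyquist")
})

test_that("magnification follows the (1 + alpha) in-band gain law", {
  fps <- 30; nT <- 600; a <- 0.5
  t <- (seq_len(nT) - 1) / fps
  inband <- uniformVideo(20, 30, nT, fps, rgb = c(80, 100, 120),
                         greenMod = a * sin(2 * pi * 2.2 * t))
  m <- magnify(inband, evmConfig())
  core <- 60:540                            # discard edge frames
  tr <- frames(m)[10, 15, 2, core]
  gain <- (max(tr) - min(tr)) / 2 / a
  expect_equal(gain, 151, tolerance = 0.02)

  outband <- uniformVideo(20, 30, nT, fps, rgb = c(80, 100, 120),
                          greenMod = a * sin(2 * pi * 1.0 * t))
  tr2 <- frames(magnify(outband, evmConfig()))[10, 15, 2, core]
  expect_equal((max(tr2) - min(tr2)) / 2 / a, 1, tolerance = 0.01)
})

test_that("alpha = 0 and static video are identity limits", {
  fps <- 30; nT <- 240
  t <- (seq_len(nT) - 1) / fps
  vid <- uniformVideo(12, 16, nT, fps, greenMod = sin(2 * pi * 2 * t))
  m0 <- magnify(vid, evmConfig(alpha = 0))
  expect_lt(max(abs(frames(m0) - frames(vid))), 1e-9)

  static <- uniformVideo(12, 16, nT, fps)
  ms <- magnify(static, evmConfig())
  expect_lt(max(abs(frames(ms) - frames(static))), 1e-9)
})

test_that("magnification is linear in the input video", {
  set.seed(32)
  fps <- 30; nT <- 240
  arr <- array(stats::rnorm(10 * 12 * 3 * nT, 100, 5),
               dim = c(10, 12, 3, nT))
  v <- frameSequence(arr, fps)
  cfg <- evmConfig()
  m1 <- frames(magnify(v, cfg))
  m2 <- frames(magnify(frameSequence(2.5 * arr, fps), cfg))
  expect_equal(m2, 2.5 * m1, tolerance = 1e-9)
})

test_that("too-short clips and out-of-band configs are rejected", {
  vid <- uniformVideo(8, 8, 30, 30)
  expect_error(magnify(vid, evmConfig()), "too short")
  long <- uniformVideo(8, 8, 120, 30)
  expect_error(magnify(long, evmConfig(fLo = 10, fHi = 16)), "Nyquist")
})
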