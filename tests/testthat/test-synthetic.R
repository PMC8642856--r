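test_that("beat generation integrates the rate profile", {
  # constant 140 BPM over 120 s: 280 beats, spacing 60/140 s
  b <- generateBeats(140, 120)
  expect_true(length(b) %in% c(279, 280))
  expect_true(all(abs(diff(b) - 60 / 140) < 1e-6))

  # constant 120 BPM: inter-beat interval exactly 0.5 s
  b2 <- generateBeats(120, 30)
  expect_true(all(abs(diff(b2) - 0.5) < 1e-9))

  # accelerating profile: strictly decreasing intervals
  b3 <- generateBeats(cbind(c(0, 60), c(120, 150)), 60)
  expect_true(all(diff(diff(b3)) < 0))

  expect_error(generateBeats(-5, 10), "BPM")
})

test_that("rendering is deterministic given spec + seed", {
  spec <- smallFaceSpec(1, seed = 70L)
  r1 <- renderVideo(spec)
  r2 <- renderVideo(spec)
  expect_identical(frames(r1$video), frames(r2$video))
  other <- renderVideo(smallFaceSpec(1, seed = 71L))
  expect_false(identical(frames(r1$video), frames(other$video)))
})

test_that("face pixels segment as skin, background does not", {
  spec <- smallFaceSpec(1, seed = 72L)
  rv <- renderVideo(spec)
  m <- skinMask(frames(rv$video)[, , , 1])
  truth <- rv$masks[, , 1]
  expect_gt(mean(m[truth]), 0.99)        # face found
  expect_lt(mean(m[!truth]), 0.01)       # background rejected
})

test_that("zero pulse amplitude and zero noise give identical frames", {
  spec <- syntheticSpec(durationS = 0.5, fps = 30, height = 24L,
                        width = 32L, pulseAmp = 0, noiseSd = 0, seed = 73L)
  rv <- renderVideo(spec)
  f <- frames(rv$video)
  for (t in 2:dim(f)[4]) expect_identical(f[, , , t], f[, , , 1])
})

test_that("the face's mean green trace oscillates at the programmed heart rate", {
  fps <- 30; dur <- 30
  spec <- syntheticSpec(durationS = dur, fps = fps, height = 40L,
                        width = 48L, hrBpm = 140, noiseSd = 0.5, seed = 74L)
  rv <- renderVideo(spec)
  tr <- greenTrace(rv$video, rv$masks[, , 1])
  v <- tr@values - mean(tr@values)
  spec_pow <- Mod(stats::fft(v))^2
  freqs <- (seq_along(v) - 1) * fps / length(v)
  half <- freqs > 0 & freqs < fps / 2
  peakF <- freqs[half][which.max(spec_pow[half])]
  expect_equal(peakF, 140 / 60, tolerance = 0.05)
})

test_that("ground-truth windowed HR matches a constant profile within 1 BPM", {
  spec <- smallFaceSpec(70, hrBpm = 150)
  hr <- truthHR(spec)
  expect_length(hrValues(hr), 11)
  expect_true(all(abs(hrValues(hr) - 150) <= 1))
})

test_that("an out-of-frame ellipse is rejected", {
  spec <- syntheticSpec(durationS = 1, height = 20L, width = 20L,
                        faceCenter = c(2, 2), faceAxes = c(10, 10))
  expect_error(renderVideo(spec), "ellipse")
})

test_that("patch corruption overwrites cells inside the face only", {
  spec <- syntheticSpec(durationS = 1, fps = 30, height = 48L, width = 64L,
                        hrBpm = 140, noiseSd = 0,
                        motion = list(type = "patch_corruption",
                                      fraction = 0.3, amplitude = 40,
                                      divisions = 8L),
                        seed = 75L)
  rv <- renderVideo(spec)
  clean <- renderVideo(syntheticSpec(durationS = 1, fps = 30, height = 48L,
                                     width = 64L, hrBpm = 140, noiseSd = 0,
                                     seed = 75L))
  diff <- frames(rv$video)[, , 2, ] != frames(clean$video)[, , 2, ]
  # corrupted pixels exist but lie inside the face
  expect_gt(sum(diff), 0)
  outside <- !array(rv$masks, dim = dim(diff))
  expect_true(all(!diff[outside]))
})

test_that("rotation moves the rendered face over time", {
  spec <- syntheticSpec(durationS = 1, fps = 10, height = 32L, width = 48L,
                        faceAxes = c(10, 18), hrBpm = 140, noiseSd = 0,
                        motion = list(type = "rotation", degPerS = 90),
                        seed = 76L)
  rv <- renderVideo(spec)
  expect_false(identical(rv$masks[, , 1], rv$masks[, , 10]))
  # area is conserved up to discretization
  expect_equal(sum(rv$masks[, , 10]), sum(rv$masks[, , 1]), tolerance = 0.05)
})
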