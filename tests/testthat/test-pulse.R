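test_that("the BVP trace is the skin-pixel mean of the green channel", {
  fps <- 30; nT <- 10
  vid <- uniformVideo(4, 4, nT, fps, rgb = c(10, 0, 30),
                      greenMod = seq_len(nT))
  tr <- greenTrace(vid, matrix(TRUE, 4, 4))
  expect_equal(tr@values, as.numeric(seq_len(nT)))
  expect_equal(fps(tr), fps)

  # half pixels 100, half 200 -> mean 150
  arr <- array(0, dim = c(2, 2, 3, 1))
  arr[, , 2, 1] <- matrix(c(100, 100, 200, 200), 2, 2)
  expect_equal(greenTrace(frameSequence(arr, 30),
                          matrix(TRUE, 2, 2))@values, 150)

  expect_error(greenTrace(vid, matrix(FALSE, 4, 4)), "empty")
  expect_error(greenTrace(vid, matrix(TRUE, 3, 3)), "shape")
})

test_that("masked averaging has larger pulsatile amplitude than whole-patch averaging", {
  fps <- 30; nT <- 60
  t <- (seq_len(nT) - 1) / fps
  arr <- array(0, dim = c(6, 6, 3, nT))
  mask <- matrix(FALSE, 6, 6); mask[1:3, ] <- TRUE   # half skin, half black
  for (tt in seq_len(nT))
    arr[1:3, , 2, tt] <- 100 + 2 * sin(2 * pi * 2 * t[tt])
  vid <- frameSequence(arr, fps)
  amp <- function(v) (max(v) - min(v)) / 2
  masked <- greenTrace(vid, mask)@values
  whole <- greenTrace(vid, matrix(TRUE, 6, 6))@values
  expect_gt(amp(masked), amp(whole))
  expect_equal(amp(masked) / amp(whole), 2, tolerance = 1e-9) # dilution 1/2
})

test_that("peak counting matches the tone frequency", {
  fps <- 30
  t <- (seq_len(1800) - 1) / fps
  tr <- bvpTrace(sin(2 * pi * 2 * t), fps)
  pk <- detectPeaks(tr)
  expect_length(pk, 120)                     # one peak per 2 Hz period, 60 s
  expect_true(all(abs(diff(pk) - 0.5) <= 0.04))

  expect_length(detectPeaks(bvpTrace(rep(3, 300), fps)), 0)
  expect_error(detectPeaks(bvpTrace(c(1, 2), fps)), "short")
})

test_that("peak counts survive noise at SNR 10", {
  set.seed(7)
  fps <- 30
  t <- (seq_len(1800) - 1) / fps
  noisy <- sin(2 * pi * 2.5 * t) + stats::rnorm(1800, sd = sqrt(1 / 20))
  pk <- detectPeaks(bvpTrace(noisy, fps))
  expect_true(abs(length(pk) - 150) <= 1)
  # all accepted peaks are genuine local maxima of the detrended trace
  v <- stats::residuals(stats::lm(noisy ~ seq_along(noisy)))
  idx <- round(pk * fps) + 1
  interior <- idx > 1 & idx < length(v)
  expect_true(all(v[idx[interior]] >= v[idx[interior] - 1] |
                  v[idx[interior]] >= v[idx[interior] + 1]))
})

test_that("sliding-window HR obeys the counting and length formulas", {
  # peaks every 0.5 s over 70 s -> every window reports 120 BPM
  pk <- seq(0, 69.5, by = 0.5)
  hr <- windowedHR(pk, 70)
  expect_equal(length(hrValues(hr)), 11)     # floor(70-60)/1 + 1
  expect_true(all(hrValues(hr) == 120))

  expect_true(all(hrValues(windowedHR(numeric(0), 65)) == 0))
  expect_length(hrValues(windowedHR(pk, 90, 60, 1)), 31)
  expect_error(windowedHR(pk, 50), "shorter")
})

test_that("shifting all peaks by one step shifts the HR series by one index", {
  set.seed(40)
  pk <- sort(stats::runif(200, 0, 100))
  h1 <- hrValues(windowedHR(pk, 100))          # windows start 0..40
  h2 <- hrValues(windowedHR(pk + 1, 101))      # windows start 0..41
  expect_equal(h2[-1], h1)                     # start i+1 sees start i's peaks
})

test_that("reference beats give the ground-truth HR through the same windowing", {
  # beats spaced 60/140 s starting at 0 over 120 s -> 140 BPM everywhere
  beats <- seq(0, 120 - 1e-9, by = 60 / 140)
  hr <- hrFromBeatTimes(beats, 120)
  expect_true(all(hrValues(hr) == 140))

  # beats identical to detected peaks -> Hr == He
  set.seed(41)
  pk <- sort(stats::runif(150, 0, 90))
  expect_equal(hrValues(hrFromBeatTimes(pk, 90)),
               hrValues(windowedHR(pk, 90)))

  # accelerating beats -> rising HR (monotone up to the +/-1 BPM
  # quantization of window counts)
  prof <- cbind(c(0, 180), c(120, 150))
  beats <- generateBeats(prof, 180)
  hr <- hrFromBeatTimes(beats, 180)
  expect_true(all(diff(hrValues(hr)) >= -1))
  expect_gt(hrValues(hr)[length(hrValues(hr))], hrValues(hr)[1] + 20)
})
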