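# Synthetic ground-truth videos.
#
# The generator emulates the measurement situation the pipeline faces: a
# skin-colored elliptical face on a non-skin background, whose face pixels
# carry a small additive periodic green-channel modulation locked to known
# beat times. It provides the ground truth the clinical recordings would
# otherwise supply, so every pipeline stage can be validated end to end.

# Evaluate the HR profile (scalar or piecewise-linear matrix) on a time
# grid. Internal.
.hrProfileAt <- function(hrBpm, t) {
  if (is.matrix(hrBpm)) {
    stats::approx(hrBpm[, 1], hrBpm[, 2], xout = t, rule = 2)$y
  } else {
    rep(as.numeric(hrBpm), length(t))
  }
}

#' Generate ground-truth beat times from a heart-rate profile
#'
#' Integrates the instantaneous rate: the cardiac phase advances by
#' hr(t)/60 cycles per second and a beat is emitted each time the
#' cumulative phase gains 1 (the first beat after one full cycle).
#' Deterministic given the profile; optional Gaussian timing jitter is
#' seeded.
#'
#' @param hrBpm constant BPM or a 2-column (time_s, bpm) matrix defining a
#'   piecewise-linear profile; must be positive throughout.
#' @param durationS clip duration, seconds.
#' @param jitterSd SD of additive beat-time jitter, seconds (default 0).
#' @param seed RNG seed used when \code{jitterSd > 0}.
#' @return numeric vector of beat times in (0, durationS].
#' @export
generateBeats <- function(hrBpm, durationS, jitterSd = 0, seed = 1L) {
  bpm <- if (is.matrix(hrBpm)) hrBpm[, 2] else hrBpm
  if (any(!is.finite(bpm)) || any(bpm <= 0) || any(bpm > 300))
    stop("hr profile must lie in (0, 300] BPM")
  tg <- seq(0, durationS, by = 1e-3)
  rate <- .hrProfileAt(hrBpm, tg) / 60             # cycles per second
  # cumulative phase by trapezoidal integration
  phase <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(tg)))
  nBeats <- floor(phase[length(phase)] + 1e-9)
  if (nBeats < 1L) return(numeric(0))
  beats <- stats::approx(phase, tg, xout = seq_len(nBeats), rule = 2)$y
  if (jitterSd > 0) {
    beats <- .withSeed(seed, beats + stats::rnorm(length(beats),
                                                  sd = jitterSd))
    beats <- sort(pmin(pmax(beats, 0), durationS))
  }
  beats
}

# Run expr under a fixed seed, restoring the caller's RNG state. Internal.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cardiac phase at arbitrary times from beat times: integer at each beat,
# linear in between, extrapolated at the local rate beyond the ends.
.phaseFromBeats <- function(beats, t) {
  k <- seq_along(beats)
  if (length(beats) >= 2L) {
    ph <- stats::approx(beats, k, xout = t, rule = 1)$y
    dt1 <- beats[2] - beats[1]
    dtN <- beats[length(beats)] - beats[length(beats) - 1L]
    lo <- t < beats[1]
    hi <- t > beats[length(beats)]
    ph[lo] <- 1 + (t[lo] - beats[1]) / dt1
    ph[hi] <- length(beats) + (t[hi] - beats[length(beats)]) / dtN
    ph
  } else if (length(beats) == 1L) {
    1 + (t - beats[1])                              # nominal 60 BPM
  } else {
    t                                               # no beats: 60 BPM
  }
}

#' Render a synthetic neonatal-face video
#'
#' Background pixels take \code{backgroundRgb} (HSV far outside the skin
#' bounds); ellipse pixels take \code{skinRgb} plus
#' \code{pulseAmp * sin(2 pi phase(t))} on the green channel, where the
#' phase advances one cycle per beat. Per-pixel Gaussian sensor noise is
#' added to all channels. Motion options: \code{rotation} spins the
#' ellipse about its center; \code{patch_corruption} replaces the
#' pulsatile term inside a seeded random fraction of d x d grid cells with
#' strong per-cell noise (the motion-artifact model: artifacts cover whole
#' regions but only a small part of the face). Frames are rendered in
#' floating point and quantized to 8 bits with seeded dither. Identical
#' spec + seed gives bit-identical frames.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param beats beat times from \code{\link{generateBeats}} (computed from
#'   \code{spec@hrBpm} when NULL).
#' @param returnMasks also return the per-frame true-face masks (set FALSE
#'   on long clips to save memory).
#' @return list: \code{video} (\linkS4class{FrameSequence}, integer 8-bit),
#'   \code{masks} (logical \code{H x W x T} true-face masks, or NULL),
#'   \code{beats} (the beat times used).
#' @export
renderVideo <- function(spec, beats = NULL, returnMasks = TRUE) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (is.null(beats)) beats <- generateBeats(spec@hrBpm, spec@durationS)
  h <- spec@height; w <- spec@width
  nT <- as.integer(round(spec@durationS * spec@fps))
  if (spec@faceCenter[1] - spec@faceAxes[1] < 0 ||
      spec@faceCenter[1] + spec@faceAxes[1] > h ||
      spec@faceCenter[2] - spec@faceAxes[2] < 0 ||
      spec@faceCenter[2] + spec@faceAxes[2] > w)
    stop("face ellipse extends outside the frame")

  tFrames <- (seq_len(nT) - 1) / spec@fps
  phase <- .phaseFromBeats(beats, tFrames)
  pulse <- spec@pulseAmp * sin(2 * pi * phase)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy0 <- rows - 0.5 - spec@faceCenter[1]
  dx0 <- cols - 0.5 - spec@faceCenter[2]
  ry <- spec@faceAxes[1]; rx <- spec@faceAxes[2]

  motion <- spec@motion
  rotating <- identical(motion$type, "rotation")
  staticMask <- NULL
  if (!rotating)
    staticMask <- (dy0 / ry)^2 + (dx0 / rx)^2 <= 1

  # corruption: choose grid cells overlapping the face, per-cell noise
  corruptIdx <- NULL
  corrNoise <- NULL
  if (identical(motion$type, "patch_corruption")) {
    ddiv <- if (is.null(motion$divisions)) 8L else as.integer(motion$divisions)
    amp <- if (is.null(motion$amplitude)) 40 else motion$amplitude
    grid <- makeGrid(h, w, ddiv)
    onFace <- vapply(grid@regions, function(r)
      any(staticMask[(r@row0 + 1L):r@row1, (r@col0 + 1L):r@col1]),
      logical(1))
    faceCells <- which(onFace)
    nCorrupt <- round(motion$fraction * length(faceCells))
    picked <- .withSeed(spec@seed + 1L,
                        sample(faceCells, nCorrupt))
    corrNoise <- .withSeed(spec@seed + 2L,
                           matrix(stats::rnorm(nCorrupt * nT, sd = amp),
                                  nCorrupt, nT))
    corruptIdx <- lapply(grid@regions[picked], function(r) {
      cellMask <- matrix(FALSE, h, w)
      cellMask[(r@row0 + 1L):r@row1, (r@col0 + 1L):r@col1] <- TRUE
      which(cellMask & staticMask)
    })
  }

  arr <- array(0L, dim = c(h, w, 3L, nT))
  masks <- if (returnMasks) array(FALSE, dim = c(h, w, nT)) else NULL
  .withSeed(spec@seed, {
    for (t in seq_len(nT)) {
      if (rotating) {
        th <- -motion$degPerS * tFrames[t] * pi / 180
        dyr <- dy0 * cos(th) - dx0 * sin(th)
        dxr <- dy0 * sin(th) + dx0 * cos(th)
        mask <- (dyr / ry)^2 + (dxr / rx)^2 <= 1
      } else {
        mask <- staticMask
      }
      if (returnMasks) masks[, , t] <- mask
      fr <- array(rep(spec@backgroundRgb, each = h * w), dim = c(h, w, 3L))
      for (ch in 1:3) {
        plane <- fr[, , ch]
        plane[mask] <- spec@skinRgb[ch]
        fr[, , ch] <- plane
      }
      g <- fr[, , 2]
      g[mask] <- g[mask] + pulse[t]
      if (!is.null(corruptIdx)) {
        for (ci in seq_along(corruptIdx)) {
          g[corruptIdx[[ci]]] <- spec@skinRgb[2] + corrNoise[ci, t]
        }
      }
      fr[, , 2] <- g
      if (spec@noiseSd > 0)
        fr <- fr + stats::rnorm(length(fr), sd = spec@noiseSd)
      # seeded dither + quantization to 8 bits
      fr <- fr + stats::runif(length(fr), -0.5, 0.5)
      arr[, , , t] <- pmin(pmax(as.integer(round(fr)), 0L), 255L)
    }
    NULL
  })
  list(video = frameSequence(arr, spec@fps), masks = masks, beats = beats)
}

#' Ground-truth HR series for a synthetic spec
#'
#' Convenience wrapper: beat times from the spec's HR profile, windowed
#' with the same one-minute window and one-second slide as the estimate.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param windowS,stepS window length and slide, seconds.
#' @return an \linkS4class{HRSeries}.
#' @export
truthHR <- function(spec, windowS = 60, stepS = 1) {
  beats <- generateBeats(spec@hrBpm, spec@durationS)
  hrFromBeatTimes(beats, spec@durationS, windowS = windowS, stepS = stepS)
}
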