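# Pulse extraction: green-channel spatial averaging, peak detection, and
# sliding-window conversion of peak counts to instantaneous heart rate.

#' Blood-volume-pulse trace of a patch video
#'
#' Spatially averages the green channel over the skin pixels of each frame.
#' The green channel carries the strongest pulsatile signal of the three;
#' averaging over skin pixels only (rather than the whole patch including
#' the zeroed background) avoids diluting the pulse amplitude by the
#' non-skin fraction of the patch.
#'
#' @param patchVideo a (typically magnified) \linkS4class{FrameSequence}.
#' @param mask logical mask restricted to the patch region, TRUE = skin.
#'   Patches with an empty mask were already dropped by the validity
#'   filter, so an empty mask is an error here.
#' @return a \linkS4class{BvpTrace}.
#' @export
greenTrace <- function(patchVideo, mask) {
  stopifnot(is(patchVideo, "FrameSequence"))
  d <- dim(patchVideo@frames)
  if (!all(dim(mask) == d[1:2]))
    stop("mask must match the patch's spatial shape")
  idx <- which(mask)
  if (!length(idx)) stop("empty skin mask: patch carries no ROI")
  nT <- d[4]
  vals <- numeric(nT)
  step <- max(1L, as.integer(2e7 / (d[1] * d[2])))  # bound copy size
  for (s in seq(1L, nT, by = step)) {
    ts <- s:min(s + step - 1L, nT)
    g <- patchVideo@frames[, , 2L, ts, drop = FALSE]
    dim(g) <- c(d[1] * d[2], length(ts))
    vals[ts] <- colMeans(g[idx, , drop = FALSE])
  }
  bvpTrace(vals, patchVideo@fps)
}

# Local maxima of a numeric vector; for a plateau the last flat sample is
# the candidate. Internal.
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  s <- sign(diff(v))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  # carry the sign of the preceding non-flat step across plateaus
  filled <- s
  z <- which(s == 0)
  if (length(z)) {
    fi <- findInterval(z, nz)
    ok <- fi > 0L
    filled[z[ok]] <- s[nz[fi[ok]]]
  }
  # a peak is a rise followed by a fall
  which(filled[-length(filled)] > 0 & filled[-1] < 0) + 1L
}

# Topographic prominence of peak p: height above the higher of the two
# minima separating it from the nearest higher terrain (or series edge).
.prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    left <- v[seq_len(p - 1L)]
    higher <- which(left > v[p])
    lo <- if (length(higher)) min(v[(max(higher) + 1L):(p - 1L)]) else
      min(left)
    right <- v[(p + 1L):length(v)]
    higherR <- which(right > v[p])
    hi <- if (length(higherR)) min(right[seq_len(min(higherR) - 1L)]) else
      min(right)
    v[p] - max(lo, hi)
  }, numeric(1))
}

#' Detect pulse peaks in a BVP trace
#'
#' Local maxima are screened by topographic prominence (at least
#' \code{prominenceFactor} times the trace SD) and a minimum separation
#' (taller peaks win). With the defaults, the separation of 0.30 s is 80%
#' of the beat period at the 160 BPM band edge, so double counting within
#' the passband is impossible. The trace is linearly detrended first
#' (the bandpass already removed DC; detrending guards residual edge
#' drift). A flat trace yields no peaks.
#'
#' @param trace a \linkS4class{BvpTrace}.
#' @param cfg a \linkS4class{PeakConfig}.
#' @return numeric vector of peak times in seconds (\code{(index-1)/fps}).
#' @export
detectPeaks <- function(trace, cfg = peakConfig()) {
  stopifnot(is(trace, "BvpTrace"), is(cfg, "PeakConfig"))
  v <- trace@values
  if (length(v) < 3L) stop("trace too short for peak detection")
  if (cfg@detrend) {
    tt <- seq_along(v)
    v <- stats::residuals(stats::lm.fit(cbind(1, tt), v))
  }
  sdv <- stats::sd(v)
  if (!is.finite(sdv) || sdv == 0) return(numeric(0))

  cand <- .localMaxima(v)
  if (!length(cand)) return(numeric(0))
  keep <- .prominence(v, cand) >= cfg@prominenceFactor * sdv
  cand <- cand[keep]
  if (!length(cand)) return(numeric(0))

  # enforce minimum separation, tallest peaks first
  minSep <- cfg@minSeparationS * trace@fps
  ord <- cand[order(v[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (p in ord) {
    if (!length(accepted) || all(abs(accepted - p) >= minSep))
      accepted <- c(accepted, p)
  }
  sort(accepted - 1L) / trace@fps
}

#' Sliding-window heart rate from peak times
#'
#' Counts peaks in a one-minute window sliding by one second: window i
#' covers \code{[i, i + windowS)} seconds and reports
#' \code{count * 60 / windowS} BPM (the raw count is already BPM for a
#' 60 s window). The series has
#' \code{floor((durationS - windowS) / stepS) + 1} values, the first at
#' window start 0.
#'
#' @param peakTimes peak (or beat) times, seconds.
#' @param durationS clip duration, seconds; must be >= \code{windowS}.
#' @param windowS,stepS window length and slide, seconds.
#' @return an \linkS4class{HRSeries}.
#' @export
windowedHR <- function(peakTimes, durationS, windowS = 60, stepS = 1) {
  if (durationS < windowS)
    stop("clip shorter than the HR window")
  starts <- seq(0, durationS - windowS, by = stepS)
  pt <- sort(peakTimes)
  counts <- vapply(starts, function(s)
    sum(pt >= s & pt < s + windowS), numeric(1))
  hrSeries(starts, counts * 60 / windowS, windowS = windowS, stepS = stepS)
}

#' Ground-truth heart rate from reference beat times
#'
#' Identical windowing contract to \code{\link{windowedHR}}, applied to
#' reference beat timestamps (e.g. ECG R-peak times): this is the
#' ground-truth Hr(i) pathway, computed with the same one-minute window
#' and one-second slide as the estimate so that the two series align.
#'
#' @inheritParams windowedHR
#' @param beatTimes reference beat times, seconds.
#' @return an \linkS4class{HRSeries}.
#' @export
hrFromBeatTimes <- function(beatTimes, durationS, windowS = 60, stepS = 1) {
  windowedHR(beatTimes, durationS, windowS = windowS, stepS = stepS)
}
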