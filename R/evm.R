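# Eulerian video magnification.
#
# The Eulerian scheme amplifies temporal intensity variation at fixed pixel
# positions instead of tracking pixel trajectories: each frame is
# decomposed into spatial frequency bands with a full Laplacian pyramid,
# every pyramid position's time series is ideally bandpass-filtered over
# the heart-rate band, the filtered signal is scaled by alpha and added
# back to the original band, and the pyramid is collapsed. For an additive
# in-band modulation the output amplitude is (1 + alpha) times the input;
# out-of-band content passes through with gain 1.
#
# All pyramid steps are linear, so they are implemented as banded operator
# matrices applied to the unfolded video array — one BLAS call per
# dimension covers every frame at once.

.pyrKernel <- c(1, 4, 6, 4, 1) / 16

# n x n binomial blur with replicate (clamped) borders.
.blurMatrix <- function(n) {
  B <- matrix(0, n, n)
  for (off in -2:2) {
    j <- pmin(pmax(seq_len(n) + off, 1L), n)
    idx <- cbind(seq_len(n), j)
    B[idx] <- B[idx] + .pyrKernel[off + 3L]
  }
  B
}

# Blur + take odd samples: ceil(n/2) x n.
.downMatrix <- function(n) {
  .blurMatrix(n)[seq(1L, n, by = 2L), , drop = FALSE]
}

# Zero-insert at odd positions then blur with twice the kernel; rows are
# renormalized so upsampling preserves constants exactly at the borders
# (and hence a constant image has identically zero detail levels).
# nBig x ceil(nBig/2).
.upMatrix <- function(nBig) {
  nSmall <- as.integer(ceiling(nBig / 2))
  Z <- matrix(0, nBig, nSmall)
  Z[cbind(seq(1L, nBig, by = 2L), seq_len(nSmall))] <- 1
  U <- 2 * .blurMatrix(nBig) %*% Z
  U / rowSums(U)
}

.as3d <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# Separable operator M_row x M_col applied frame by frame; allocates only
# the result, keeping peak memory low on long clips.
.applySep <- function(a, Mr, Mc) {
  a <- .as3d(a)
  nT <- dim(a)[3]
  out <- array(0, dim = c(nrow(Mr), nrow(Mc), nT))
  tMc <- t(Mc)
  for (t in seq_len(nT)) out[, , t] <- Mr %*% a[, , t] %*% tMc
  out
}

.pyrDown <- function(a) {
  a <- .as3d(a)
  .applySep(a, .downMatrix(dim(a)[1]), .downMatrix(dim(a)[2]))
}

.pyrUp <- function(a, targetHW) {
  .applySep(.as3d(a), .upMatrix(targetHW[1]), .upMatrix(targetHW[2]))
}

# Number of detail levels for an H x W frame: keep the coarsest level at
# least ~4 px per side.
.pyramidDepth <- function(h, w, maxLevels) {
  if (min(h, w) < 2L) return(0L)
  min(as.integer(maxLevels), max(1L, floor(log2(min(h, w))) - 2L))
}

#' Build the Laplacian pyramid of a single-channel image
#'
#' The image is repeatedly blurred (5-tap binomial kernel, replicate
#' borders) and downsampled by 2; each detail level is the difference
#' between a Gaussian level and the upsampled next-coarser level. The
#' number of detail levels is \code{min(maxLevels,
#' max(1, floor(log2(min(H, W))) - 2))}, keeping the residual at least
#' about 4 px per side; a 1-pixel image yields a residual-only pyramid.
#'
#' @param frame numeric matrix (single channel).
#' @param maxLevels cap on the number of detail levels.
#' @return a \linkS4class{Pyramid}.
#' @export
buildPyramid <- function(frame, maxLevels = 8L) {
  if (!is.matrix(frame)) stop("frame must be a single-channel matrix")
  if (maxLevels < 1L) stop("maxLevels must be >= 1")
  L <- .pyramidDepth(nrow(frame), ncol(frame), maxLevels)
  g <- frame
  levels <- vector("list", L)
  if (L > 0L) {
    for (i in seq_len(L)) {
      gd <- .pyrDown(g)[, , 1]
      levels[[i]] <- g - .pyrUp(gd, dim(g))[, , 1]
      g <- gd
    }
  }
  new("Pyramid", levels = levels, residual = as.matrix(g))
}

#' Collapse a Laplacian pyramid back to an image
#'
#' Exactly inverts \code{\link{buildPyramid}}: starting from the residual,
#' each level is upsampled and the detail image added back.
#'
#' @param pyr a \linkS4class{Pyramid}.
#' @return the reconstructed matrix.
#' @export
collapsePyramid <- function(pyr) {
  stopifnot(is(pyr, "Pyramid"))
  g <- pyr@residual
  for (i in rev(seq_along(pyr@levels))) {
    lvl <- pyr@levels[[i]]
    if (!all(dim(g) == ceiling(dim(lvl) / 2)))
      stop("pyramid level shapes are inconsistent")
    g <- .pyrUp(g, dim(lvl))[, , 1] + lvl
  }
  g
}

#' Ideal temporal bandpass filter
#'
#' Zeroes every Fourier coefficient whose frequency magnitude lies outside
#' \code{[fLo, fHi]} (inclusive), including DC, and inverts the transform.
#' This is the hard-cutoff filter used over the 110-160 BPM heart-rate
#' band: it cuts the band of interest out directly and never amplifies
#' neighboring frequencies.
#'
#' @param series numeric vector (length >= 2).
#' @param fps sampling rate, Hz.
#' @param fLo,fHi passband edges, Hz; \code{fHi} must be below Nyquist.
#' @return real-valued filtered series of the same length.
#' @export
idealBandpass <- function(series, fps, fLo = 110 / 60, fHi = 160 / 60) {
  if (length(series) < 2L) stop("series must have length >= 2")
  if (!(fLo > 0 && fLo < fHi)) stop("need 0 < fLo < fHi")
  if (fHi >= fps / 2) stop("passband must lie below the Nyquist frequency")
  m <- matrix(series, ncol = 1L)
  drop(.bandpassTime(m, fps, fLo, fHi))
}

# Bandpass the columns of a T x N matrix.
.bandpassTime <- function(M, fps, fLo, fHi) {
  nT <- nrow(M)
  f <- (seq_len(nT) - 1) * fps / nT
  keep <- (f >= fLo & f <= fHi) | ((fps - f) >= fLo & (fps - f) <= fHi)
  Fm <- stats::mvfft(M)
  Fm[!keep, ] <- 0+0i
  Re(stats::mvfft(Fm, inverse = TRUE)) / nT
}

#' Eulerian magnification of a patch video
#'
#' Per selected channel: build the video's Laplacian pyramid (all frames at
#' once), ideally bandpass every pyramid position's time series over
#' \code{[fLo, fHi]}, multiply the filtered signal by \code{alpha}, add it
#' to the original level, and collapse. Filtering runs once over the whole
#' clip (offline). The output is kept in floating point and may exceed
#' [0, 255]; it is clipped only if re-exported as video.
#'
#' @param patchVideo a \linkS4class{FrameSequence} with at least
#'   \code{2 * fps / fLo} frames (~2 periods at the slow band edge).
#' @param cfg an \linkS4class{EVMConfig}.
#' @return a real-valued \linkS4class{FrameSequence}.
#' @export
magnify <- function(patchVideo, cfg = evmConfig()) {
  stopifnot(is(patchVideo, "FrameSequence"), is(cfg, "EVMConfig"))
  fps <- patchVideo@fps
  if (cfg@fHi >= fps / 2)
    stop("passband must lie below the Nyquist frequency")
  d <- dim(patchVideo@frames)
  if (d[4] < 2 * fps / cfg@fLo)
    stop("patch video too short: need at least 2 * fps / fLo frames")

  chanIdx <- match(cfg@channels, c("r", "g", "b"))
  L <- .pyramidDepth(d[1], d[2], cfg@maxLevels)
  nT <- d[4]

  # R += D + alpha * bandpass(D), where D = G - U rowwise, streamed over
  # pixel chunks so large patches never materialize full complex spectra.
  addAmplified <- function(R, G, U, chunk = 2048L) {
    hw <- nrow(G)
    for (s in seq(1L, hw, by = chunk)) {
      cs <- s:min(s + chunk - 1L, hw)
      D <- G[cs, , drop = FALSE]
      if (!is.null(U)) D <- D - U[cs, , drop = FALSE]
      D <- D + cfg@alpha * t(.bandpassTime(t(D), fps, cfg@fLo, cfg@fHi))
      R[cs, ] <- R[cs, ] + D
    }
    R
  }
  flat <- function(a) { dim(a) <- c(dim(a)[1] * dim(a)[2], nT); a }

  magnified <- vector("list", 3L)
  for (ch in chanIdx) {
    gp <- vector("list", L + 1L)
    gp[[1L]] <- array(as.numeric(patchVideo@frames[, , ch, , drop = FALSE]),
                      dim = d[c(1, 2, 4)])
    if (L > 0L) for (i in seq_len(L)) gp[[i + 1L]] <- .pyrDown(gp[[i]])

    # residual level: amplify in place
    res <- gp[[L + 1L]]
    hwRes <- dim(res)[1:2]
    acc <- addAmplified(matrix(0, hwRes[1] * hwRes[2], nT), flat(res), NULL)
    dim(acc) <- c(hwRes, nT)
    if (L > 0L) {
      for (i in rev(seq_len(L))) {
        hwi <- dim(gp[[i]])[1:2]
        R <- flat(.pyrUp(acc, hwi))
        U <- flat(.pyrUp(gp[[i + 1L]], hwi))
        gp[i + 1L] <- list(NULL)
        R <- addAmplified(R, flat(gp[[i]]), U)
        rm(U)
        dim(R) <- c(hwi, nT)
        acc <- R
      }
    }
    gp <- NULL
    magnified[[ch]] <- acc
  }

  out <- array(0, dim = d)
  for (ch in 1:3) {
    out[, , ch, ] <- if (is.null(magnified[[ch]])) {
      as.numeric(patchVideo@frames[, , ch, , drop = FALSE])
    } else {
      magnified[[ch]]
    }
    magnified[ch] <- list(NULL)
  }
  frameSequence(out, fps)
}
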