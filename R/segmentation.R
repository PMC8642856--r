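# Skin segmentation: HSV-interval thresholding + morphological smoothing.
#
# Skin is located by its color rather than by facial features, so the
# segmentation keeps working regardless of head rotation or non-rigid
# motion (the motions neonates actually make). The working assumption is
# that no large skin-colored objects other than the face are in view.

#' Convert an RGB frame to HSV
#'
#' Uses the 8-bit convention H in [0, 180), S and V in [0, 255] (the scale
#' on which the default skin bounds (0,10,60)-(20,150,255) are expressed).
#' Values are continuous (no 8-bit re-quantization of the HSV channels).
#'
#' @param frame numeric \code{H x W x 3} RGB array, values in [0, 255].
#' @return numeric \code{H x W x 3} HSV array.
#' @export
rgbToHsv <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stop("frame must be an H x W x 3 RGB array")
  m <- matrix(as.numeric(frame), ncol = 3L)          # N x (r, g, b)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- hsv[1, ] * 180
  out[, , 2] <- hsv[2, ] * 255
  out[, , 3] <- hsv[3, ] * 255
  out
}

#' Threshold an HSV frame against interval bounds
#'
#' @param hsv \code{H x W x 3} HSV array on the H 0-180 / S,V 0-255 scale.
#' @param bounds an \linkS4class{HsvBounds}.
#' @return logical \code{H x W} mask, TRUE where all three channels lie
#'   inside \code{[lower, upper]} (inclusive at both ends).
#' @export
hsvInRange <- function(hsv, bounds) {
  stopifnot(is(bounds, "HsvBounds"))
  lo <- bounds@lower; hi <- bounds@upper
  (hsv[, , 1] >= lo[1] & hsv[, , 1] <= hi[1] &
   hsv[, , 2] >= lo[2] & hsv[, , 2] <= hi[2] &
   hsv[, , 3] >= lo[3] & hsv[, , 3] <= hi[3])
}

#' Skin mask of a single RGB frame
#'
#' Converts the frame to HSV and retains pixels inside the skin interval.
#'
#' @param frame \code{H x W x 3} RGB array, 8-bit values.
#' @param bounds an \linkS4class{HsvBounds} (default: neonatal skin).
#' @return logical \code{H x W} mask, TRUE = skin.
#' @export
skinMask <- function(frame, bounds = hsvBounds()) {
  hsvInRange(rgbToHsv(frame), bounds)
}

#' Morphological smoothing of a binary mask
#'
#' Applies the morphological open operation (erosion then dilation, which
#' removes small skin-colored specks) and close operation (dilation then
#' erosion, which fills small holes) in succession, perfecting the
#' elliptical face boundary. Backed by \pkg{EBImage}.
#'
#' @param mask logical \code{H x W} mask.
#' @param cfg a \linkS4class{MorphConfig}.
#' @return logical mask of the same shape.
#' @export
morphSmooth <- function(mask, cfg = morphConfig()) {
  stopifnot(is(cfg, "MorphConfig"))
  if (cfg@kernelSize > min(dim(mask)))
    stop("structuring element larger than the mask")
  kern <- EBImage::makeBrush(cfg@kernelSize, shape = cfg@kernelShape)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- if (cfg@openThenClose) {
    EBImage::closing(EBImage::opening(m, kern), kern)
  } else {
    EBImage::opening(EBImage::closing(m, kern), kern)
  }
  matrix(as.logical(out > 0), nrow(mask), ncol(mask))
}

#' Zero the background of a sequence
#'
#' Sets every pixel where the mask is FALSE to (0, 0, 0); skin pixels are
#' untouched. After this step the video background is black, which is what
#' the patch-validity rule keys on.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param masks logical \code{H x W x T} array or a list of T masks (a
#'   single \code{H x W} mask is recycled over all frames).
#' @return a masked \linkS4class{FrameSequence}.
#' @export
applyMask <- function(seq, masks) {
  stopifnot(is(seq, "FrameSequence"))
  d <- dim(seq@frames)
  if (is.list(masks)) masks <- array(unlist(masks), dim = c(d[1], d[2],
                                                            length(masks)))
  if (is.matrix(masks)) {
    if (!all(dim(masks) == d[1:2]))
      stop("mask shape does not match the frames")
    masks <- array(masks, dim = c(d[1], d[2], d[4]))
  }
  if (!all(dim(masks) == d[c(1, 2, 4)]))
    stop("need one H x W mask per frame")
  arr <- seq@frames
  drop3 <- !masks                      # recycled over the channel planes
  for (ch in 1:3) {
    plane <- arr[, , ch, , drop = FALSE]
    plane[drop3] <- 0L
    arr[, , ch, ] <- plane
  }
  frameSequence(arr, seq@fps)
}

#' Segment a whole sequence
#'
#' Per-frame skin mask + morphological smoothing, then background zeroing.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param bounds an \linkS4class{HsvBounds}.
#' @param morph a \linkS4class{MorphConfig}.
#' @return list with \code{seq} (masked sequence) and \code{masks}
#'   (logical \code{H x W x T}).
#' @export
segmentSequence <- function(seq, bounds = hsvBounds(),
                            morph = morphConfig()) {
  d <- dim(seq@frames)
  masks <- array(FALSE, dim = c(d[1], d[2], d[4]))
  for (t in seq_len(d[4])) {
    m <- skinMask(seq@frames[, , , t], bounds)
    masks[, , t] <- morphSmooth(m, morph)
  }
  list(seq = applyMask(seq, masks), masks = masks)
}
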