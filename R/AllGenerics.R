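# Accessor generics and show methods.

#' @rdname FrameSequence-class
#' @param object,x a FrameSequence (or other object with the accessor).
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname FrameSequence-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname HRSeries-class
#' @param x an HRSeries.
#' @export
setGeneric("hrTimes", function(x) standardGeneric("hrTimes"))

#' @rdname HRSeries-class
#' @export
setGeneric("hrValues", function(x) standardGeneric("hrValues"))

#' @export
#' @describeIn FrameSequence-class frame rate in Hz.
setMethod("fps", "FrameSequence", function(x) x@fps)

#' @export
#' @describeIn BvpTrace-class sampling rate in Hz.
setMethod("fps", "BvpTrace", function(x) x@fps)

#' @export
#' @describeIn FrameSequence-class the H x W x 3 x T array.
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @export
#' @describeIn FrameSequence-class number of frames T.
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[4])

#' @export
#' @describeIn FrameSequence-class c(H, W) spatial size.
setMethod("frameDim", "FrameSequence", function(x) dim(x@frames)[1:2])

#' @export
#' @describeIn HRSeries-class window start times, seconds.
setMethod("hrTimes", "HRSeries", function(x) x@times)

#' @export
#' @describeIn HRSeries-class heart rates, BPM.
setMethod("hrValues", "HRSeries", function(x) x@values)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d @ %.6g fps (%.4g s), %s\n",
              d[4], d[1], d[2], object@fps, d[4] / object@fps,
              storage.mode(object@frames)))
})

setMethod("show", "HRSeries", function(object) {
  cat(sprintf(
    "HRSeries: %d values, window %g s / step %g s, t = [%g, %g] s\n",
    length(object@values), object@windowS, object@stepS,
    if (length(object@times)) min(object@times) else NA,
    if (length(object@times)) max(object@times) else NA))
  v <- object@values[is.finite(object@values)]
  if (length(v))
    cat(sprintf("  HR range %.1f - %.1f BPM (median %.1f)\n",
                min(v), max(v), stats::median(v)))
})

setMethod("show", "BvpTrace", function(object) {
  cat(sprintf("BvpTrace: %d samples @ %g fps (%.3g s), sd %.4g\n",
              length(object@values), object@fps,
              length(object@values) / object@fps, stats::sd(object@values)))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d x %d tiling of a %d x %d frame (%d regions)\n",
              object@divisions, object@divisions, object@height,
              object@width, length(object@regions)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "HR agreement over %d s:\n  MAE %.3f BPM  MRE %.3f%%  RMSE %.3f BPM  SD %.3f BPM  (mean error %.3f BPM)\n",
    object@n, object@mae, object@mre, object@rmse, object@sd, object@mu))
})

setMethod("show", "BlandAltman", function(object) {
  cat(sprintf(
    "Bland-Altman: bias %.3f BPM, sd %.3f, 95%% LoA [%.3f, %.3f] BPM\n",
    object@bias, object@sdDiff, object@loaLo, object@loaHi))
})

setMethod("show", "PipelineResult", function(object) {
  cat(sprintf("PipelineResult: %d patches voted over %d seconds\n",
              length(object@perPatch), length(object@hr@values)))
  show(object@hr)
})
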