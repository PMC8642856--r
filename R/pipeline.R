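# End-to-end orchestration: segment -> divide -> magnify -> pulse -> vote.

#' Run the full heart-rate estimation pipeline
#'
#' Stages, in order: (1) per-frame skin segmentation (HSV thresholding +
#' morphological smoothing) and background zeroing; (2) division of the
#' frame into a d x d grid, keeping patches whose first frame contains ROI
#' content; (3) Eulerian magnification of each patch video; (4) per-patch
#' BVP extraction by green-channel averaging over the patch's first-frame
#' skin pixels, peak detection, and sliding-window HR; (5) histogram
#' majority voting across patches at each second. Patch videos are
#' processed independently and sequentially; the run is deterministic —
#' there is no randomness anywhere in the estimation path.
#'
#' Seconds with no in-range patch vote carry the previous voted value
#' forward and are flagged in the diagnostics.
#'
#' @param video a \linkS4class{FrameSequence}; duration must be at least
#'   \code{windowS + 2} seconds.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param verbose print per-stage progress.
#' @return a \linkS4class{PipelineResult}.
#' @examples
#' \donttest{
#' spec <- syntheticSpec(durationS = 65, fps = 30, height = 60L,
#'                       width = 80L, hrBpm = 140, seed = 1L)
#' rv <- renderVideo(spec, returnMasks = FALSE)
#' res <- runPipeline(rv$video, pipelineConfig(divisions = 4L))
#' res@hr
#' computeMetrics(res@hr, hrFromBeatTimes(rv$beats, 65))
#' }
#' @export
runPipeline <- function(video, cfg = pipelineConfig(), verbose = FALSE) {
  stopifnot(is(video, "FrameSequence"), is(cfg, "PipelineConfig"))
  durationS <- nFrames(video) / fps(video)
  if (durationS < cfg@windowS + 2)
    stop("video too short: need at least windowS + 2 seconds")

  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  seg <- segmentSequence(video, cfg@bounds, cfg@morph)
  timings["segmentation"] <- tic() - t0
  say("segmented %d frames in %.1f s", nFrames(video),
      timings["segmentation"])

  t0 <- tic()
  hw <- frameDim(video)
  grid <- makeGrid(hw[1], hw[2], cfg@divisions)
  firstFrame <- seg$seq@frames[, , , 1]
  regions <- validPatches(firstFrame, grid)
  timings["patching"] <- tic() - t0
  if (!length(regions))
    stop("empty ROI: no patch contains skin in the first frame")
  say("retained %d / %d patches", length(regions), length(grid@regions))

  firstMask <- seg$masks[, , 1]
  seg["masks"] <- list(NULL)          # release per-frame masks
  t0 <- tic()
  perPatch <- vector("list", length(regions))
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    wholeFrame <- r@row0 == 0L && r@col0 == 0L &&
      r@row1 == hw[1] && r@col1 == hw[2]
    patchSeq <- if (wholeFrame) seg$seq else extractPatch(seg$seq, r)
    mag <- magnify(patchSeq, cfg@evm)
    trace <- greenTrace(mag, .maskPatch(firstMask, r))
    peaks <- detectPeaks(trace, cfg@peak)
    perPatch[[k]] <- windowedHR(peaks, durationS,
                                windowS = cfg@windowS, stepS = cfg@stepS)
    big <- prod(dim(mag@frames)) > 5e7
    rm(patchSeq, mag, trace)
    if (big) gc(verbose = FALSE)      # large patches: return memory eagerly
  }
  timings["magnify_pulse"] <- tic() - t0
  say("magnified + pulsed %d patches in %.1f s", length(regions),
      timings["magnify_pulse"])

  t0 <- tic()
  voted <- voteSeries(perPatch, cfg@vote)
  timings["voting"] <- tic() - t0

  new("PipelineResult",
      hr = voted, perPatch = perPatch, regions = regions,
      diagnostics = list(
        retainedPatches = length(regions),
        totalPatches = length(grid@regions),
        timings = timings,
        binCounts = attr(voted, "binCounts"),
        noConsensus = attr(voted, "noConsensus")))
}
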