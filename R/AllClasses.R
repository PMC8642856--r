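#' @import methods
NULL

# ---------------------------------------------------------------------------
# FrameSequence
# ---------------------------------------------------------------------------

#' FrameSequence: a time-ordered stack of RGB frames
#'
#' The universal carrier between pipeline stages: a 4-dimensional array of
#' dimension \code{H x W x 3 x T} (rows, columns, RGB channel, frame index)
#' together with a frame rate in Hz. Frames are indexed \code{t = 1..T}
#' (time \code{(t-1)/fps} seconds); pixel \code{(1, 1)} is the top-left
#' corner. Channel order is always RGB internally; the AVI reader/writer
#' isolates the container's BGR convention.
#'
#' Pixel values of freshly read or rendered video are 8-bit integers in
#' \code{[0, 255]}. After Eulerian magnification the carrier holds real
#' values which may exceed that range; values are only clipped back to
#' 8 bits when a sequence is re-exported as video.
#'
#' @slot frames numeric or integer array, \code{H x W x 3 x T}.
#' @slot fps frames per second (Hz), positive.
#' @export
setClass("FrameSequence",
  representation(frames = "array", fps = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 4L) return("frames must be a H x W x 3 x T array")
    if (d[3] != 3L) return("third dimension must hold exactly 3 (RGB) channels")
    if (d[4] < 1L) return("sequence must contain at least one frame")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      return("fps must be a single positive number")
    TRUE
  }
)

#' Construct a FrameSequence
#'
#' @param frames array \code{H x W x 3 x T} (a single \code{H x W x 3} frame
#'   is promoted to \code{T = 1}).
#' @param fps frames per second, Hz.
#' @return A \linkS4class{FrameSequence}.
#' @export
frameSequence <- function(frames, fps) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  new("FrameSequence", frames = frames, fps = as.numeric(fps))
}

# ---------------------------------------------------------------------------
# Segmentation configuration
# ---------------------------------------------------------------------------

#' HSV interval bounds for skin segmentation
#'
#' Componentwise-inclusive lower/upper bounds in HSV space under the 8-bit
#' convention H in [0, 180), S and V in [0, 255]. The defaults are the skin
#' interval for (Chinese) neonates: lower (0, 10, 60), upper (20, 150, 255).
#'
#' @slot lower,upper numeric length-3 vectors (h, s, v).
#' @export
setClass("HsvBounds",
  representation(lower = "numeric", upper = "numeric"),
  validity = function(object) {
    if (length(object@lower) != 3L || length(object@upper) != 3L)
      return("lower and upper must be (h, s, v) triples")
    if (any(object@lower > object@upper))
      return("lower must be <= upper componentwise")
    if (object@lower[1] < 0 || object@upper[1] > 180)
      return("hue must lie in [0, 180]")
    if (any(object@lower[-1] < 0) || any(object@upper[-1] > 255))
      return("saturation/value must lie in [0, 255]")
    TRUE
  }
)

#' @rdname HsvBounds-class
#' @param lower,upper (h, s, v) triples; h on 0-180, s and v on 0-255.
#' @export
hsvBounds <- function(lower = c(0, 10, 60), upper = c(20, 150, 255)) {
  new("HsvBounds", lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Morphological smoothing configuration
#'
#' Structuring element and operation order for smoothing the binary skin
#' mask. Default: 5x5 elliptical (disc) element, opening followed by
#' closing — opening removes isolated skin-colored specks, closing fills
#' small holes inside the face.
#'
#' @slot kernelSize odd integer, side of the structuring element in pixels.
#' @slot kernelShape \code{"disc"} or \code{"box"}.
#' @slot openThenClose logical; if FALSE, close then open.
#' @export
setClass("MorphConfig",
  representation(kernelSize = "integer", kernelShape = "character",
                 openThenClose = "logical"),
  validity = function(object) {
    if (object@kernelSize < 1L) return("kernel size must be >= 1 pixel")
    if (object@kernelSize %% 2L == 0L) return("kernel size must be odd")
    if (!object@kernelShape %in% c("disc", "box"))
      return("kernelShape must be 'disc' or 'box'")
    TRUE
  }
)

#' @rdname MorphConfig-class
#' @param kernelSize odd structuring-element side length, pixels.
#' @param kernelShape "disc" (elliptical) or "box".
#' @param openThenClose apply opening before closing.
#' @export
morphConfig <- function(kernelSize = 5L, kernelShape = "disc",
                        openThenClose = TRUE) {
  new("MorphConfig", kernelSize = as.integer(kernelSize),
      kernelShape = kernelShape, openThenClose = openThenClose)
}

# ---------------------------------------------------------------------------
# Patching
# ---------------------------------------------------------------------------

#' A rectangular patch of the frame
#'
#' Bounds are 0-based and half-open: the patch covers pixel rows
#' \code{row0 .. row1 - 1} and columns \code{col0 .. col1 - 1}.
#'
#' @slot row0,row1,col0,col1 integer pixel bounds.
#' @export
setClass("PatchRegion",
  representation(row0 = "integer", row1 = "integer",
                 col0 = "integer", col1 = "integer"),
  validity = function(object) {
    if (object@row0 < 0L || object@col0 < 0L) return("bounds must be >= 0")
    if (object@row0 >= object@row1 || object@col0 >= object@col1)
      return("half-open bounds require row0 < row1 and col0 < col1")
    TRUE
  }
)

#' @rdname PatchRegion-class
#' @param row0,row1,col0,col1 0-based half-open pixel bounds.
#' @export
patchRegion <- function(row0, row1, col0, col1) {
  new("PatchRegion", row0 = as.integer(row0), row1 = as.integer(row1),
      col0 = as.integer(col0), col1 = as.integer(col1))
}

#' An equal d x d tiling of the frame
#'
#' @slot divisions number of cuts per dimension.
#' @slot height,width frame dimensions the grid tiles.
#' @slot regions list of \linkS4class{PatchRegion}, row-major order.
#' @export
setClass("PatchGrid",
  representation(divisions = "integer", height = "integer", width = "integer",
                 regions = "list"),
  validity = function(object) {
    if (length(object@regions) != object@divisions^2)
      return("grid must contain divisions^2 regions")
    TRUE
  }
)

# ---------------------------------------------------------------------------
# Eulerian video magnification
# ---------------------------------------------------------------------------

#' Eulerian video magnification configuration
#'
#' Defaults follow the neonatal operating point: amplification
#' \code{alpha = 150} and an ideal temporal bandpass over the infant
#' heart-rate range 110-160 BPM, i.e. cutoffs 110/60 = 1.8333 Hz and
#' 160/60 = 2.6667 Hz. \code{channels} selects which RGB channels are
#' magnified; only the green channel is consumed downstream, so the default
#' magnifies green only (all three available via \code{c("r","g","b")}).
#'
#' @slot alpha dimensionless amplification factor, >= 0.
#' @slot fLo,fHi bandpass cutoffs, Hz.
#' @slot maxLevels cap on Laplacian-pyramid depth.
#' @slot channels character subset of \code{c("r","g","b")}.
#' @export
setClass("EVMConfig",
  representation(alpha = "numeric", fLo = "numeric", fHi = "numeric",
                 maxLevels = "integer", channels = "character"),
  validity = function(object) {
    if (object@alpha < 0) return("alpha must be >= 0")
    if (!(object@fLo > 0 && object@fLo < object@fHi))
      return("need 0 < fLo < fHi")
    if (object@maxLevels < 1L) return("maxLevels must be >= 1")
    if (!all(object@channels %in% c("r", "g", "b")) ||
        length(object@channels) < 1L)
      return("channels must be a non-empty subset of c('r','g','b')")
    TRUE
  }
)

#' @rdname EVMConfig-class
#' @param alpha amplification factor.
#' @param fLo,fHi temporal passband, Hz (defaults 110/60 and 160/60).
#' @param maxLevels pyramid depth cap.
#' @param channels channels to magnify.
#' @export
evmConfig <- function(alpha = 150, fLo = 110 / 60, fHi = 160 / 60,
                      maxLevels = 8L, channels = "g") {
  new("EVMConfig", alpha = alpha, fLo = fLo, fHi = fHi,
      maxLevels = as.integer(maxLevels), channels = channels)
}

#' Laplacian pyramid of a single-channel image
#'
#' \code{levels} holds the detail (bandpass) images from finest to
#' coarsest; \code{residual} is the low-pass remainder at the coarsest
#' resolution. \code{collapsePyramid(buildPyramid(x))} reconstructs
#' \code{x} exactly up to floating-point error.
#'
#' @slot levels list of detail matrices, finest first.
#' @slot residual low-pass residual matrix.
#' @export
setClass("Pyramid",
  representation(levels = "list", residual = "matrix"))

# ---------------------------------------------------------------------------
# Pulse extraction
# ---------------------------------------------------------------------------

#' Blood-volume-pulse trace of one patch
#'
#' The spatially averaged green-channel time series of a (magnified) patch
#' video, in arbitrary intensity units.
#'
#' @slot values real time series.
#' @slot fps sampling rate, Hz.
#' @export
setClass("BvpTrace",
  representation(values = "numeric", fps = "numeric"),
  validity = function(object) {
    if (length(object@values) < 1L) return("trace must be non-empty")
    if (!all(is.finite(object@values))) return("trace must be finite")
    if (object@fps <= 0) return("fps must be positive")
    TRUE
  }
)

#' @rdname BvpTrace-class
#' @param values numeric time series.
#' @param fps sampling rate, Hz.
#' @export
bvpTrace <- function(values, fps) {
  new("BvpTrace", values = as.numeric(values), fps = as.numeric(fps))
}

#' Per-second instantaneous heart-rate series
#'
#' One heart-rate value (BPM) per sliding-window position. Windows are
#' indexed by their start second: \code{times[i]} is the start of the i-th
#' window \code{[times[i], times[i] + windowS)}, with the first value at
#' time 0 once a full window of data exists.
#'
#' @slot times window start times, seconds, spaced \code{stepS}.
#' @slot values heart rates, BPM (NA marks seconds without consensus).
#' @slot windowS window length, seconds (default 60).
#' @slot stepS slide step, seconds (default 1).
#' @export
setClass("HRSeries",
  representation(times = "numeric", values = "numeric",
                 windowS = "numeric", stepS = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@values))
      return("times and values must have equal length")
    if (any(object@values < 0, na.rm = TRUE)) return("HR must be >= 0")
    if (length(object@times) > 1L) {
      dt <- diff(object@times)
      if (any(abs(dt - object@stepS) > 1e-9))
        return("times must increase with spacing stepS")
    }
    TRUE
  }
)

#' @rdname HRSeries-class
#' @param times window start times, seconds.
#' @param values BPM values.
#' @param windowS,stepS window length and slide step, seconds.
#' @export
hrSeries <- function(times, values, windowS = 60, stepS = 1) {
  new("HRSeries", times = as.numeric(times), values = as.numeric(values),
      windowS = windowS, stepS = stepS)
}

#' Peak-detection configuration
#'
#' @slot minSeparationS minimum distance between accepted peaks, seconds.
#'   Default 0.30 s = 80% of the beat period at the 160 BPM band edge,
#'   which forbids double-counting anywhere inside the passband.
#' @slot prominenceFactor peaks must have topographic prominence of at
#'   least this multiple of the trace standard deviation (default 0.5).
#' @slot detrend linearly detrend the trace before detection (default TRUE).
#' @export
setClass("PeakConfig",
  representation(minSeparationS = "numeric", prominenceFactor = "numeric",
                 detrend = "logical"),
  validity = function(object) {
    if (object@minSeparationS <= 0) return("minSeparationS must be > 0")
    if (object@prominenceFactor < 0) return("prominenceFactor must be >= 0")
    TRUE
  }
)

#' @rdname PeakConfig-class
#' @param minSeparationS minimum peak separation, seconds.
#' @param prominenceFactor prominence threshold as a multiple of trace SD.
#' @param detrend linearly detrend before detection.
#' @export
peakConfig <- function(minSeparationS = 60 / 160 * 0.8,
                       prominenceFactor = 0.5, detrend = TRUE) {
  new("PeakConfig", minSeparationS = minSeparationS,
      prominenceFactor = prominenceFactor, detrend = detrend)
}

# ---------------------------------------------------------------------------
# Voting
# ---------------------------------------------------------------------------

#' Majority-voting configuration
#'
#' Histogram bins are left-closed right-open, aligned at \code{hrMin} and
#' exactly tiling \code{[hrMin, hrMax)}. The default 5 BPM bins over
#' [100, 170] cover the 110-160 BPM passband with margin. Values outside
#' the range are excluded from voting. \code{binValue} selects whether the
#' vote returns the mean of the modal bin's members (default) or the bin
#' midpoint. Ties between equally populated bins are broken towards the
#' previous voted estimate; at the first time point the lower bin wins.
#'
#' @slot binWidth bin width, BPM.
#' @slot hrMin,hrMax voting range, BPM.
#' @slot binValue \code{"member_mean"} or \code{"midpoint"}.
#' @export
setClass("VoteConfig",
  representation(binWidth = "numeric", hrMin = "numeric", hrMax = "numeric",
                 binValue = "character"),
  validity = function(object) {
    if (object@binWidth <= 0) return("binWidth must be > 0")
    if (object@hrMin >= object@hrMax) return("hrMin must be < hrMax")
    nb <- (object@hrMax - object@hrMin) / object@binWidth
    if (abs(nb - round(nb)) > 1e-9)
      return("bins must exactly tile [hrMin, hrMax]")
    if (!object@binValue %in% c("member_mean", "midpoint"))
      return("binValue must be 'member_mean' or 'midpoint'")
    TRUE
  }
)

#' @rdname VoteConfig-class
#' @param binWidth histogram bin width, BPM.
#' @param hrMin,hrMax voting range, BPM.
#' @param binValue "member_mean" or "midpoint".
#' @export
voteConfig <- function(binWidth = 5, hrMin = 100, hrMax = 170,
                       binValue = "member_mean") {
  new("VoteConfig", binWidth = binWidth, hrMin = hrMin, hrMax = hrMax,
      binValue = binValue)
}

# ---------------------------------------------------------------------------
# Metrics
# ---------------------------------------------------------------------------

#' Agreement metrics between estimated and reference heart rate
#'
#' MAE = mean |He - Hr|; MRE = mean |He - Hr| / Hr x 100%;
#' RMSE = sqrt(mean (He - Hr)^2); SD = population standard deviation of the
#' error He - Hr about its mean mu.
#'
#' @slot mae,rmse,sd,mu BPM; \code{mre} percent; \code{n} compared seconds.
#' @export
setClass("MetricsReport",
  representation(mae = "numeric", mre = "numeric", rmse = "numeric",
                 sd = "numeric", mu = "numeric", n = "integer"))

#' Bland-Altman agreement statistics
#'
#' @slot bias mean difference He - Hr, BPM.
#' @slot sdDiff standard deviation of the differences, BPM.
#' @slot loaLo,loaHi 95% limits of agreement, bias -/+ 1.96 sdDiff.
#' @export
setClass("BlandAltman",
  representation(bias = "numeric", sdDiff = "numeric",
                 loaLo = "numeric", loaHi = "numeric"))

# ---------------------------------------------------------------------------
# Synthetic generator
# ---------------------------------------------------------------------------

#' Specification of a synthetic neonatal-face video
#'
#' Emulates the measurement situation: a skin-colored elliptical face on a
#' non-skin (mid-blue) background whose face pixels carry a small additive
#' periodic green-channel modulation locked to known beat times, plus
#' per-pixel sensor noise, optional rotation and optional corruption of a
#' fraction of grid cells (the motion-artifact model).
#'
#' @slot durationS clip length, seconds.
#' @slot fps frame rate, Hz (default 30, the recording rate).
#' @slot height,width frame size, pixels (default 480 x 640).
#' @slot faceCenter (row, col) ellipse center; NA = frame center.
#' @slot faceAxes (semi-row, semi-col) axes; NA = (0.35 H, 0.28 W).
#' @slot skinRgb base skin color; its HSV lies inside the skin bounds.
#' @slot backgroundRgb background color; HSV far outside the bounds.
#' @slot pulseAmp additive green amplitude, 8-bit units (default 1.5).
#' @slot hrBpm constant BPM, or a 2-column (time_s, bpm) matrix defining a
#'   piecewise-linear profile; must stay within the 110-160 passband.
#' @slot noiseSd per-pixel Gaussian noise SD, 8-bit units (default 2).
#' @slot motion list: \code{list(type = "none")},
#'   \code{list(type = "rotation", degPerS =)}, or
#'   \code{list(type = "patch_corruption", fraction =, amplitude = 40,
#'   divisions = 8)}.
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   frames.
#' @export
setClass("SyntheticSpec",
  representation(durationS = "numeric", fps = "numeric",
                 height = "integer", width = "integer",
                 faceCenter = "numeric", faceAxes = "numeric",
                 skinRgb = "numeric", backgroundRgb = "numeric",
                 pulseAmp = "numeric", hrBpm = "ANY", noiseSd = "numeric",
                 motion = "list", seed = "integer"),
  validity = function(object) {
    if (object@durationS <= 0 || object@fps <= 0)
      return("duration and fps must be positive")
    hr <- object@hrBpm
    bpm <- if (is.matrix(hr)) hr[, 2] else hr
    if (any(bpm <= 0)) return("hr profile must be positive")
    if (!object@motion$type %in% c("none", "rotation", "patch_corruption"))
      return("unknown motion type")
    TRUE
  }
)

#' @rdname SyntheticSpec-class
#' @param durationS,fps,height,width,faceCenter,faceAxes,skinRgb,backgroundRgb
#'   see slots.
#' @param pulseAmp,hrBpm,noiseSd,motion,seed see slots.
#' @export
syntheticSpec <- function(durationS = 90, fps = 30, height = 480L,
                          width = 640L, faceCenter = NA_real_,
                          faceAxes = NA_real_,
                          skinRgb = c(180, 120, 90),
                          backgroundRgb = c(30, 40, 160),
                          pulseAmp = 1.5, hrBpm = 140, noiseSd = 2,
                          motion = list(type = "none"), seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (anyNA(faceCenter)) faceCenter <- c(height / 2, width / 2)
  if (anyNA(faceAxes)) faceAxes <- c(0.35 * height, 0.28 * width)
  new("SyntheticSpec", durationS = durationS, fps = fps, height = height,
      width = width, faceCenter = faceCenter, faceAxes = faceAxes,
      skinRgb = skinRgb, backgroundRgb = backgroundRgb, pulseAmp = pulseAmp,
      hrBpm = hrBpm, noiseSd = noiseSd, motion = motion,
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Pipeline
# ---------------------------------------------------------------------------

#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations. The defaults reproduce the reference
#' operating point: skin bounds (0,10,60)-(20,150,255), 5x5 disc morphology,
#' d = 8 grid (patch size 1/64 of the frame), alpha = 150 over the
#' 1.8333-2.6667 Hz band, 60 s windows sliding by 1 s, 5 BPM voting bins
#' over [100, 170].
#'
#' @slot bounds \linkS4class{HsvBounds}.
#' @slot morph \linkS4class{MorphConfig}.
#' @slot divisions grid cuts per dimension.
#' @slot evm \linkS4class{EVMConfig}.
#' @slot peak \linkS4class{PeakConfig}.
#' @slot vote \linkS4class{VoteConfig}.
#' @slot windowS,stepS HR window length and slide, seconds.
#' @export
setClass("PipelineConfig",
  representation(bounds = "HsvBounds", morph = "MorphConfig",
                 divisions = "integer", evm = "EVMConfig",
                 peak = "PeakConfig", vote = "VoteConfig",
                 windowS = "numeric", stepS = "numeric"),
  validity = function(object) {
    if (object@divisions < 1L) return("divisions must be >= 1")
    if (object@windowS <= 0 || object@stepS <= 0)
      return("windowS and stepS must be positive")
    TRUE
  }
)

#' @rdname PipelineConfig-class
#' @param bounds,morph,divisions,evm,peak,vote,windowS,stepS see slots.
#' @export
pipelineConfig <- function(bounds = hsvBounds(), morph = morphConfig(),
                           divisions = 8L, evm = evmConfig(),
                           peak = peakConfig(), vote = voteConfig(),
                           windowS = 60, stepS = 1) {
  new("PipelineConfig", bounds = bounds, morph = morph,
      divisions = as.integer(divisions), evm = evm, peak = peak,
      vote = vote, windowS = windowS, stepS = stepS)
}

#' Result of a full pipeline run
#'
#' @slot hr the voted \linkS4class{HRSeries}.
#' @slot perPatch list of per-patch \linkS4class{HRSeries}.
#' @slot regions list of retained \linkS4class{PatchRegion}.
#' @slot diagnostics list: retained-patch count, per-stage timings
#'   (seconds), per-second vote bin counts, carried-forward seconds.
#' @export
setClass("PipelineResult",
  representation(hr = "HRSeries", perPatch = "list", regions = "list",
                 diagnostics = "list"))
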