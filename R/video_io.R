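# Video and CSV input/output.
#
# Video is carried in RIFF/AVI containers with uncompressed 24-bit RGB
# frames ('DIB '/BI_RGB). Uncompressed AVI is lossless, so write -> read is
# the identity on pixels and fps, which is what test fixtures and synthetic
# ground-truth clips require. Compressed payloads (MJPEG, H.264, ...) are
# rejected with a clear error; decode such material to uncompressed AVI
# externally (e.g. ffmpeg -c:v rawvideo -pix_fmt bgr24) before loading.

.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                             endian = "little")
.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                             endian = "little")

.readU32 <- function(raw, off) {   # off: 0-based byte offset
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4L, endian = "little")
}

.readU16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}

.fourcc <- function(raw, off) rawToChar(raw[(off + 1):(off + 4)])

.chunk <- function(id, payload) {
  n <- length(payload)
  c(charToRaw(id), .u32(n), payload, if (n %% 2L) as.raw(0L))
}

.list <- function(type, payload) .chunk("LIST", c(charToRaw(type), payload))

# One frame as bottom-up, BGR, 4-byte-aligned rows (the BI_RGB layout).
.frameToDib <- function(fr) {
  h <- dim(fr)[1]; w <- dim(fr)[2]
  v <- aperm(fr[h:1, , 3:1, drop = FALSE], c(3L, 2L, 1L))  # BGR, col, row
  bytes <- as.raw(pmin(pmax(round(as.vector(v)), 0), 255))
  pad <- (4L - (w * 3L) %% 4L) %% 4L
  if (pad > 0L) {
    m <- matrix(bytes, nrow = w * 3L)
    bytes <- as.vector(rbind(m, matrix(as.raw(0L), pad, h)))
  }
  bytes
}

.dibToFrame <- function(bytes, h, w) {
  pad <- (4L - (w * 3L) %% 4L) %% 4L
  v <- as.integer(bytes)
  if (pad > 0L) {
    m <- matrix(v, nrow = w * 3L + pad)
    v <- as.vector(m[seq_len(w * 3L), , drop = FALSE])
  }
  a <- array(v, dim = c(3L, w, h))          # BGR, col, row (bottom-up)
  aperm(a, c(3L, 2L, 1L))[h:1, , 3:1, drop = FALSE]
}

#' Write a FrameSequence as an uncompressed AVI file
#'
#' Frames are rounded, clipped to [0, 255] and stored as uncompressed
#' 24-bit RGB, so reading the file back recovers the 8-bit pixel values
#' exactly (lossless round-trip).
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVideo <- function(seq, path) {
  stopifnot(is(seq, "FrameSequence"))
  d <- dim(seq@frames)
  h <- d[1]; w <- d[2]; nT <- d[4]
  frameBytes <- h * (w * 3L + (4L - (w * 3L) %% 4L) %% 4L)

  scale <- 1000L
  rate <- as.integer(round(seq@fps * 1000))

  avih <- c(.u32(round(1e6 / seq@fps)),      # dwMicroSecPerFrame
            .u32(frameBytes * as.integer(round(seq@fps))),
            .u32(0L), .u32(0x10L),           # padding, flags: HASINDEX
            .u32(nT), .u32(0L), .u32(1L),    # totalframes, initial, streams
            .u32(frameBytes), .u32(w), .u32(h),
            .u32(0L), .u32(0L), .u32(0L), .u32(0L))
  strh <- c(charToRaw("vids"), charToRaw("DIB "),
            .u32(0L), .u16(0L), .u16(0L), .u32(0L),
            .u32(scale), .u32(rate), .u32(0L), .u32(nT),
            .u32(frameBytes), .u32(-1L), .u32(0L),
            .u16(0L), .u16(0L), .u16(w), .u16(h))
  strf <- c(.u32(40L), .u32(w), .u32(h), .u16(1L), .u16(24L),
            .u32(0L),                        # biCompression = BI_RGB
            .u32(frameBytes), .u32(0L), .u32(0L), .u32(0L), .u32(0L))

  hdrl <- .list("hdrl", c(.chunk("avih", avih),
                          .list("strl", c(.chunk("strh", strh),
                                          .chunk("strf", strf)))))

  frameChunks <- vector("list", nT)
  idx <- vector("list", nT)
  off <- 4L                                  # past the 'movi' fourcc
  for (t in seq_len(nT)) {
    payload <- .frameToDib(seq@frames[, , , t, drop = FALSE][, , , 1])
    frameChunks[[t]] <- .chunk("00db", payload)
    idx[[t]] <- c(charToRaw("00db"), .u32(0x10L), .u32(off),
                  .u32(length(payload)))
    off <- off + 8L + length(payload) + (length(payload) %% 2L)
  }
  movi <- .list("movi", do.call(c, frameChunks))
  idx1 <- .chunk("idx1", do.call(c, idx))

  body <- c(charToRaw("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("RIFF"), .u32(length(body)), body), con)
  invisible(path)
}

# Walk the subchunks of a RIFF list; returns list of (id, start, size) with
# start the 0-based offset of the payload.
.riffChildren <- function(raw, start, end) {
  out <- list()
  p <- start
  while (p + 8L <= end) {
    id <- .fourcc(raw, p)
    size <- .readU32(raw, p + 4L)
    out[[length(out) + 1L]] <- list(id = id, start = p + 8L, size = size,
      type = if (id %in% c("RIFF", "LIST")) .fourcc(raw, p + 8L) else NULL)
    p <- p + 8L + size + (size %% 2L)
  }
  out
}

#' Read an uncompressed AVI file into a FrameSequence
#'
#' Parses the RIFF/AVI container and decodes uncompressed 24-bit RGB
#' ('DIB ') frames; the frame rate is taken from the stream header.
#' Compressed video streams are rejected.
#'
#' @param path path to an AVI file.
#' @return A \linkS4class{FrameSequence} with integer 8-bit frames.
#' @export
readVideo <- function(path) {
  if (!file.exists(path)) stop("cannot read video: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 12L || .fourcc(raw, 0L) != "RIFF" ||
      .fourcc(raw, 8L) != "AVI ")
    stop("not a RIFF/AVI file: ", path)

  top <- .riffChildren(raw, 12L, length(raw))
  hdrl <- Filter(function(x) identical(x$type, "hdrl"), top)
  movi <- Filter(function(x) identical(x$type, "movi"), top)
  if (!length(hdrl) || !length(movi)) stop("malformed AVI: ", path)

  h1 <- hdrl[[1]]
  kids <- .riffChildren(raw, h1$start + 4L, h1$start + h1$size)
  avih <- Filter(function(x) x$id == "avih", kids)[[1]]
  w <- .readU32(raw, avih$start + 32L)
  h <- .readU32(raw, avih$start + 36L)

  strl <- Filter(function(x) identical(x$type, "strl"), kids)[[1]]
  skids <- .riffChildren(raw, strl$start + 4L, strl$start + strl$size)
  strh <- Filter(function(x) x$id == "strh", skids)[[1]]
  strf <- Filter(function(x) x$id == "strf", skids)[[1]]
  scale <- .readU32(raw, strh$start + 20L)
  rate <- .readU32(raw, strh$start + 24L)
  fps <- rate / scale
  bitCount <- .readU16(raw, strf$start + 14L)
  compression <- .readU32(raw, strf$start + 16L)
  if (compression != 0L || bitCount != 24L)
    stop("unsupported codec: only uncompressed 24-bit RGB AVI is readable ",
         "(biCompression=", compression, ", bitCount=", bitCount, ")")

  m1 <- movi[[1]]
  chunks <- .riffChildren(raw, m1$start + 4L, m1$start + m1$size)
  vid <- Filter(function(x) x$id %in% c("00db", "00dc"), chunks)
  if (!length(vid)) stop("empty video: no frames in ", path)

  arr <- array(0L, dim = c(h, w, 3L, length(vid)))
  for (t in seq_along(vid)) {
    ch <- vid[[t]]
    arr[, , , t] <- .dibToFrame(raw[(ch$start + 1):(ch$start + ch$size)],
                                h, w)
  }
  frameSequence(arr, fps)
}

#' Read and write reference beat times
#'
#' Beat timestamps (the ground-truth substitute for ECG R-peaks) are stored
#' as a headered single-column CSV, \code{beat_time_s}.
#'
#' @param path CSV file path.
#' @return \code{readBeats}: numeric vector of beat times in seconds.
#' @export
readBeats <- function(path) {
  df <- utils::read.csv(path)
  if (!"beat_time_s" %in% names(df))
    stop("beats CSV must have a 'beat_time_s' column")
  as.numeric(df$beat_time_s)
}

#' @rdname readBeats
#' @param beats numeric vector of beat times, seconds.
#' @export
writeBeats <- function(beats, path) {
  utils::write.csv(data.frame(beat_time_s = beats), path, row.names = FALSE)
  invisible(path)
}

#' Read and write heart-rate series
#'
#' HR series are stored as headered CSV with columns \code{time_s}
#' (window start, seconds) and \code{hr_bpm}.
#'
#' @param path CSV file path.
#' @param windowS,stepS window metadata to attach on read.
#' @return \code{readHRSeries}: an \linkS4class{HRSeries}.
#' @export
readHRSeries <- function(path, windowS = 60, stepS = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "hr_bpm") %in% names(df)))
    stop("HR CSV must have 'time_s' and 'hr_bpm' columns")
  if (is.null(stepS))
    stepS <- if (nrow(df) > 1L) df$time_s[2] - df$time_s[1] else 1
  hrSeries(df$time_s, df$hr_bpm, windowS = windowS, stepS = stepS)
}

#' @rdname readHRSeries
#' @param hr an \linkS4class{HRSeries}.
#' @export
writeHRSeries <- function(hr, path) {
  stopifnot(is(hr, "HRSeries"))
  utils::write.csv(data.frame(time_s = hr@times, hr_bpm = hr@values),
                   path, row.names = FALSE)
  invisible(path)
}
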