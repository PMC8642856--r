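# Histogram majority voting across patches.
#
# At each second every retained patch contributes one candidate HR value.
# A histogram over the voting range is drawn and the mean of the values in
# the most populated bin is reported. Patches disturbed by motion vote for
# scattered rates and, as long as motion covers only a small part of the
# face, are statistically unlikely to win the modal bin.

# Single-instant vote; returns value + bin counts (internal).
.voteOnce <- function(values, cfg, prev = NULL) {
  lo <- cfg@hrMin; hi <- cfg@hrMax; bw <- cfg@binWidth
  nb <- as.integer(round((hi - lo) / bw))
  inRange <- values[values >= lo & values < hi]
  counts <- integer(nb)
  if (!length(inRange)) {
    return(list(value = NA_real_, counts = counts, consensus = FALSE))
  }
  bins <- pmin(floor((inRange - lo) / bw) + 1L, nb)
  counts <- tabulate(bins, nbins = nb)
  modal <- which(counts == max(counts))
  if (length(modal) > 1L) {
    means <- vapply(modal, function(b) mean(inRange[bins == b]), numeric(1))
    modal <- if (!is.null(prev) && is.finite(prev)) {
      modal[which.min(abs(means - prev))]   # temporal continuity
    } else {
      modal[1L]                             # lower bin at the first instant
    }
  }
  members <- inRange[bins == modal]
  value <- switch(cfg@binValue,
    member_mean = mean(members),
    midpoint = lo + (modal - 0.5) * bw)
  list(value = value, counts = counts, consensus = TRUE)
}

#' Majority vote over one instant's candidate heart rates
#'
#' Bins the in-range values into left-closed right-open bins of width
#' \code{binWidth} aligned at \code{hrMin} and returns the arithmetic mean
#' of the values falling in the most populated bin (or the bin midpoint if
#' \code{binValue = "midpoint"}). Ties between equally full bins go to the
#' bin whose member mean is closest to \code{prev}; with no previous
#' estimate the lower bin wins. Values outside \code{[hrMin, hrMax)} are
#' excluded rather than clamped.
#'
#' @param values candidate HR values, BPM (one per patch).
#' @param cfg a \linkS4class{VoteConfig}.
#' @param prev previous voted HR for tie-breaking, or NULL.
#' @return the voted HR, BPM.
#' @examples
#' # 50 clean patches near 140 BPM outvote 14 motion-corrupted ones
#' vote(c(rnorm(50, 140, 1), runif(14, 100, 170)))
#' @export
vote <- function(values, cfg = voteConfig(), prev = NULL) {
  stopifnot(is(cfg, "VoteConfig"))
  r <- .voteOnce(values, cfg, prev)
  if (!r$consensus)
    stop("no consensus: no candidate HR inside [hrMin, hrMax)")
  r$value
}

#' Majority vote across per-patch heart-rate series
#'
#' Element-wise vote at each time index across all patch series, which
#' must share their time grid. Seconds where no patch votes in range carry
#' the previous voted value forward (NA before any consensus exists); the
#' affected indices are returned in the \code{noConsensus} attribute, and
#' the full per-second bin-count matrix in \code{binCounts}.
#'
#' @param perPatch list of \linkS4class{HRSeries}, one per patch.
#' @param cfg a \linkS4class{VoteConfig}.
#' @return an \linkS4class{HRSeries} with attributes \code{noConsensus}
#'   (integer indices) and \code{binCounts} (bins x time matrix).
#' @export
voteSeries <- function(perPatch, cfg = voteConfig()) {
  stopifnot(length(perPatch) >= 1L,
            all(vapply(perPatch, is, logical(1), "HRSeries")))
  t0 <- perPatch[[1]]@times
  for (s in perPatch)
    if (length(s@times) != length(t0) || any(abs(s@times - t0) > 1e-9))
      stop("per-patch series are not aligned on the same time grid")

  vals <- vapply(perPatch, function(s) s@values, numeric(length(t0)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)  # single instant
  nb <- as.integer(round((cfg@hrMax - cfg@hrMin) / cfg@binWidth))
  out <- numeric(length(t0))
  counts <- matrix(0L, nb, length(t0))
  noCons <- integer(0)
  prev <- NULL
  for (i in seq_along(t0)) {
    r <- .voteOnce(vals[i, ], cfg, prev)
    counts[, i] <- r$counts
    if (r$consensus) {
      out[i] <- r$value
      prev <- r$value
    } else {
      out[i] <- if (is.null(prev)) NA_real_ else prev
      noCons <- c(noCons, i)
    }
  }
  res <- hrSeries(t0, out, windowS = perPatch[[1]]@windowS,
                  stepS = perPatch[[1]]@stepS)
  attr(res, "noConsensus") <- noCons
  attr(res, "binCounts") <- counts
  res
}
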