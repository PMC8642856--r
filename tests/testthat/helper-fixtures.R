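# Shared fixtures, built in code at test time.

# A small uniform-color video: every pixel rgb, optional additive green
# modulation g(t).
uniformVideo <- function(h, w, nT, fps, rgb = c(100, 100, 100),
                         greenMod = rep(0, nT)) {
  arr <- array(0, dim = c(h, w, 3L, nT))
  for (ch in 1:3) arr[, , ch, ] <- rgb[ch]
  for (t in seq_len(nT)) arr[, , 2, t] <- rgb[2] + greenMod[t]
  frameSequence(arr, fps)
}

# Default small synthetic face clip (60 x 80) for mid-weight tests.
smallFaceSpec <- function(durationS, hrBpm = 140, seed = 5L, ...) {
  syntheticSpec(durationS = durationS, fps = 30, height = 60L, width = 80L,
                hrBpm = hrBpm, seed = seed, ...)
}

# Brute-force morphology oracle: erosion keeps a pixel iff every in-bounds
# kernel neighbor is foreground; dilation sets a pixel iff any in-bounds
# neighbor is foreground (out-of-bounds ignored, matching the package's
# border convention).
bruteErode <- function(m, k) {
  ch <- (nrow(k) + 1L) / 2L; cw <- (ncol(k) + 1L) / 2L
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ok <- TRUE
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      ii <- i + a - ch; jj <- j + b - cw
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          !m[ii, jj]) ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

bruteDilate <- function(m, k) {
  ch <- (nrow(k) + 1L) / 2L; cw <- (ncol(k) + 1L) / 2L
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    any1 <- FALSE
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      ii <- i + a - ch; jj <- j + b - cw
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          m[ii, jj]) any1 <- TRUE
    }
    out[i, j] <- any1
  }
  out
}

# Brute-force histogram vote oracle: count every bin explicitly, return the
# mean of the members of the fullest bin (lowest bin on ties).
bruteVote <- function(values, binWidth, hrMin, hrMax) {
  edges <- seq(hrMin, hrMax, by = binWidth)
  best <- -1L; bestMean <- NA_real_
  for (b in seq_len(length(edges) - 1L)) {
    members <- values[values >= edges[b] & values < edges[b + 1L]]
    if (length(members) > best) {
      best <- length(members)
      bestMean <- mean(members)
    }
  }
  if (best < 1L) stop("no in-range values")
  bestMean
}
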