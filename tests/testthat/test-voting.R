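test_that("unanimous and single-value votes are the identity", {
  cfg <- voteConfig()
  expect_equal(vote(rep(140, 64), cfg), 140)
  expect_equal(vote(123.4, cfg), 123.4)
  expect_error(vote(c(20, 500), cfg), "consensus")
})

test_that("the vote matches a brute-force histogram oracle", {
  set.seed(50)
  # clustered + scattered values, bins of 5 aligned at 110
  cfg <- voteConfig(binWidth = 5, hrMin = 110, hrMax = 170)
  vals <- c(stats::runif(40, 138, 142), stats::runif(24, 110, 135))
  expect_equal(vote(vals, cfg), bruteVote(vals, 5, 110, 170))

  # random instances, default config
  cfg2 <- voteConfig()
  for (rep in 1:25) {
    vals <- stats::runif(sample(5:80, 1), 95, 175)
    vals <- vals[vals >= 100 & vals < 170]
    if (!length(vals)) next
    got <- vote(vals, cfg2)
    # oracle ties go to the lower bin, like vote() with no previous value
    expect_equal(got, bruteVote(vals, 5, 100, 170))
  }
})

test_that("ties break towards the previous estimate, else the lower bin", {
  cfg <- voteConfig()
  vals <- c(121, 122, 141, 142)          # bins [120,125) and [140,145) tied
  expect_equal(vote(vals, cfg), mean(c(121, 122)))              # no prev
  expect_equal(vote(vals, cfg, prev = 139), mean(c(141, 142)))  # near prev
  expect_equal(vote(vals, cfg, prev = 125), mean(c(121, 122)))
})

test_that("the vote is permutation invariant and lies inside the modal bin", {
  set.seed(51)
  cfg <- voteConfig()
  for (rep in 1:10) {
    vals <- stats::runif(30, 105, 165)
    expect_equal(vote(vals, cfg), vote(sample(vals), cfg))
    v <- vote(vals, cfg)
    bin <- floor((v - 100) / 5)
    members <- vals[floor((vals - 100) / 5) == bin]
    expect_gte(v, min(members))
    expect_lte(v, max(members))
  }
})

test_that("a strict majority bin always pulls the vote within one bin of truth", {
  # exhaustive small-case enumeration: n = 5 values on a coarse grid
  cfg <- voteConfig(binWidth = 5, hrMin = 100, hrMax = 130)
  grid <- c(101, 103, 112, 118, 121, 127)
  combos <- expand.grid(rep(list(grid), 5))
  for (i in seq_len(nrow(combos))) {
    vals <- as.numeric(combos[i, ])
    bins <- floor((vals - 100) / 5)
    counts <- table(bins)
    top <- counts[counts == max(counts)]
    if (length(top) > 1L) next                   # no strict winner
    truthBin <- as.integer(names(top))
    v <- vote(vals, cfg)
    binLo <- 100 + truthBin * 5
    expect_gte(v, binLo); expect_lt(v, binLo + 5)
  }
})

test_that("series voting is element-wise and robust to corrupted patches", {
  cfg <- voteConfig()
  mk <- function(vals) hrSeries(0:(length(vals) - 1), vals)
  s <- mk(c(140, 141, 139, 140))
  expect_equal(hrValues(voteSeries(list(s, s, s), cfg)), hrValues(s))
  expect_equal(hrValues(voteSeries(list(s), cfg)), hrValues(s))
  expect_error(voteSeries(list(s, mk(c(1, 2, 3))), cfg), "aligned")

  # 70% of patches at ~140, 30% corrupted to uniform [110, 160]
  set.seed(52)
  nPatch <- 20; nT <- 40
  series <- lapply(seq_len(nPatch), function(p) {
    vals <- if (p <= 14) 140 + stats::runif(nT, -1, 1)
            else stats::runif(nT, 110, 160)
    hrSeries(0:(nT - 1), vals)
  })
  out <- voteSeries(series, cfg)
  expect_true(all(abs(hrValues(out) - 140) <= 5))
})

test_that("no-consensus seconds carry the last vote forward and are flagged", {
  cfg <- voteConfig()
  a <- hrSeries(0:2, c(140, 20, 141))    # second 1: out of range everywhere
  b <- hrSeries(0:2, c(139, 30, 140))
  out <- voteSeries(list(a, b), cfg)
  expect_equal(attr(out, "noConsensus"), 2L)
  expect_equal(hrValues(out)[2], hrValues(out)[1])
  expect_equal(dim(attr(out, "binCounts")), c(14, 3))
})
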