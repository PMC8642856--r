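# Agreement metrics between estimated (He) and reference (Hr) heart rate.

.alignedDiff <- function(he, hr) {
  stopifnot(is(he, "HRSeries"), is(hr, "HRSeries"))
  if (length(he@values) != length(hr@values))
    stop("series lengths differ")
  if (any(abs(he@times - hr@times) > 1e-9))
    stop("series are not aligned on the same time grid")
  he@values - hr@values
}

#' Error metrics between estimated and reference HR
#'
#' With e(i) = He(i) - Hr(i) over N aligned seconds:
#' MAE = mean |e|; MRE = mean |e / Hr| x 100%; RMSE = sqrt(mean e^2);
#' SD = sqrt(mean (e - mu)^2) with mu = mean e. The SD uses the population
#' form (1/N inside the root), as the metric definitions state it.
#'
#' @param he estimated \linkS4class{HRSeries}.
#' @param hr reference \linkS4class{HRSeries}, aligned with \code{he};
#'   every Hr(i) must be nonzero for the MRE to be defined.
#' @return a \linkS4class{MetricsReport}.
#' @export
computeMetrics <- function(he, hr) {
  e <- .alignedDiff(he, hr)
  n <- length(e)
  if (n < 1L) stop("need at least one compared second")
  if (any(hr@values == 0))
    stop("MRE undefined: reference HR contains zeros")
  mu <- mean(e)
  new("MetricsReport",
      mae = mean(abs(e)),
      mre = mean(abs(e / hr@values)) * 100,
      rmse = sqrt(mean(e^2)),
      sd = sqrt(mean((e - mu)^2)),
      mu = mu,
      n = as.integer(n))
}

#' Bland-Altman agreement statistics
#'
#' Bias = mean difference He - Hr; 95% limits of agreement =
#' bias +/- 1.96 x SD of the differences. The SD convention defaults to
#' the same population form as \code{\link{computeMetrics}}; a sample-SD
#' (1/(N-1)) option is available.
#'
#' @inheritParams computeMetrics
#' @param sdType \code{"population"} (default) or \code{"sample"}.
#' @return a \linkS4class{BlandAltman}.
#' @export
blandAltman <- function(he, hr, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  e <- .alignedDiff(he, hr)
  n <- length(e)
  if (n < 2L) stop("need at least two compared seconds")
  bias <- mean(e)
  sdDiff <- if (sdType == "population") {
    sqrt(mean((e - bias)^2))
  } else {
    stats::sd(e)
  }
  new("BlandAltman", bias = bias, sdDiff = sdDiff,
      loaLo = bias - 1.96 * sdDiff, loaHi = bias + 1.96 * sdDiff)
}

#' Bland-Altman plot
#'
#' Paired differences against paired means, with the bias and the 95%
#' limits of agreement as horizontal lines. Requires \pkg{ggplot2}.
#'
#' @inheritParams blandAltman
#' @return a ggplot object.
#' @export
plotBlandAltman <- function(he, hr, sdType = c("population", "sample")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotBlandAltman requires the ggplot2 package")
  ba <- blandAltman(he, hr, sdType)
  df <- data.frame(mean = (he@values + hr@values) / 2,
                   diff = he@values - hr@values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba@bias, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(ba@loaLo, ba@loaHi),
                        colour = "darkgreen") +
    ggplot2::labs(x = "Mean of He and Hr (BPM)",
                  y = "He - Hr (BPM)",
                  title = sprintf("Bias %.2f BPM, 95%% LoA [%.2f, %.2f]",
                                  ba@bias, ba@loaLo, ba@loaHi))
}
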