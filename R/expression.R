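#' Boxplot-outlier threshold (upper fence)
#'
#' `Q3 + 1.5 * IQR` with linear-interpolation (type-7) quantiles: the
#' classical upper boxplot fence used to flag highly enriched regions. With
#' a constant input the IQR is 0 and the fence equals the constant, so under
#' the strict-exceedance convention nothing is flagged.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return The fence value.
#' @examples
#' boxplotThreshold(c(1, 2, 3, 4, 100))  # Q1 = 2, Q3 = 4 -> 7
#' @export
boxplotThreshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4L) stop("need at least 4 finite values")
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Classify regions or genes into BT / B / T / loBT
#'
#' Applies the boxplot-outlier rule independently to the nucRNA and RNAPII
#' fold-enrichment scores: regions strictly above both fences are BT
#' (bound and transcribed), above only the RNAPII fence B, above only the
#' nucRNA fence T, and the rest loBT. Ties at a fence go to the low class.
#' For gene-level input, genes at or below `minGeneLength` are excluded
#' before the fences are computed.
#'
#' @param scored A `GRanges` (from [windowScores()] or [geneScores()]) or a
#'   data.frame with numeric columns `nucScore` and `polScore`; gene input
#'   should carry widths (GRanges) for the length filter.
#' @param minGeneLength Exclude regions of width <= this many bp before
#'   computing thresholds (default 300; set to 0 to keep everything).
#' @return A list with `thresholds` (named vector: `nucRNA`, `RNAPII`),
#'   `regions` (the retained input with added `label` and `ratio` =
#'   nucScore/polScore columns) and `excluded` (number removed by the
#'   length filter).
#' @export
classifyExpression <- function(scored, minGeneLength = 300) {
  isGR <- is(scored, "GRanges")
  nuc <- scored$nucScore
  pol <- scored$polScore
  if (is.null(nuc) || is.null(pol))
    stop("input must carry nucScore and polScore")
  if (length(nuc) == 0L) stop("empty score list")
  keep <- rep(TRUE, length(nuc))
  if (isGR && minGeneLength > 0)
    keep <- width(scored) > minGeneLength
  scored <- scored[keep]
  nuc <- nuc[keep]; pol <- pol[keep]
  if (any(!is.finite(nuc)) || any(!is.finite(pol)))
    stop("scores must be finite")
  thr <- c(nucRNA = boxplotThreshold(nuc), RNAPII = boxplotThreshold(pol))
  hiN <- nuc > thr["nucRNA"]
  hiP <- pol > thr["RNAPII"]
  label <- ifelse(hiN & hiP, "BT",
           ifelse(hiP, "B",
           ifelse(hiN, "T", "loBT")))
  scored$label <- label
  scored$ratio <- nuc / pol
  list(thresholds = thr, regions = scored, excluded = sum(!keep))
}

#' Per-class transcription-efficiency ratio
#'
#' The nucRNA:RNAPII score ratio summarises how much RNA a unit of
#' polymerase occupancy yields. Per class, the summary is a trimmed mean
#' ([trimmedMean()], ceiling rule) of the per-region ratios.
#'
#' @param classified Output of [classifyExpression()].
#' @param trim Fraction trimmed from each tail (default 0.05).
#' @return Named numeric vector of per-class trimmed-mean ratios (classes
#'   BT, B, T, loBT; `NA` for an empty class).
#' @export
efficiencyRatio <- function(classified, trim = 0.05) {
  regions <- classified$regions
  out <- vapply(c("BT", "B", "T", "loBT"), function(cl) {
    r <- regions$ratio[regions$label == cl]
    if (length(r) == 0L) NA_real_ else trimmedMean(r, trim)
  }, numeric(1))
  out
}
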