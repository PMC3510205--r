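#' Promoter-proximal and 3' end stalling indices
#'
#' The stalling index of a gene is the maximum input-normalised RNAPII
#' signal within +/-`flank` bp of the anchor (TSS for the promoter index,
#' TES for the 3' index) divided by the mean signal over the gene body,
#' where the body is the gene span minus *both* anchor windows (the
#' symmetric definition prevents a 3' peak from inflating the promoter
#' index's denominator, and vice versa). A high index indicates a polymerase
#' peak at that end; a uniform signal gives exactly 1.
#'
#' Genes with an empty body after removing the anchor windows, or shorter
#' than `minGeneLength`, are excluded with a reason code rather than
#' silently dropped.
#'
#' @param geneset A [GeneModelSet].
#' @param polTrack,inputTrack [CoverageTrack]s for RNAPII and genomic input.
#' @param nucTrack Optional nucRNA [CoverageTrack]; when given, body-level
#'   nucRNA signal and the nucRNA:RNAPII body ratio are included.
#' @param flank Half-width of the anchor windows in bp (default 300).
#' @param eps Pseudocount for the per-base enrichment track.
#' @param minGeneLength Genes at or below this span are excluded
#'   (default 300 bp).
#' @return A data.frame with one row per gene: `gene_id`, `promoterIndex`,
#'   `threePrimeIndex`, `bodyPolMean`, `bodyNucMean` (if `nucTrack`),
#'   `bodyRatio`, `excluded`, `reason`.
#' @export
stallingTable <- function(geneset, polTrack, inputTrack, nucTrack = NULL,
                          flank = 300, eps = 1, minGeneLength = 300) {
  fe <- enrichmentTrack(polTrack, inputTrack, eps)
  feNuc <- if (!is.null(nucTrack)) enrichmentTrack(nucTrack, inputTrack, eps)
  g <- genes(geneset)
  ids <- geneIds(geneset)
  tss <- tssPositions(geneset)
  tes <- tesPositions(geneset)
  n <- length(g)
  out <- data.frame(gene_id = ids,
                    promoterIndex = NA_real_, threePrimeIndex = NA_real_,
                    bodyPolMean = NA_real_, bodyNucMean = NA_real_,
                    bodyRatio = NA_real_,
                    excluded = FALSE, reason = "")
  for (i in seq_len(n)) {
    ch <- as.character(seqnames(g)[i])
    s <- start(g)[i]; e <- end(g)[i]
    if (e - s + 1L <= minGeneLength) {
      out$excluded[i] <- TRUE; out$reason[i] <- "short_gene"; next
    }
    r <- fe[[ch]]
    w5 <- IRanges(max(tss[i] - flank, 1L), min(tss[i] + flank, length(r)))
    w3 <- IRanges(max(tes[i] - flank, 1L), min(tes[i] + flank, length(r)))
    body <- setdiff(IRanges(s, e), union(w5, w3))
    if (sum(width(body)) == 0L) {
      out$excluded[i] <- TRUE; out$reason[i] <- "empty_body"; next
    }
    bodyMean <- sum(viewSums(Views(r, body))) / sum(width(body))
    if (bodyMean == 0) {
      out$excluded[i] <- TRUE; out$reason[i] <- "zero_body_signal"; next
    }
    out$promoterIndex[i] <- max(viewMaxs(Views(r, w5))) / bodyMean
    out$threePrimeIndex[i] <- max(viewMaxs(Views(r, w3))) / bodyMean
    out$bodyPolMean[i] <- bodyMean
    if (!is.null(feNuc)) {
      nb <- sum(viewSums(Views(feNuc[[ch]], body))) / sum(width(body))
      out$bodyNucMean[i] <- nb
      out$bodyRatio[i] <- nb / bodyMean
    }
  }
  out
}

#' Single-gene stalling index
#'
#' Convenience wrapper over [stallingTable()] for one end of one gene.
#'
#' @inheritParams stallingTable
#' @param end `"five_prime"` (promoter) or `"three_prime"`.
#' @return Numeric vector of indices named by gene_id (NA where excluded).
#' @export
stallingIndex <- function(geneset, polTrack, inputTrack,
                          end = c("five_prime", "three_prime"),
                          flank = 300, eps = 1) {
  end <- match.arg(end)
  tab <- stallingTable(geneset, polTrack, inputTrack, flank = flank,
                       eps = eps)
  v <- if (end == "five_prime") tab$promoterIndex else tab$threePrimeIndex
  stats::setNames(v, tab$gene_id)
}

#' Categorise genes by their RNAPII peak configuration
#'
#' Computes a percentile cutoff (default the 95th, type-7) for each index
#' over the genes with defined indices, then assigns: `double` when both
#' indices strictly exceed their cutoffs, `promoter` or `three_prime` when
#' only one does, `none` otherwise.
#'
#' @param records Output of [stallingTable()].
#' @param percentile Cutoff percentile (default 95).
#' @return `records` with an added `category` column plus attributes
#'   `cutoffs` (named vector) and `counts` (table of categories).
#' @export
categorizeStalling <- function(records, percentile = 95) {
  ok <- !records$excluded & is.finite(records$promoterIndex) &
        is.finite(records$threePrimeIndex)
  if (sum(ok) < 20L) stop("need at least 20 genes with defined indices")
  p <- percentile / 100
  cutP <- stats::quantile(records$promoterIndex[ok], p, type = 7,
                          names = FALSE)
  cut3 <- stats::quantile(records$threePrimeIndex[ok], p, type = 7,
                          names = FALSE)
  cat <- rep(NA_character_, nrow(records))
  hiP <- records$promoterIndex > cutP
  hi3 <- records$threePrimeIndex > cut3
  cat[ok] <- ifelse(hiP[ok] & hi3[ok], "double",
             ifelse(hiP[ok], "promoter",
             ifelse(hi3[ok], "three_prime", "none")))
  records$category <- cat
  attr(records, "cutoffs") <- c(promoter = cutP, three_prime = cut3)
  attr(records, "counts") <- table(factor(cat, levels = c("promoter",
                                                          "three_prime",
                                                          "double", "none")))
  records
}

#' Compare the RNA-per-polymerase body ratio across stalling categories
#'
#' Tests whether the nucRNA:RNAPII ratio over gene bodies (anchor windows
#' excluded) differs between the promoter, 3' end, double-peak and
#' no-peak categories, with the tie-corrected Kruskal-Wallis H and its
#' chi-square p-value. Empty categories are dropped with a warning.
#'
#' @param records Output of [categorizeStalling()] (with `bodyRatio`, i.e.
#'   [stallingTable()] must have been given the nucRNA track).
#' @return A list with `H`, `df`, `p`, per-category `medians` and `n`.
#' @export
bodyRatioTest <- function(records) {
  if (is.null(records$category)) stop("run categorizeStalling() first")
  ok <- !records$excluded & is.finite(records$bodyRatio) &
        !is.na(records$category)
  groups <- split(records$bodyRatio[ok], records$category[ok])
  empty <- setdiff(c("promoter", "three_prime", "double", "none"),
                   names(groups))
  if (length(empty))
    warning("empty categories dropped: ", paste(empty, collapse = ", "))
  if (length(groups) < 2L) stop("need at least 2 non-empty categories")
  kw <- kruskalWallisTest(groups)
  list(H = kw$H, df = kw$df, p = kw$p,
       medians = vapply(groups, stats::median, numeric(1)),
       n = lengths(groups))
}

#' Ordered-trend test of an outcome across stalling-index bins
#'
#' Bins genes by a stalling index into `nBins` ordered groups (quantile
#' bins) and applies the Jonckheere-Terpstra test to the outcome (typically
#' nucRNA coverage), by default one-sided for a decreasing trend — the
#' direction of the claim that highly stalled genes are less transcribed.
#'
#' @param indexValues Numeric stalling indices.
#' @param outcome Numeric outcome, parallel to `indexValues`.
#' @param nBins Number of ordered bins (default 5, quintiles).
#' @param alternative Passed to [jonckheereTest()]; default `"decreasing"`.
#' @return The [jonckheereTest()] result plus `binSizes`.
#' @export
trendTest <- function(indexValues, outcome, nBins = 5,
                      alternative = "decreasing") {
  ok <- is.finite(indexValues) & is.finite(outcome)
  iv <- indexValues[ok]; ov <- outcome[ok]
  br <- stats::quantile(iv, probs = seq(0, 1, length.out = nBins + 1),
                        type = 7)
  br <- unique(br)
  if (length(br) < 3L) stop("fewer than 2 non-empty bins")
  bins <- cut(iv, breaks = br, include.lowest = TRUE)
  groups <- split(ov, bins)
  groups <- groups[lengths(groups) > 0L]
  res <- jonckheereTest(groups, alternative = alternative)
  res$binSizes <- lengths(groups)
  res
}
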