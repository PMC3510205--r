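#' Call RNAPII summits from strand imbalance
#'
#' A minimal summit caller in the spirit of strand-imbalance methods for
#' short-tag ChIP-Seq: 5' tag positions are counted per strand in
#' `window`-bp bins and summed over a sliding `span`-bp window; a candidate
#' summit lies at a boundary where the windowed net count (forward minus
#' reverse) changes sign from positive to negative - the geometry produced
#' by tags flanking a protein-bound site, where forward tags accumulate
#' upstream and reverse tags downstream of the site. To suppress spurious
#' sign flips in diffuse strand-balanced coverage, the imbalance must be
#' significant (`|net| / sqrt(total) >= minZ`) somewhere within `span` on
#' each side of the crossing. Candidates are kept when the local tag count
#' exceeds a Poisson background (genome-average rate) at `p < pCut`;
#' summits closer than `span` are merged (strongest kept).
#'
#' Externally called peaks can be used instead anywhere a peak set is
#' consumed - every downstream function takes a plain `GRanges`.
#'
#' @param tags Stranded `GRanges` of RNAPII tags ('+'/'-'; unstranded input
#'   is an error - import externally-called peaks instead).
#' @param chromSizes Named chromosome lengths.
#' @param window Bin width in bp (default 20).
#' @param span Sliding-window width for the net count, in bp (default 160;
#'   rounded to a multiple of `window`).
#' @param pCut Poisson p-value threshold (default 0.001).
#' @param minZ Minimum strand-imbalance z required on each side of the
#'   summit (default 2.5).
#' @return A `GRanges` of peak intervals with metadata `summit` (bp),
#'   `score` (tag count within `span` of the summit) and `p`.
#' @export
callPeaks <- function(tags, chromSizes, window = 20, span = 160,
                      pCut = 0.001, minZ = 2.5) {
  .checkChromSizes(chromSizes)
  str <- as.character(strand(tags))
  if (length(tags) && all(str == "*"))
    stop("unstranded tags: summit calling needs strand; ",
         "import externally-called peaks as a GRanges instead")
  tags <- tags[str %in% c("+", "-")]
  str <- as.character(strand(tags))
  pos5 <- ifelse(str == "+", start(tags), end(tags))
  genomeLen <- sum(as.numeric(chromSizes))
  k <- max(1L, round(span / window))
  lambda <- length(tags) / genomeLen * (2 * k * window)

  # trailing running sum over k bins
  runsum <- function(x) {
    cx <- cumsum(x)
    cx - c(rep(0, k), utils::head(cx, -k))
  }
  # running max/min of x over the k previous (incl. current) / next bins
  lagmax <- function(x) {
    out <- x
    for (j in seq_len(k - 1L))
      out <- pmax(out, c(rep(-Inf, j), utils::head(x, -j)))
    out
  }
  leadmin <- function(x) {
    out <- x
    for (j in seq_len(k - 1L))
      out <- pmin(out, c(utils::tail(x, -j), rep(Inf, j)))
    out
  }

  res <- list()
  for (ch in names(chromSizes)) {
    sel <- as.character(seqnames(tags)) == ch
    if (!any(sel)) next
    p5 <- pos5[sel]; st <- str[sel]
    nb <- ceiling(chromSizes[[ch]] / window)
    bin <- pmin(pmax((p5 - 1L) %/% window + 1L, 1L), nb)
    f <- tabulate(bin[st == "+"], nbins = nb)
    r <- tabulate(bin[st == "-"], nbins = nb)
    netW <- runsum(f - r)
    totW <- runsum(f + r)
    zW <- ifelse(totW > 0, netW / sqrt(totW), 0)
    zBefore <- lagmax(zW)
    zAfter <- leadmin(zW)
    i <- which(netW[-nb] > 0 & netW[-1] < 0 &
               zBefore[-nb] >= minZ & zAfter[-1] <= -minZ)
    if (!length(i)) next
    count <- totW[i] + totW[pmin(i + k, nb)]   # tags in [i-k+1 .. i+k]
    p <- stats::ppois(count - 1L, lambda, lower.tail = FALSE)
    keep <- p < pCut
    if (!any(keep)) next
    i <- i[keep]; count <- count[keep]; p <- p[keep]
    summit <- i * window   # boundary between bins i and i+1
    # merge summits closer than span, keeping the strongest
    grp <- cumsum(c(TRUE, diff(summit) >= span))
    best <- tapply(seq_along(i), grp, function(ii) ii[which.max(count[ii])])
    s1 <- tapply(i, grp, min); s2 <- tapply(i, grp, max)
    pk <- GRanges(ch, IRanges(pmax((s1 - k) * window + 1L, 1L),
                              pmin((s2 + k) * window, chromSizes[[ch]])))
    pk$summit <- summit[unlist(best)]
    pk$score <- count[unlist(best)]
    pk$p <- as.numeric(tapply(p, grp, min))
    res[[ch]] <- pk
  }
  if (!length(res))
  {
    out <- .emptyGR(chromSizes)
    out$summit <- integer(0); out$score <- integer(0); out$p <- numeric(0)
    return(out)
  }
  out <- do.call(c, unname(res))
  seqlevels(out) <- names(chromSizes)
  seqlengths(out) <- chromSizes
  out
}

#' Merge nucRNA tags into covered regions
#'
#' Reads separated by at most `maxGap` bp are merged; merged intervals
#' shorter than `minSize` are discarded. The survivors delimit the
#' moderately-to-abundantly transcribed portion of the genome used to
#' filter RNAPII peaks.
#'
#' @param tags `GRanges` of nucRNA tags.
#' @param maxGap Maximum gap width merged across (default 100 bp).
#' @param minSize Minimum merged-region size kept (default 1000 bp).
#' @return A `GRanges` of regions.
#' @export
nucrnaRegions <- function(tags, maxGap = 100, minSize = 1000) {
  if (maxGap < 0) stop("maxGap must be non-negative")
  r <- reduce(granges(tags), min.gapwidth = maxGap + 1, ignore.strand = TRUE)
  r[width(r) >= minSize]
}

#' Retain RNAPII peaks outside transcribed regions
#'
#' Drops every peak whose interval overlaps a nucRNA-covered region by at
#' least 1 bp; the survivors are the RNAPII+/nucRNA- candidate regulatory
#' regions. Input order is preserved.
#'
#' @param peaks `GRanges` of RNAPII peaks.
#' @param regions `GRanges` of transcribed regions ([nucrnaRegions()]).
#' @return The retained peaks.
#' @export
subtractTranscribed <- function(peaks, regions) {
  if (length(regions) == 0L) return(peaks)
  peaks[!overlapsAny(peaks, regions, ignore.strand = TRUE)]
}

#' Classify peaks by position relative to annotated genes
#'
#' Each peak is classified by its midpoint with the fixed precedence
#' TSS > gene_body > upstream_10kb > downstream_10kb > intergenic:
#' `TSS` when the midpoint lies within `tssFlank` of any gene's TSS,
#' `gene_body` when inside a gene span, `upstream_10kb` / `downstream_10kb`
#' when within `near` bp of the nearest gene on its 5' / 3' side
#' (strand-aware), and `intergenic` otherwise. The class fractions sum to 1.
#'
#' @param peaks `GRanges` of candidate peaks.
#' @param geneset A [GeneModelSet] (an empty one classifies everything
#'   intergenic).
#' @param tssFlank TSS window half-width (default 500 bp).
#' @param near Distance defining "near a gene" (default 10 kb).
#' @return `peaks` with an added `positionalClass` column and a `fractions`
#'   attribute (named proportions).
#' @export
positionalClassify <- function(peaks, geneset, tssFlank = 500, near = 1e4) {
  lvls <- c("TSS", "gene_body", "upstream_10kb", "downstream_10kb",
            "intergenic")
  cls <- rep("intergenic", length(peaks))
  g <- genes(geneset)
  if (length(g) && length(peaks)) {
    mid <- floor((start(peaks) + end(peaks)) / 2)
    midGR <- GRanges(seqnames(peaks), IRanges(mid, mid))
    tss <- tssPositions(geneset)
    tssGR <- GRanges(seqnames(g), IRanges(pmax(tss - tssFlank, 1L),
                                          tss + tssFlank))
    atTSS <- overlapsAny(midGR, tssGR, ignore.strand = TRUE)
    inBody <- overlapsAny(midGR, g, ignore.strand = TRUE)
    nearestIdx <- nearest(midGR, g, ignore.strand = TRUE)
    d <- rep(NA_integer_, length(peaks))
    side <- rep(NA_character_, length(peaks))
    okN <- !is.na(nearestIdx)
    gn <- g[nearestIdx[okN]]
    m <- mid[okN]
    before <- m < start(gn)       # 5' of span in genome coordinates
    after <- m > end(gn)
    dist <- ifelse(before, start(gn) - m, ifelse(after, m - end(gn), 0L))
    plus <- as.character(strand(gn)) == "+"
    side[okN] <- ifelse(before & plus | after & !plus, "upstream_10kb",
                 ifelse(after & plus | before & !plus, "downstream_10kb",
                        NA_character_))
    d[okN] <- dist
    cls[atTSS] <- "TSS"
    sel <- !atTSS & inBody
    cls[sel] <- "gene_body"
    sel <- !atTSS & !inBody & !is.na(d) & d <= near & !is.na(side)
    cls[sel] <- side[sel]
  }
  peaks$positionalClass <- factor(cls, levels = lvls)
  fr <- if (length(peaks)) prop.table(table(peaks$positionalClass)) else
    table(factor(character(0), levels = lvls))
  attr(peaks, "fractions") <- fr
  peaks
}

# count bases above a score cut within spans of an RleList
.conservedBases <- function(track, spans, cut) {
  tot <- 0; con <- 0
  chr <- as.character(seqnames(spans))
  for (ch in unique(chr)) {
    i <- which(chr == ch)
    r <- track[[ch]]
    s <- pmax(start(spans)[i], 1L)
    e <- pmin(end(spans)[i], length(r))
    v <- Views(r > cut, start = s, end = e)
    con <- con + sum(viewSums(v))
    tot <- tot + sum(e - s + 1L)
  }
  c(conserved = con, total = tot)
}

#' Conservation enrichment of candidate regions vs random regions
#'
#' Counts bases with conservation score above `cut` in the `span` bp of
#' sequence centred on each candidate midpoint, against the same count for
#' an equal number of random midpoints sampled uniformly outside the
#' candidate footprints, and reports the natural-log odds ratio (Haldane
#' 0.5 correction when a cell is zero) with a 1-df chi-square p-value.
#' Spans extending past a chromosome end are clipped.
#'
#' @param candidates `GRanges` of candidate regions.
#' @param consTrack Per-base conservation `RleList` ([readWiggle()] or
#'   [simulateTracks()]).
#' @param chromSizes Named chromosome lengths.
#' @param cut Conservation threshold (default 0.8).
#' @param span Width of the window around each midpoint (default 1000 bp).
#' @param seed Seed for the random-region draw (recorded in the output).
#' @param nRandom Number of random regions (default: same as candidates).
#' @return A list with `logOdds`, `se`, `p` (chi-square), `pWald`, `table`
#'   (conserved/total for candidates and random), `seed`.
#' @export
conservationEnrichment <- function(candidates, consTrack, chromSizes,
                                   cut = 0.8, span = 1000, seed = 1L,
                                   nRandom = length(candidates)) {
  .checkChromSizes(chromSizes)
  if (length(candidates) == 0L) stop("no candidate regions")
  half <- floor(span / 2)
  mid <- floor((start(candidates) + end(candidates)) / 2)
  candSpan <- GRanges(seqnames(candidates),
                      IRanges(pmax(mid - half, 1L),
                              pmin(mid + half - 1L,
                                   chromSizes[as.character(
                                     seqnames(candidates))])))
  set.seed(.subSeed(seed, 5L))
  # rejection-sample random midpoints outside candidate footprints
  rnd <- GRanges()
  guard <- 0L
  while (length(rnd) < nRandom && guard < 50L) {
    ch <- sample(names(chromSizes), nRandom, replace = TRUE,
                 prob = chromSizes / sum(chromSizes))
    m <- floor(stats::runif(nRandom, half + 1, chromSizes[ch] - half))
    cand <- GRanges(ch, IRanges(m, m))
    cand <- cand[!overlapsAny(cand, candidates, ignore.strand = TRUE)]
    rnd <- c(rnd, cand)
    guard <- guard + 1L
  }
  rnd <- head(rnd, nRandom)
  rndSpan <- GRanges(seqnames(rnd), IRanges(start(rnd) - half,
                                            start(rnd) + half - 1L))
  cc <- .conservedBases(consTrack, candSpan, cut)
  rc <- .conservedBases(consTrack, rndSpan, cut)
  a <- cc["conserved"]; b <- cc["total"] - cc["conserved"]
  c2 <- rc["conserved"]; d <- rc["total"] - rc["conserved"]
  lo <- logOdds(a, b, c2, d)
  tab <- matrix(c(a, b, c2, d), nrow = 2, byrow = TRUE)
  pChi <- if (any(tab == 0)) lo$p else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(logOdds = lo$logOdds, se = lo$se, p = pChi, pWald = lo$p,
       table = tab, seed = seed)
}

#' Transcription-factor overlap enrichment on genomic bins
#'
#' Tiles the genome into `bin`-bp bins and, for each TF peak set and for
#' all sets combined, forms the 2x2 table of bins by (overlaps a candidate)
#' x (overlaps a TF peak), reporting the natural-log odds ratio and a
#' chi-square p-value. Also returns the "TF-bound subset": candidates
#' overlapping at least one TF peak.
#'
#' @param candidates `GRanges` of candidate regions.
#' @param tfPeaks Named `GRangesList` (or list of `GRanges`) of TF peak
#'   sets; empty sets are skipped with a warning.
#' @param chromSizes Named chromosome lengths.
#' @param bin Bin width (default 1000 bp).
#' @return A list with `perTF` (data.frame: tf, logOdds, se, p, a, b, c, d),
#'   `combined` (same for the union of all peaks), and `subset` (logical
#'   vector flagging candidates bound by >= 1 TF).
#' @export
tfOverlapEnrichment <- function(candidates, tfPeaks, chromSizes, bin = 1000) {
  .checkChromSizes(chromSizes)
  bins <- tileGenome(chromSizes, tilewidth = bin,
                     cut.last.tile.in.chrom = TRUE)
  inCand <- overlapsAny(bins, candidates, ignore.strand = TRUE)
  oneTF <- function(peaks, label) {
    inTF <- overlapsAny(bins, peaks, ignore.strand = TRUE)
    a <- sum(inCand & inTF); b <- sum(inCand & !inTF)
    c2 <- sum(!inCand & inTF); d <- sum(!inCand & !inTF)
    lo <- logOdds(a, b, c2, d)
    tab <- matrix(c(a, b, c2, d), 2, byrow = TRUE)
    p <- if (any(tab == 0)) lo$p else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    data.frame(tf = label, logOdds = lo$logOdds, se = lo$se, p = p,
               a = a, b = b, c = c2, d = d)
  }
  keep <- vapply(tfPeaks, length, integer(1)) > 0L
  if (any(!keep))
    warning("empty TF set(s) skipped: ",
            paste(names(tfPeaks)[!keep], collapse = ", "))
  tfPeaks <- tfPeaks[keep]
  if (length(tfPeaks) == 0L) stop("no non-empty TF peak sets")
  perTF <- do.call(rbind, lapply(names(tfPeaks), function(nm)
    oneTF(tfPeaks[[nm]], nm)))
  allPeaks <- reduce(unlist(GRangesList(lapply(tfPeaks, granges))),
                     ignore.strand = TRUE)
  combined <- oneTF(allPeaks, "combined")
  subset <- overlapsAny(candidates, allPeaks, ignore.strand = TRUE)
  list(perTF = perTF, combined = combined, subset = subset)
}
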