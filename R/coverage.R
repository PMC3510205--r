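#' Build a per-base coverage track from aligned tags
#'
#' Every tag contributes depth 1 over its aligned span (both mates of a pair
#' count individually), so the total depth mass equals the total number of
#' aligned bases. The library size stored in the track is the number of
#' aligned tags and is reused by every normalisation downstream.
#'
#' @param tags A `GRanges` of aligned tags.
#' @param chromSizes Named chromosome lengths. May be omitted when `tags`
#'   carries seqlengths.
#' @param libraryId Label stored in the track.
#' @return A [CoverageTrack].
#' @examples
#' tags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 136))
#' trk <- coverageTrack(tags, c(chr1 = 1000), "demo")
#' librarySize(trk)
#' @export
coverageTrack <- function(tags, chromSizes = NULL, libraryId = "") {
  if (is.null(chromSizes)) {
    chromSizes <- seqlengths(tags)
    if (any(is.na(chromSizes)))
      stop("supply chromSizes or tags with seqlengths")
  }
  .checkChromSizes(chromSizes)
  if (length(tags)) {
    bad <- as.character(seqnames(tags)) %in% names(chromSizes) &
      end(tags) <= chromSizes[as.character(seqnames(tags))] & start(tags) >= 1L
    if (!all(bad))
      stop("tag beyond chromosome bounds")
  }
  tags2 <- GRanges(seqnames(tags), ranges(tags))
  seqlevels(tags2) <- names(chromSizes)
  seqlengths(tags2) <- chromSizes
  cov <- coverage(tags2)
  new("CoverageTrack", coverage = cov, librarySize = as.numeric(length(tags)),
      libraryId = libraryId)
}

# per-million scaled depth statistic over regions
.scaledStat <- function(track, regions, stat) {
  raw <- .regionViewStat(trackCoverage(track), regions, stat)
  if (librarySize(track) == 0) return(raw * 0)
  raw * 1e6 / librarySize(track)
}

#' Fold enrichment of a sample library over genomic input
#'
#' For each region, the per-million-scaled depth statistic of the sample
#' divided by that of the input, each offset by a pseudocount:
#' `(stat(sample) * 1e6 / N_sample + eps) / (stat(input) * 1e6 / N_input +
#' eps)`. Library-size scaling makes the score invariant to duplicating both
#' libraries; the pseudocount (default 1 scaled-depth unit) keeps regions
#' empty in both libraries at exactly 1 and bounds scores over zero-input
#' regions. Input normalisation is what removes mappability artifacts:
#' a region where all libraries are inflated by the same factor scores ~1.
#'
#' @param sample,input [CoverageTrack] objects covering the same genome.
#' @param regions A `GRanges` of query regions (non-empty widths).
#' @param stat `"max"` (used for window and gene scores) or `"mean"`.
#' @param eps Pseudocount in scaled-depth units, default 1.
#' @return Numeric vector of fold enrichments, parallel to `regions`.
#' @export
foldEnrichment <- function(sample, input, regions, stat = c("max", "mean"),
                           eps = 1) {
  stat <- match.arg(stat)
  s <- .scaledStat(sample, regions, stat)
  i <- .scaledStat(input, regions, stat)
  (s + eps) / (i + eps)
}

#' Per-base fold-enrichment track
#'
#' `(scaled sample depth + eps) / (scaled input depth + eps)` at every base;
#' the signal the stalling indices are computed from.
#'
#' @inheritParams foldEnrichment
#' @return A numeric `RleList`.
#' @export
enrichmentTrack <- function(sample, input, eps = 1) {
  sc <- trackCoverage(sample)
  ic <- trackCoverage(input)
  if (!identical(names(sc), names(ic)))
    stop("sample and input tracks cover different chromosomes")
  sScale <- if (librarySize(sample) > 0) 1e6 / librarySize(sample) else 0
  iScale <- if (librarySize(input) > 0) 1e6 / librarySize(input) else 0
  out <- RleList(lapply(names(sc), function(ch) {
    (sc[[ch]] * sScale + eps) / (ic[[ch]] * iScale + eps)
  }))
  names(out) <- names(sc)
  out
}

#' Reads per kilobase of feature per million mapped reads
#'
#' Counts tags overlapping the chosen feature of each gene and scales by
#' feature length (kb) and library size (millions):
#' `count / (kb * millions)`.
#'
#' @param geneset A [GeneModelSet].
#' @param tags A `GRanges` of aligned tags.
#' @param librarySize Aligned tag count, default `length(tags)`.
#' @param feature `"gene_span"` (whole span) or `"exon1"` (the 5'-most exon
#'   in transcription order).
#' @return Numeric vector of RPKM values named by gene_id.
#' @export
rpkm <- function(geneset, tags, librarySize = length(tags),
                 feature = c("gene_span", "exon1")) {
  feature <- match.arg(feature)
  if (librarySize <= 0) stop("librarySize must be positive")
  if (feature == "gene_span") {
    regions <- granges(genes(geneset))
  } else {
    ex <- exonRanges(geneset)
    str <- as.character(strand(genes(geneset)))
    regions <- do.call(c, lapply(seq_along(ex), function(i) {
      e <- ex[[i]]
      if (str[i] == "+") e[which.min(start(e))] else e[which.max(end(e))]
    }))
  }
  if (any(width(regions) == 0L)) stop("zero-length feature")
  counts <- countOverlaps(regions, tags, ignore.strand = TRUE)
  val <- counts / ((width(regions) / 1000) * (librarySize / 1e6))
  stats::setNames(val, geneIds(geneset))
}

#' Score non-overlapping genomic windows in two libraries
#'
#' Tiles each chromosome with non-overlapping windows from its first base
#' (a trailing partial window is kept and flagged) and scores each window in
#' both sample libraries as the maximum coverage depth normalised to the
#' genomic input ([foldEnrichment()] with `stat = "max"`).
#'
#' @param nucTrack,polTrack,inputTrack [CoverageTrack]s for the nucRNA,
#'   RNAPII and input libraries.
#' @param windowSize Window width in bp (default 10 kb).
#' @param geneset Optional [GeneModelSet]; when given, each window is flagged
#'   with whether it overlaps an annotated gene.
#' @param eps Pseudocount passed to [foldEnrichment()].
#' @return A `GRanges` of windows with metadata columns `nucScore`,
#'   `polScore`, `partial` and (when `geneset` is given) `hasGene`.
#' @export
windowScores <- function(nucTrack, polTrack, inputTrack, windowSize = 1e4,
                         geneset = NULL, eps = 1) {
  if (windowSize <= 0) stop("windowSize must be positive")
  cs <- chromSizes(inputTrack)
  tiles <- tileGenome(cs, tilewidth = windowSize,
                      cut.last.tile.in.chrom = TRUE)
  tiles$nucScore <- foldEnrichment(nucTrack, inputTrack, tiles, "max", eps)
  tiles$polScore <- foldEnrichment(polTrack, inputTrack, tiles, "max", eps)
  tiles$partial <- width(tiles) < windowSize
  if (!is.null(geneset))
    tiles$hasGene <- overlapsAny(tiles, genes(geneset), ignore.strand = TRUE)
  tiles
}

#' Score annotated genes in two libraries
#'
#' Gene-level analogue of [windowScores()]: each gene span is scored as the
#' maximum depth normalised to input, in both sample libraries.
#'
#' @inheritParams windowScores
#' @param geneset A [GeneModelSet].
#' @return A `GRanges` of gene spans with `gene_id`, `nucScore`, `polScore`.
#' @export
geneScores <- function(geneset, nucTrack, polTrack, inputTrack, eps = 1) {
  g <- granges(genes(geneset))
  g$gene_id <- geneIds(geneset)
  g$nucScore <- foldEnrichment(nucTrack, inputTrack, g, "max", eps)
  g$polScore <- foldEnrichment(polTrack, inputTrack, g, "max", eps)
  g
}

#' Exonic and intronic coverage by gene thirds
#'
#' Splits each gene span into equal thirds in transcription order (the 5'
#' third of a `-` strand gene is at the span end) and reports the mean
#' per-base depth over exonic and intronic bases within each third and over
#' the whole gene. Thirds with no exonic (or intronic) bases report `NA`
#' rather than 0, as the mean is undefined there.
#'
#' @param geneset A [GeneModelSet].
#' @param track A [CoverageTrack] (raw depth; pass a normalised track's
#'   statistics through [foldEnrichment()] if enrichment units are wanted).
#' @return A data.frame with columns `gene_id`, `region` (`five_prime`,
#'   `body`, `three_prime`, `whole`), `exonicMean`, `intronicMean`.
#' @export
exonIntronSummary <- function(geneset, track) {
  cov <- trackCoverage(track)
  g <- genes(geneset)
  ex <- exonRanges(geneset)
  intr <- intronRanges(geneset)
  res <- vector("list", length(g))
  for (i in seq_along(g)) {
    ch <- as.character(seqnames(g)[i])
    s <- start(g)[i]; e <- end(g)[i]
    len <- e - s + 1L
    b1 <- s + floor(len / 3); b2 <- s + floor(2 * len / 3)
    thirds <- IRanges(c(s, b1, b2), c(b1 - 1L, b2 - 1L, e))
    if (as.character(strand(g)[i]) == "-") thirds <- rev(thirds)
    thirds <- c(thirds, IRanges(s, e))
    labs <- c("five_prime", "body", "three_prime", "whole")
    exi <- ranges(ex[[i]]); ini <- ranges(intr[[i]])
    r <- cov[[ch]]
    meanOver <- function(part, third) {
      seg <- intersect(part, IRanges(start(third), end(third)))
      if (sum(width(seg)) == 0L) return(NA_real_)
      sum(viewSums(Views(r, seg))) / sum(width(seg))
    }
    res[[i]] <- data.frame(
      gene_id = geneIds(geneset)[i],
      region = labs,
      exonicMean = vapply(seq_len(4), function(k)
        meanOver(exi, thirds[k]), numeric(1)),
      intronicMean = vapply(seq_len(4), function(k)
        meanOver(ini, thirds[k]), numeric(1)))
  }
  do.call(rbind, res)
}

#' Fraction of aligned bases falling in exons
#'
#' Genome-level summary of splicing signal: the proportion of all aligned
#' tag bases that lie within annotated (merged) exons. A fully spliced
#' library is strongly exonic; nuclear RNA with retained introns is not.
#'
#' @param tags A `GRanges` of aligned tags.
#' @param geneset A [GeneModelSet].
#' @return A single fraction in [0, 1] (`NA` for an empty tag set).
#' @export
exonicFraction <- function(tags, geneset) {
  total <- sum(as.numeric(width(tags)))
  if (total == 0) return(NA_real_)
  ex <- reduce(unlist(exonRanges(geneset)), ignore.strand = TRUE)
  hits <- findOverlaps(tags, ex, ignore.strand = TRUE)
  ovw <- width(pintersect(tags[queryHits(hits)], ex[subjectHits(hits)],
                          ignore.strand = TRUE))
  sum(as.numeric(ovw)) / total
}
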