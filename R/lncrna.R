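#' One contig-building pass over nucRNA tags
#'
#' Merges reads separated by at most `maxGap` bp into semi-contiguous
#' contigs; optionally merges surviving contigs separated by less than
#' `mergeWithin` bp; then drops contigs below `minSize`. Two standard
#' parameterisations are used by [discoverContigs()]: a strict pass tuned
#' for highly expressed units (2 kb gap, 4.5 kb minimum) and a sensitive
#' pass for weakly expressed ones (1 kb gap, 2.5 kb minimum, merging
#' contigs closer than 5 kb).
#'
#' @param tags `GRanges` of nucRNA tags.
#' @param maxGap Maximum read gap merged across (bp, non-negative).
#' @param minSize Minimum contig size kept (bp).
#' @param mergeWithin Optional: merge surviving contigs separated by less
#'   than this many bp, before the size filter.
#' @return A `GRanges` of contigs.
#' @export
contigPass <- function(tags, maxGap, minSize, mergeWithin = NULL) {
  if (maxGap < 0) stop("maxGap must be non-negative")
  r <- reduce(granges(tags), min.gapwidth = maxGap + 1, ignore.strand = TRUE)
  if (!is.null(mergeWithin) && mergeWithin > 0)
    r <- reduce(r, min.gapwidth = mergeWithin, ignore.strand = TRUE)
  r[width(r) >= minSize]
}

#' Discover intergenic transcription-unit candidates
#'
#' Runs the strict and sensitive contig passes over the nucRNA tags, adds
#' sensitive-pass contigs that are less than half covered by a strict-pass
#' contig, and removes every candidate overlapping the exclusion annotation
#' (gene spans plus any extra sets such as pseudogenes, rRNA, miRNA) by at
#' least 1 bp. The counts before and after exclusion are recorded.
#'
#' @param tags `GRanges` of nucRNA tags.
#' @param geneset A [GeneModelSet] whose gene spans are excluded.
#' @param exclusions Optional extra `GRanges` (or `GRangesList`) of
#'   annotation to exclude.
#' @param strictGap,strictMin Strict-pass parameters (default 2000 / 4500).
#' @param sensGap,sensMin,sensMerge Sensitive-pass parameters (default
#'   1000 / 2500 / 5000).
#' @return A `GRanges` of candidates with a `pass` column (`strict` /
#'   `sensitive`) and metadata `nInitial` (contigs before annotation
#'   exclusion) and `nExcluded`.
#' @export
discoverContigs <- function(tags, geneset, exclusions = NULL,
                            strictGap = 2000, strictMin = 4500,
                            sensGap = 1000, sensMin = 2500,
                            sensMerge = 5000) {
  strict <- contigPass(tags, strictGap, strictMin)
  sens <- contigPass(tags, sensGap, sensMin, mergeWithin = sensMerge)
  covered <- rep(FALSE, length(sens))
  if (length(strict) && length(sens)) {
    hits <- findOverlaps(sens, strict, ignore.strand = TRUE)
    ovw <- width(pintersect(sens[queryHits(hits)],
                            strict[subjectHits(hits)]))
    covFrac <- rep(0, length(sens))
    agg <- tapply(ovw, queryHits(hits), sum)
    covFrac[as.integer(names(agg))] <- agg / width(sens)[as.integer(names(agg))]
    covered <- covFrac >= 0.5
  }
  cand <- c(strict, sens[!covered])
  pass <- c(rep("strict", length(strict)),
            rep("sensitive", sum(!covered)))
  o <- order(as.character(seqnames(cand)), start(cand))
  cand <- cand[o]; pass <- pass[o]
  cand$pass <- pass
  nInitial <- length(cand)

  excl <- granges(genes(geneset))
  if (!is.null(exclusions)) {
    if (is(exclusions, "GRangesList"))
      exclusions <- unlist(exclusions)
    excl <- c(excl, granges(exclusions))
  }
  drop <- overlapsAny(cand, excl, ignore.strand = TRUE)
  out <- cand[!drop]
  S4Vectors::metadata(out)$nInitial <- nInitial
  S4Vectors::metadata(out)$nExcluded <- sum(drop)
  out
}

#' Select stable nuclear-retained candidates by nucRNA:RNAPII ratio
#'
#' For each candidate, the average coverage depth is normalised for length
#' (the mean is already per-base) and library size (per million tags) in
#' each library, and the ratio nucRNA/RNAPII is computed (an optional
#' pseudocount `eps` on both sides bounds the ratio when the RNAPII depth
#' is zero; by default the plain ratio is used and a zero-RNAPII candidate
#' gets an infinite ratio, i.e. is trivially high-ratio). Selection uses one of three rules: the default
#' boxplot upper fence on the ratio distribution (mirroring the
#' transcribed-not-bound class logic), the top `n`, or a fixed minimum
#' ratio.
#'
#' @param candidates `GRanges` of candidates ([discoverContigs()]).
#' @param nucTrack,polTrack [CoverageTrack]s for nucRNA and RNAPII.
#' @param rule `"boxplot"`, `"top_n"` or `"min_ratio"`.
#' @param n Number kept under `"top_n"`.
#' @param minRatio Threshold under `"min_ratio"`.
#' @param eps Pseudocount in scaled-depth units (default 0).
#' @return `candidates` with added columns `nucNorm`, `polNorm`, `ratio`,
#'   `selected`, and attributes `rule` and `threshold`.
#' @export
selectStable <- function(candidates, nucTrack, polTrack,
                         rule = c("boxplot", "top_n", "min_ratio"),
                         n = NULL, minRatio = NULL, eps = 0) {
  rule <- match.arg(rule)
  nucNorm <- .scaledStat(nucTrack, candidates, "mean")
  polNorm <- .scaledStat(polTrack, candidates, "mean")
  ratio <- (nucNorm + eps) / (polNorm + eps)
  threshold <- NA_real_
  if (rule == "boxplot") {
    threshold <- boxplotThreshold(ratio)
    selected <- ratio > threshold
  } else if (rule == "top_n") {
    if (is.null(n)) stop("rule 'top_n' needs n")
    selected <- rank(-ratio, ties.method = "first") <= n
  } else {
    if (is.null(minRatio)) stop("rule 'min_ratio' needs minRatio")
    threshold <- minRatio
    selected <- ratio >= minRatio
  }
  candidates$nucNorm <- nucNorm
  candidates$polNorm <- polNorm
  candidates$ratio <- ratio
  candidates$selected <- selected
  attr(candidates, "rule") <- rule
  attr(candidates, "threshold") <- threshold
  candidates
}

#' Overlap candidates with reference annotation sets
#'
#' Reports, per named reference set, how many candidates intersect at
#' least one interval of the set, and flags candidates that cover two or
#' more intervals of a set (consolidation of previously fragmented
#' annotations into a single transcription unit).
#'
#' @param candidates `GRanges` of candidates.
#' @param sets Named list / `GRangesList` of reference interval sets.
#' @return A list with `summary` (data.frame: set, nOverlap, fraction,
#'   nConsolidating) and `perCandidate` (data.frame with one logical
#'   overlap column and one consolidation column per set).
#' @export
annotateOverlaps <- function(candidates, sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be named")
  per <- data.frame(row.names = seq_along(candidates))
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    cnt <- countOverlaps(candidates, s, ignore.strand = TRUE)
    per[[paste0(nm, "_overlap")]] <<- cnt > 0L
    per[[paste0(nm, "_consolidates")]] <<- cnt >= 2L
    data.frame(set = nm, nOverlap = sum(cnt > 0L),
               fraction = if (length(candidates))
                 sum(cnt > 0L) / length(candidates) else NA_real_,
               nConsolidating = sum(cnt >= 2L))
  })
  list(summary = do.call(rbind, rows), perCandidate = per)
}
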