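# internal helpers shared across modules

# GRanges from chrom/start/end vectors with seqlengths attached
.gr <- function(chrom, start, end, strand = "*", chromSizes = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  if (!is.null(chromSizes))
    seqlengths(gr) <- chromSizes[seqlevels(gr)]
  gr
}

# empty GRanges carrying the genome's seqinfo
.emptyGR <- function(chromSizes) {
  GRanges(seqinfo = Seqinfo(names(chromSizes), as.integer(chromSizes)))
}

.checkChromSizes <- function(chromSizes) {
  if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
    stop("chromosome sizes must be a named vector")
  if (any(chromSizes <= 0)) stop("chromosome sizes must be positive")
  chromSizes
}

# apply a Views statistic over regions of an RleList; regions on chromosomes
# absent from the list are an error
.regionViewStat <- function(rlelist, regions, stat = c("max", "mean", "sum")) {
  stat <- match.arg(stat)
  if (any(width(regions) == 0L)) stop("empty region")
  chr <- as.character(seqnames(regions))
  bad <- setdiff(unique(chr), names(rlelist))
  if (length(bad))
    stop("track does not cover chromosome(s): ", paste(bad, collapse = ", "))
  out <- numeric(length(regions))
  for (ch in unique(chr)) {
    i <- which(chr == ch)
    r <- rlelist[[ch]]
    s <- pmax(start(regions)[i], 1L)
    e <- pmin(end(regions)[i], length(r))
    if (any(e < s)) stop("region outside chromosome bounds on ", ch)
    v <- Views(r, start = s, end = e)
    out[i] <- switch(stat,
      max = viewMaxs(v),
      mean = viewMeans(v),
      sum = viewSums(v))
  }
  out
}

# deterministic sub-seed derivation; keeps values well below 2^31
.subSeed <- function(seed, offset) {
  (as.integer(seed) %% 199999991L) * 10L + as.integer(offset)
}

.isSingleNumber <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
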