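# Independent brute-force oracles and tiny fixture builders. These are
# deliberately naive (per-base arrays, all-pairs scans, exhaustive
# enumeration) and share no code with the package implementations they
# check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# tags as a plain data.frame -> per-base depth vector of length chromLen
oracleCoverage <- function(starts, ends, chromLen) {
  depth <- integer(chromLen)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# merge intervals with gap <= maxGap, then drop merged < minSize
oracleMerge <- function(starts, ends, maxGap, minSize,
                        mergeWithin = NULL) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- c(); me <- c()
  for (i in seq_along(starts)) {
    if (length(ms) && starts[i] - me[length(me)] - 1 <= maxGap) {
      me[length(me)] <- max(me[length(me)], ends[i])
    } else {
      ms <- c(ms, starts[i]); me <- c(me, ends[i])
    }
  }
  if (!is.null(mergeWithin) && length(ms) > 1) {
    ks <- ms[1]; ke <- me[1]
    for (i in 2:length(ms)) {
      if (ms[i] - ke[length(ke)] - 1 < mergeWithin) {
        ke[length(ke)] <- max(ke[length(ke)], me[i])
      } else {
        ks <- c(ks, ms[i]); ke <- c(ke, me[i])
      }
    }
    ms <- ks; me <- ke
  }
  keep <- (me - ms + 1) >= minSize
  cbind(start = ms[keep], end = me[keep])
}

# all-pairs overlap count (1-based closed intervals)
oracleOverlapCount <- function(qs, qe, ss, se) {
  vapply(seq_along(qs), function(i)
    sum(qs[i] <= se & qe[i] >= ss), integer(1))
}

# positional classification of a midpoint against gene table
# genes: data.frame(start, end, strand)
oracleClassify <- function(mid, genes, tssFlank = 500, near = 1e4) {
  if (nrow(genes) == 0) return("intergenic")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  if (any(abs(mid - tss) <= tssFlank)) return("TSS")
  if (any(mid >= genes$start & mid <= genes$end)) return("gene_body")
  d <- pmin(abs(mid - genes$start), abs(mid - genes$end))
  j <- which.min(d)
  if (d[j] > near) return("intergenic")
  g <- genes[j, ]
  if (mid < g$start) {
    if (g$strand == "+") "upstream_10kb" else "downstream_10kb"
  } else {
    if (g$strand == "+") "downstream_10kb" else "upstream_10kb"
  }
}

# naive JT statistic (double loop, ties = 1/2)
oracleJT <- function(groups) {
  jt <- 0
  for (i in seq_len(length(groups) - 1)) {
    for (j in (i + 1):length(groups)) {
      for (x in groups[[i]]) for (y in groups[[j]]) {
        if (y > x) jt <- jt + 1 else if (y == x) jt <- jt + 0.5
      }
    }
  }
  jt
}

# exact JT permutation distribution via full permutations of pooled values
oracleJTDistribution <- function(values, sizes) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  vapply(perms(values), function(p) {
    g <- lapply(seq_along(sizes), function(k) p[starts[k]:ends[k]])
    oracleJT(g)
  }, numeric(1))
}

# tie-corrected KW H from first principles
oracleKW <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(v) length(v) * mean(v)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Spearman rho via explicit average ranks + Pearson formula
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a small two-gene annotation used across tests
makeToyGenes <- function() {
  g <- GRanges(c("chr1", "chr1"),
               IRanges(c(10001, 40001), c(18000, 52000)),
               strand = c("+", "-"))
  g$gene_id <- c("gA", "gB")
  ex <- GRangesList(
    gA = GRanges("chr1", IRanges(c(10001, 13001, 16001),
                                 c(10800, 13600, 18000)), strand = "+"),
    gB = GRanges("chr1", IRanges(c(40001, 45001, 50001),
                                 c(41000, 46000, 52000)), strand = "-"))
  geneModelSet(g, ex)
}

toyChromSizes <- c(chr1 = 100000L)

# a CoverageTrack with explicit depths and library size
makeTrack <- function(depths, librarySize, id = "t",
                      chromLen = length(depths[[1]])) {
  cov <- IRanges::RleList(lapply(depths, S4Vectors::Rle))
  names(cov) <- names(depths)
  new("CoverageTrack", coverage = cov, librarySize = librarySize,
      libraryId = id)
}

# uniform-depth track over one chromosome
flatTrack <- function(depth, len, librarySize, id = "flat") {
  makeTrack(list(chr1 = rep(depth, len)), librarySize, id)
}

# tags from start positions (width w) on one chromosome
makeTags <- function(starts, w = 36, strand = "*", chrom = "chr1") {
  GRanges(chrom, IRanges(starts, width = w), strand = strand)
}

# default-scale stalling fixture config (shared by tests and acceptance)
stallSimConfig <- function(seed) {
  simConfig(seed = seed, nChroms = 2L, chromLength = 1.6e6,
            nGenes = c(BT = 0L, B = 215L, T = 0L, loBT = 0L),
            nStall = c(promoter = 6L, three_prime = 6L, double = 3L),
            interGeneGapRange = c(2000, 5000),
            nEnhancers = 0L, nLncRNA = 0L, nLncDecoys = 0L,
            nArtifacts = 0L)
}
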