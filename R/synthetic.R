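#' Create a synthetic-data configuration
#'
#' Returns a [SimConfig] describing a toy genome with planted ground truth:
#' genes of four transcriptional classes (BT, B, T, loBT), optional
#' promoter / 3' end / double RNAPII stalling configurations, intergenic
#' enhancer-like regions (RNAPII without transcription), intergenic lncRNA
#' units (transcription with little RNAPII) plus moderate-ratio decoy units,
#' an input-coverage artifact region, a conservation track and transcription
#' factor peak sets.
#'
#' Rates are expected tags per bp per million library tags, added on top of
#' the per-library background. The defaults emulate the study conditions at
#' desk scale: a 2 x 3 Mb genome, 36 bp tags, intended library sizes of
#' 3e5 tags, a deep uniform genomic input, sparse intergenic nucRNA
#' background, planted outlier classes kept to a minority of genes (as in
#' real data, where highly bound/transcribed outliers are a few hundred out
#' of ~31k genes), and a 10x stall factor over the gene-body RNAPII rate.
#' See the methods vignette for the rationale of each value.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param nChroms,chromLength Genome geometry.
#' @param tagLength Tag width in bp (paired-end 36 bp tags are emulated as
#'   independent 36 bp tags; both mates of a real pair contribute coverage
#'   over their aligned spans only).
#' @param depth Named intended library sizes (tags) for nucRNA / RNAPII /
#'   input; used to scale the per-million rates.
#' @param backgroundRate Named per-library background rates (tags/bp per
#'   million tags).
#' @param nGenes Named counts of planted gene classes (BT, B, T, loBT).
#' @param classRates List of `c(nucRNA, RNAPII)` rates per class.
#' @param rateJitterSd Lognormal sd (log scale) of per-gene rate jitter, so
#'   expression varies continuously within a class.
#' @param geneLengthRange,nExonsRange,exonFraction Gene geometry: span
#'   length range, exon count range, and the fraction of the span that is
#'   exonic.
#' @param splicingFraction Probability that an intronic position has been
#'   spliced out of the nuclear RNA pool; intronic nucRNA rate is
#'   `(1 - splicingFraction)` times the exonic rate.
#' @param interGeneGapRange Range of gaps between consecutive features.
#' @param nStall Named counts of genes with planted promoter, 3' end, or
#'   double RNAPII peaks (assigned among RNAPII-bound genes).
#' @param stallFactor Multiplier of the RNAPII rate in the TSS/TES +/-300 bp
#'   windows of stalled genes.
#' @param stallNucBoost Multiplier of the nucRNA rate for double-peak genes
#'   (these genes produce more RNA per polymerase).
#' @param nEnhancers,enhancerWidth,enhancerRate Enhancer-like regions:
#'   count, width, and RNAPII rate (tags concentrated around the summit with
#'   forward tags upstream and reverse tags downstream, the strand geometry
#'   a summit caller expects).
#' @param nLncRNA,nLncDecoys,lncLengthRange,lncNucRate,decoyRates Intergenic
#'   transcription units: high-ratio lncRNA units (nucRNA at `lncNucRate`,
#'   RNAPII at background) and RNAPII-bound decoy units transcribed at the
#'   moderate `decoyRates` (named nucRNA/RNAPII), whose nucRNA:RNAPII ratio
#'   is unremarkable.
#' @param nLncOverlapping Number of additional lncRNA-like units planted
#'   inside gene bodies (invisible to annotation-excluding discovery; used
#'   to assert that property).
#' @param nArtifacts,artifactWidth,artifactRate Input artifact regions:
#'   an alignment/mappability artifact adds `artifactRate` tags/bp/million
#'   to every library (reads from elsewhere piling up in proportion to
#'   library depth), producing raw enrichment in every sample library that
#'   input normalisation corrects to ~1.
#' @param consBlock,consBgHighProb,consCoreWidth Conservation track: block
#'   size of piecewise-constant scores, probability that a background block
#'   is highly conserved (>0.8), and the width of the conserved core planted
#'   in each enhancer.
#' @param tfNames,tfPeakWidth,tfBackgroundPeaks Transcription factor peak
#'   sets: names, peak width, and the number of background (random) peaks
#'   per factor in addition to peaks planted on enhancers.
#' @param fishC Rate constant of the synthetic transcription-frequency table
#'   (`1 - exp(-fishC * rate)`, emulating single-allele detection
#'   frequencies).
#' @return A validated [SimConfig].
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 2L,
                      chromLength = 3e6,
                      tagLength = 36L,
                      depth = c(nucRNA = 3e5, RNAPII = 3e5, input = 3e5),
                      backgroundRate = c(nucRNA = 4e-4, RNAPII = 0.02,
                                         input = 0.3),
                      nGenes = c(BT = 4L, B = 4L, T = 4L, loBT = 28L),
                      classRates = list(BT = c(4, 4), B = c(0.1, 4),
                                        T = c(4, 0.1), loBT = c(0.1, 0.05)),
                      rateJitterSd = 0.5,
                      geneLengthRange = c(6000, 12000),
                      nExonsRange = c(4L, 8L),
                      exonFraction = 0.2,
                      splicingFraction = 0.7,
                      interGeneGapRange = c(10000, 25000),
                      nStall = c(promoter = 0L, three_prime = 0L,
                                 double = 0L),
                      stallFactor = 10,
                      stallNucBoost = 5,
                      nEnhancers = 8L,
                      enhancerWidth = 1000,
                      enhancerRate = 4,
                      nLncRNA = 5L,
                      nLncDecoys = 18L,
                      lncLengthRange = c(5000, 9000),
                      lncNucRate = 4,
                      decoyRates = c(nucRNA = 1, RNAPII = 4),
                      nLncOverlapping = 0L,
                      nArtifacts = 1L,
                      artifactWidth = 5000,
                      artifactRate = 3,
                      consBlock = 100L,
                      consBgHighProb = 0.05,
                      consCoreWidth = 200L,
                      tfNames = c("GATA1", "TAL1", "KLF1"),
                      tfPeakWidth = 300,
                      tfBackgroundPeaks = 20L,
                      fishC = 0.5) {
  p <- as.list(environment())
  obj <- new("SimConfig", params = p)
  validObject(obj)
  obj
}

#' @rdname simConfig
#' @param x A [SimConfig].
#' @export
simParams <- function(x) x@params

# draw exon structure within a span: nExons exons totalling ~exonFraction of
# the span, exons anchored at both span ends; returns starts/widths
.drawExons <- function(s, e, cfg) {
  len <- e - s + 1L
  nex <- sample(seq(cfg$nExonsRange[1], cfg$nExonsRange[2]), 1L)
  exonTotal <- max(nex * 50L, round(cfg$exonFraction * len))
  w <- stats::rmultinom(1, exonTotal - nex * 50L, rep(1, nex))[, 1] + 50L
  gapTotal <- len - sum(w)
  if (gapTotal < nex - 1L)             # degenerate: fall back to one exon
    return(list(starts = s, widths = len))
  inner <- stats::rmultinom(1, gapTotal, rep(1, max(nex - 1L, 1L)))[, 1]
  if (nex == 1L) inner <- integer(0)
  starts <- s + cumsum(c(0L, w[-nex] + inner))
  list(starts = starts, widths = w)
}

#' Build a synthetic genome with planted ground truth
#'
#' Lays out genes and intergenic features sequentially along each
#' chromosome with random gaps (features are non-overlapping and at least
#' 10 kb apart under the default gap range), assigns each gene a class, a
#' stalling configuration and jittered tag rates, and returns the truth
#' table that makes every downstream result checkable.
#'
#' @param config A [SimConfig].
#' @return A list with elements:
#'   \describe{
#'     \item{genes}{A [GeneModelSet] of the planted genes.}
#'     \item{truth}{A `GRanges` of all planted features (genes,
#'       enhancer-like, lncRNA units, decoys, input artifacts) with
#'       metadata columns `feature_id`, `feature_kind`, `planted_class`,
#'       `planted_stall`, `nucRate`, `polRate`, `splicingFraction`,
#'       `highRatio`.}
#'     \item{chromSizes}{Named chromosome lengths.}
#'   }
#'   Re-running with the same config gives identical output.
#' @export
buildGenome <- function(config) {
  cfg <- simParams(config)
  set.seed(.subSeed(cfg$seed, 0L))
  chromSizes <- stats::setNames(rep(as.integer(cfg$chromLength), cfg$nChroms),
                                paste0("chrS", seq_len(cfg$nChroms)))

  classes <- rep(names(cfg$nGenes), cfg$nGenes)
  nGene <- length(classes)
  if (nGene) classes <- sample(classes)   # shuffle placement order

  stallLabels <- rep(names(cfg$nStall), cfg$nStall)
  boundGenes <- which(vapply(classes, function(cl) cfg$classRates[[cl]][2] > 0.5,
                             logical(1)))
  if (length(stallLabels) > length(boundGenes))
    stop("more stall genes requested than RNAPII-bound genes available")
  stallAssign <- rep("none", nGene)
  if (length(stallLabels))
    stallAssign[sample(boundGenes, length(stallLabels))] <- stallLabels

  kinds <- c(rep("gene", nGene),
             rep("enhancer_like", cfg$nEnhancers),
             rep("lncRNA_unit", cfg$nLncRNA),
             rep("lnc_decoy", cfg$nLncDecoys),
             rep("input_artifact", cfg$nArtifacts))
  widths <- c(round(stats::runif(nGene, cfg$geneLengthRange[1],
                                 cfg$geneLengthRange[2])),
              rep(cfg$enhancerWidth, cfg$nEnhancers),
              round(stats::runif(cfg$nLncRNA + cfg$nLncDecoys,
                                 cfg$lncLengthRange[1],
                                 cfg$lncLengthRange[2])),
              rep(cfg$artifactWidth, cfg$nArtifacts))
  ord <- sample(length(kinds))
  kinds <- kinds[ord]; widths <- widths[ord]
  geneSlot <- cumsum(kinds == "gene")    # index into classes for gene rows

  # sequential placement with random inter-feature gaps
  chrom <- character(length(kinds))
  fs <- integer(length(kinds)); fe <- integer(length(kinds))
  ci <- 1L
  pos <- 1L + round(stats::runif(1, cfg$interGeneGapRange[1],
                                 cfg$interGeneGapRange[2]))
  for (i in seq_along(kinds)) {
    gap <- round(stats::runif(1, cfg$interGeneGapRange[1],
                              cfg$interGeneGapRange[2]))
    if (pos + widths[i] + gap > chromSizes[ci]) {
      ci <- ci + 1L
      if (ci > length(chromSizes))
        stop("requested features exceed genome capacity; ",
             "increase chromLength or nChroms")
      pos <- 1L + gap
    }
    chrom[i] <- names(chromSizes)[ci]
    fs[i] <- pos
    fe[i] <- pos + widths[i] - 1L
    pos <- fe[i] + gap
  }

  truth <- GRanges(chrom, IRanges(fs, fe), strand = "*")
  seqlevels(truth) <- names(chromSizes)
  seqlengths(truth) <- chromSizes
  truth$feature_kind <- kinds
  truth$planted_class <- "none"
  truth$planted_stall <- "none"
  truth$nucRate <- 0
  truth$polRate <- 0
  truth$splicingFraction <- NA_real_
  truth$highRatio <- FALSE

  gi <- which(kinds == "gene")
  if (length(gi)) {
    cls <- classes[geneSlot[gi]]
    truth$planted_class[gi] <- cls
    truth$planted_stall[gi] <- stallAssign[geneSlot[gi]]
    jit <- function(n) exp(stats::rnorm(n, 0, cfg$rateJitterSd))
    base <- t(vapply(cls, function(cl) cfg$classRates[[cl]], numeric(2)))
    truth$nucRate[gi] <- base[, 1] * jit(length(gi))
    truth$polRate[gi] <- base[, 2] * jit(length(gi))
    dbl <- truth$planted_stall[gi] == "double"
    truth$nucRate[gi][dbl] <- truth$nucRate[gi][dbl] * cfg$stallNucBoost
    truth$splicingFraction[gi] <- cfg$splicingFraction
    strand(truth)[gi] <- sample(c("+", "-"), length(gi), replace = TRUE)
  }
  ei <- which(kinds == "enhancer_like")
  truth$polRate[ei] <- cfg$enhancerRate
  li <- which(kinds == "lncRNA_unit")
  truth$nucRate[li] <- cfg$lncNucRate
  truth$highRatio[li] <- TRUE
  truth$splicingFraction[li] <- 0
  di <- which(kinds == "lnc_decoy")
  truth$nucRate[di] <- cfg$decoyRates[["nucRNA"]]
  truth$polRate[di] <- cfg$decoyRates[["RNAPII"]]
  truth$splicingFraction[di] <- 0

  # optional gene-overlapping lncRNA-like units (planted inside gene bodies)
  if (cfg$nLncOverlapping > 0L) {
    host <- truth[gi][order(-width(truth[gi]))][seq_len(cfg$nLncOverlapping)]
    ov <- GRanges(seqnames(host),
                  IRanges(start(host) + 500L,
                          width = pmin(width(host) - 1000L, 6000L)),
                  strand = "*")
    seqlevels(ov) <- names(chromSizes)
    seqlengths(ov) <- chromSizes
    ov$feature_kind <- "lncRNA_unit"
    ov$planted_class <- "none"
    ov$planted_stall <- "none"
    ov$nucRate <- cfg$lncNucRate
    ov$polRate <- 0
    ov$splicingFraction <- 0
    ov$highRatio <- TRUE
    truth <- c(truth, ov)
  }

  truth$feature_id <- sprintf("%s_%03d", truth$feature_kind,
                              stats::ave(seq_along(truth),
                                         truth$feature_kind,
                                         FUN = seq_along))

  gidx <- which(truth$feature_kind == "gene" & truth$planted_class != "none")
  if (length(gidx)) {
    spans <- granges(truth[gidx])
    spans$gene_id <- truth$feature_id[gidx]
    drawn <- lapply(gidx, function(i)
      .drawExons(start(truth)[i], end(truth)[i], cfg))
    nper <- vapply(drawn, function(d) length(d$starts), integer(1))
    rep_i <- rep(seq_along(gidx), nper)
    allEx <- GRanges(seqnames(truth)[gidx][rep_i],
                     IRanges(unlist(lapply(drawn, `[[`, "starts")),
                             width = unlist(lapply(drawn, `[[`, "widths"))),
                     strand = strand(truth)[gidx][rep_i])
    exons <- split(allEx, factor(truth$feature_id[gidx][rep_i],
                                 levels = truth$feature_id[gidx]))
    gms <- geneModelSet(spans, exons)
  } else {
    gms <- new("GeneModelSet",
               genes = GRanges(gene_id = character(0)),
               exons = GRangesList())
  }
  list(genes = gms, truth = truth, chromSizes = chromSizes)
}

# piecewise-constant rate segments (tags/bp/million) for one library
.rateSegments <- function(genome, library, cfg) {
  truth <- genome$truth
  chromSizes <- genome$chromSizes
  bg <- cfg$backgroundRate[[library]]
  segList <- list(GRanges(names(chromSizes), IRanges(1L, chromSizes),
                          rate = bg))

  addSeg <- function(gr, rate) {
    if (length(gr) == 0L || all(rate == 0)) return(invisible(NULL))
    keep <- rate > 0
    if (!any(keep)) return(invisible(NULL))
    g <- granges(gr[keep])
    strand(g) <- "*"
    g$rate <- rate[keep]
    segList[[length(segList) + 1L]] <<- g
    invisible(NULL)
  }

  genesIdx <- which(truth$feature_kind == "gene")
  if (library == "nucRNA") {
    # exonic bases at full rate, intronic at (1 - splicing) * rate
    gms <- genome$genes
    if (length(gms)) {
      ids <- geneIds(gms)
      tmatch <- match(ids, truth$feature_id)
      rate <- truth$nucRate[tmatch]
      spl <- truth$splicingFraction[tmatch]
      ex <- exonRanges(gms)
      intr <- intronRanges(gms)
      addSeg(unlist(ex, use.names = FALSE), rep(rate, lengths(ex)))
      addSeg(unlist(intr, use.names = FALSE),
             rep(rate * (1 - spl), lengths(intr)))
    }
    other <- which(truth$feature_kind %in% c("lncRNA_unit", "lnc_decoy"))
    addSeg(truth[other], truth$nucRate[other])
  } else if (library == "RNAPII") {
    addSeg(truth[genesIdx], truth$polRate[genesIdx])
    # stall windows multiply the local rate: add (factor - 1) * body rate
    st <- truth[genesIdx]
    pr <- which(st$planted_stall %in% c("promoter", "double"))
    tp <- which(st$planted_stall %in% c("three_prime", "double"))
    if (length(pr)) {
      tss <- ifelse(as.character(strand(st)[pr]) == "-",
                    end(st)[pr], start(st)[pr])
      addSeg(GRanges(seqnames(st)[pr],
                     IRanges(pmax(tss - 300L, 1L), tss + 300L)),
             st$polRate[pr] * (cfg$stallFactor - 1))
    }
    if (length(tp)) {
      tes <- ifelse(as.character(strand(st)[tp]) == "-",
                    start(st)[tp], end(st)[tp])
      addSeg(GRanges(seqnames(st)[tp],
                     IRanges(pmax(tes - 300L, 1L), tes + 300L)),
             st$polRate[tp] * (cfg$stallFactor - 1))
    }
    dec <- which(truth$feature_kind == "lnc_decoy")
    addSeg(truth[dec], truth$polRate[dec])
    # enhancers are simulated separately with summit-centred strand geometry
  }
  # mapping artifact: attracts a fixed fraction of each library's reads,
  # so its per-(intended)-million rate is scaled by the library's expected
  # realised size
  art <- which(truth$feature_kind == "input_artifact")
  if (length(art)) {
    expTotal <- sum(vapply(segList, function(g)
      sum(g$rate * width(g)), numeric(1))) * cfg$depth[[library]] / 1e6
    artRate <- cfg$artifactRate * max(expTotal, 1) / cfg$depth[[library]]
    addSeg(truth[art], rep(artRate, length(art)))
  }
  suppressWarnings(do.call(c, segList))
}

# sample Poisson tag starts from rate segments
.sampleSegmentTags <- function(segs, depth, tagLength, chromSizes) {
  lambda <- segs$rate * width(segs) * depth / 1e6
  n <- stats::rpois(length(segs), lambda)
  if (sum(n) == 0L)
    return(.emptyGR(chromSizes))
  idx <- rep(seq_along(segs), n)
  starts <- floor(stats::runif(sum(n), start(segs)[idx],
                               end(segs)[idx] + 1L))
  maxStart <- chromSizes[as.character(seqnames(segs))[idx]] - tagLength + 1L
  starts <- pmin(pmax(starts, 1L), maxStart)
  gr <- GRanges(seqnames(segs)[idx], IRanges(starts, width = tagLength))
  seqlevels(gr) <- names(chromSizes)
  seqlengths(gr) <- chromSizes
  gr
}

#' Simulate one aligned library over a synthetic genome
#'
#' Tag starts follow a Poisson process whose per-base rate is the library
#' background plus the planted feature rates: nucRNA tags cover exons at the
#' full gene rate and introns at `(1 - splicingFraction)` times it, and take
#' the gene strand; RNAPII tags cover gene bodies with stall windows
#' (TSS/TES +/- 300 bp) multiplied by the stall factor, and enhancer-like
#' features receive summit-centred tags with forward tags upstream and
#' reverse tags downstream of the summit; the input library is background
#' everywhere. All three libraries are inflated inside planted input
#' artifact regions, which is exactly the situation input normalisation
#' corrects. Strands of non-genic tags are balanced at random.
#'
#' @param genome Output of [buildGenome()].
#' @param library `"nucRNA"`, `"RNAPII"` or `"input"`.
#' @param config The same [SimConfig] used to build the genome.
#' @return A `GRanges` of tags (deterministic given the config seed).
#' @export
simulateLibrary <- function(genome, library = c("nucRNA", "RNAPII", "input"),
                            config) {
  library <- match.arg(library)
  cfg <- simParams(config)
  offset <- match(library, c("nucRNA", "RNAPII", "input"))
  set.seed(.subSeed(cfg$seed, offset))
  if (cfg$depth[[library]] <= 0)
    return(.emptyGR(genome$chromSizes))
  segs <- .rateSegments(genome, library, cfg)
  tags <- .sampleSegmentTags(segs, cfg$depth[[library]], cfg$tagLength,
                             genome$chromSizes)
  truth <- genome$truth

  # strand assignment
  strand(tags) <- sample(c("+", "-"), length(tags), replace = TRUE)
  if (library == "nucRNA" && length(tags)) {
    gidx <- which(truth$feature_kind == "gene")
    if (length(gidx)) {
      hit <- findOverlaps(tags, truth[gidx], select = "first")
      has <- !is.na(hit)
      strand(tags)[has] <- strand(truth[gidx])[hit[has]]
    }
  }

  if (library == "RNAPII") {
    ei <- which(truth$feature_kind == "enhancer_like")
    if (length(ei)) {
      enh <- truth[ei]
      summit <- floor((start(enh) + end(enh)) / 2)
      lam <- truth$polRate[ei] * width(enh) * cfg$depth[["RNAPII"]] / 1e6
      n <- stats::rpois(length(enh), lam)
      if (sum(n) > 0L) {
        idx <- rep(seq_along(enh), n)
        fwd <- stats::runif(sum(n)) < 0.5
        # forward tags end just upstream of the summit, reverse start just
        # downstream: the strand-imbalance sign change a summit caller needs
        end3 <- summit[idx] - round(stats::runif(sum(n), 10, 120))
        startF <- end3 - cfg$tagLength + 1L
        startR <- summit[idx] + round(stats::runif(sum(n), 10, 120))
        starts <- ifelse(fwd, startF, startR)
        starts <- pmin(pmax(starts, 1L),
                       genome$chromSizes[as.character(seqnames(enh))[idx]] -
                         cfg$tagLength + 1L)
        etags <- GRanges(seqnames(enh)[idx],
                         IRanges(starts, width = cfg$tagLength),
                         strand = ifelse(fwd, "+", "-"))
        seqlevels(etags) <- names(genome$chromSizes)
        seqlengths(etags) <- genome$chromSizes
        tags <- c(tags, etags)
      }
    }
  }
  sort(tags, ignore.strand = TRUE)
}

#' Simulate conservation and transcription-factor tracks
#'
#' The conservation track is piecewise constant over `consBlock`-sized
#' blocks: background blocks are highly conserved (score drawn in
#' (0.8, 0.95]) with probability `consBgHighProb` and low otherwise, while
#' each enhancer-like feature carries a planted conserved core of
#' `consCoreWidth` bases scoring above 0.85. Each enhancer is covered by
#' 1..k of the configured TF peak sets (centred near its summit), and each
#' TF also gets `tfBackgroundPeaks` random background peaks.
#'
#' @param genome Output of [buildGenome()].
#' @param config The same [SimConfig].
#' @return A list with `conservation` (per-base `RleList`) and `tfPeaks`
#'   (named `GRangesList`, one element per TF).
#' @export
simulateTracks <- function(genome, config) {
  cfg <- simParams(config)
  set.seed(.subSeed(cfg$seed, 4L))
  chromSizes <- genome$chromSizes
  truth <- genome$truth

  cons <- RleList(lapply(chromSizes, function(len) {
    nb <- ceiling(len / cfg$consBlock)
    hi <- stats::runif(nb) < cfg$consBgHighProb
    val <- ifelse(hi, stats::runif(nb, 0.801, 0.95),
                  stats::runif(nb, 0, 0.7))
    Rle(val, c(rep(cfg$consBlock, nb - 1L),
               len - (nb - 1L) * cfg$consBlock))
  }))
  names(cons) <- names(chromSizes)

  ei <- which(truth$feature_kind == "enhancer_like")
  if (length(ei)) {
    enh <- truth[ei]
    mid <- floor((start(enh) + end(enh)) / 2)
    cs <- mid - floor(cfg$consCoreWidth / 2)
    for (k in seq_along(enh)) {
      ch <- as.character(seqnames(enh))[k]
      at <- seq(cs[k], cs[k] + cfg$consCoreWidth - 1L)
      cons[[ch]][at] <- stats::runif(cfg$consCoreWidth, 0.85, 1)
    }
  }

  tfPeaks <- lapply(seq_along(cfg$tfNames), function(t) {
    peaks <- .emptyGR(chromSizes)
    if (length(ei)) {
      enh <- truth[ei]
      mid <- floor((start(enh) + end(enh)) / 2)
      # each enhancer bound by TF t with decreasing probability, the first
      # TF binding all of them so every enhancer has >= 1 peak
      bound <- if (t == 1L) rep(TRUE, length(enh)) else
        stats::runif(length(enh)) < 0.6
      if (any(bound)) {
        ctr <- mid[bound] + round(stats::rnorm(sum(bound), 0, 50))
        peaks <- GRanges(seqnames(enh)[bound],
                         IRanges(ctr - floor(cfg$tfPeakWidth / 2),
                                 width = cfg$tfPeakWidth))
      }
    }
    if (cfg$tfBackgroundPeaks > 0L) {
      ch <- sample(names(chromSizes), cfg$tfBackgroundPeaks, replace = TRUE)
      st <- floor(stats::runif(cfg$tfBackgroundPeaks, 1,
                               chromSizes[ch] - cfg$tfPeakWidth))
      peaks <- c(peaks, GRanges(ch, IRanges(st, width = cfg$tfPeakWidth)))
    }
    seqlevels(peaks) <- names(chromSizes)
    seqlengths(peaks) <- chromSizes
    sort(peaks)
  })
  names(tfPeaks) <- cfg$tfNames
  list(conservation = cons, tfPeaks = GRangesList(tfPeaks))
}

#' Synthetic transcription-frequency table
#'
#' Emits, per gene, a detection frequency `100 * (1 - exp(-c * nucRate))`
#' emulating the percentage of alleles with a visible primary-transcript
#' signal; used to exercise the log-linear correlation between transcription
#' frequency and maximum nucRNA coverage depth.
#'
#' @param genome Output of [buildGenome()].
#' @param config The [SimConfig] (supplies `fishC`).
#' @return A data.frame with `gene_id` and `frequency` (percent).
#' @export
fishFrequencies <- function(genome, config) {
  cfg <- simParams(config)
  truth <- genome$truth
  gi <- which(truth$feature_kind == "gene")
  data.frame(gene_id = truth$feature_id[gi],
             frequency = 100 * (1 - exp(-cfg$fishC * truth$nucRate[gi])))
}

#' Write a full synthetic dataset to disk
#'
#' Emits the three libraries (SAM or BED), the gene annotation (GTF), the
#' conservation track (bedGraph), the TF peak sets (BED) and the truth table
#' (TSV) into a directory, exercising every writer in the package.
#'
#' @param genome Output of [buildGenome()].
#' @param config The [SimConfig].
#' @param outdir Output directory (created if needed).
#' @param alignmentFormat `"BED"` or `"SAM"`.
#' @return Invisibly, a named vector of the written paths.
#' @export
writeSimulation <- function(genome, config, outdir,
                            alignmentFormat = c("BED", "SAM")) {
  alignmentFormat <- match.arg(alignmentFormat)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (lib in c("nucRNA", "RNAPII", "input")) {
    tags <- simulateLibrary(genome, lib, config)
    if (alignmentFormat == "BED") {
      p <- file.path(outdir, paste0(lib, ".bed"))
      writeBed(tags, p)
    } else {
      p <- file.path(outdir, paste0(lib, ".sam"))
      writeSam(tags, p, genome$chromSizes)
    }
    paths[lib] <- p
  }
  gtf <- file.path(outdir, "annotation.gtf")
  g <- genes(genome$genes)
  ex <- unlist(exonRanges(genome$genes))
  feats <- c(granges(g), granges(ex))
  feats$type <- c(rep("gene", length(g)), rep("exon", length(ex)))
  feats$gene_id <- c(g$gene_id, names(ex))
  feats$source <- "nucstate_sim"
  rtracklayer::export(feats, gtf, format = "GFF2")
  paths["annotation"] <- gtf

  tracks <- simulateTracks(genome, config)
  bgp <- file.path(outdir, "conservation.bedgraph")
  consGR <- as(tracks$conservation, "GRanges")
  rtracklayer::export(consGR, bgp, format = "bedGraph")
  paths["conservation"] <- bgp
  for (tf in names(tracks$tfPeaks)) {
    p <- file.path(outdir, paste0("tf_", tf, ".bed"))
    writeBed(tracks$tfPeaks[[tf]], p)
    paths[paste0("tf_", tf)] <- p
  }
  tp <- file.path(outdir, "truth.tsv")
  writeFeatureTable(as.data.frame(genome$truth), tp)
  paths["truth"] <- tp
  invisible(paths)
}
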