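#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @import GenomeInfoDb
#' @importFrom BiocGenerics strand start end width
NULL

#' Per-base coverage for one sequencing library
#'
#' A `CoverageTrack` holds per-base tag depth for one library across all
#' chromosomes, together with the library size (number of aligned tags) used
#' for per-million scaling. It is the substrate of all downstream scoring:
#' fold enrichment over input, window scores, RPKM and stalling indices all
#' consume `CoverageTrack` objects.
#'
#' @slot coverage An [IRanges::RleList] of integer depths, one element per
#'   chromosome. The sum of all depths equals the total number of aligned
#'   bases.
#' @slot librarySize Numeric scalar, the number of aligned tags in the
#'   library (tags, not pairs).
#' @slot libraryId Character scalar naming the library (e.g. `"nucRNA"`).
#'
#' @seealso [coverageTrack()] to build one from aligned tags.
#' @export
setClass("CoverageTrack",
  representation(
    coverage = "RleList",
    librarySize = "numeric",
    libraryId = "character"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- NULL
  if (length(object@librarySize) != 1L || is.na(object@librarySize) ||
      object@librarySize < 0)
    msg <- c(msg, "'librarySize' must be a single non-negative number")
  if (length(object@libraryId) != 1L)
    msg <- c(msg, "'libraryId' must be a single string")
  if (length(object@coverage) && any(vapply(object@coverage, function(r)
        length(r) > 0L && min(runValue(r)) < 0, logical(1))))
    msg <- c(msg, "coverage depths must be non-negative")
  if (is.null(names(object@coverage)) && length(object@coverage))
    msg <- c(msg, "coverage RleList must be named by chromosome")
  if (is.null(msg)) TRUE else msg
})

#' A set of gene models with exon structure
#'
#' Container for gene annotation: one genomic span per gene plus an ordered,
#' disjoint set of exons within that span. Strand determines the positions of
#' the transcription start site (TSS) and transcription end site (TES):
#' for a `+` gene the TSS is the span start, for a `-` gene the span end.
#' Introns are the span minus the exons.
#'
#' @slot genes A [GenomicRanges::GRanges] of gene spans with a `gene_id`
#'   metadata column; strand must be `+` or `-`.
#' @slot exons A [GenomicRanges::GRangesList] parallel to `genes` (same
#'   length, names equal to `gene_id`), each element sorted, disjoint and
#'   contained in the gene span.
#'
#' @seealso [geneModelSet()], [readAnnotation()], [tssPositions()].
#' @export
setClass("GeneModelSet",
  representation(
    genes = "GRanges",
    exons = "GRangesList"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- NULL
  g <- object@genes
  e <- object@exons
  if (is.null(g$gene_id))
    return("'genes' must carry a 'gene_id' metadata column")
  if (length(g) != length(e))
    return("'genes' and 'exons' must have the same length")
  if (length(g)) {
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "duplicated gene_id")
    if (any(!as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    if (!identical(names(e), as.character(g$gene_id)))
      msg <- c(msg, "names(exons) must equal genes$gene_id")
    nex <- lengths(e)
    if (any(nex == 0L))
      msg <- c(msg, paste0("gene without exons: ",
                           paste(g$gene_id[nex == 0L], collapse = ", ")))
    ue <- unlist(e, use.names = FALSE)
    grp <- rep(seq_along(e), lengths(e))
    bad <- as.character(seqnames(ue)) != as.character(seqnames(g))[grp] |
      start(ue) < start(g)[grp] | end(ue) > end(g)[grp]
    if (any(bad))
      msg <- c(msg, paste0("exon outside gene span for: ",
                           paste(unique(g$gene_id[grp[bad]]),
                                 collapse = ", ")))
    disj <- isDisjoint(e)
    if (!all(disj))
      msg <- c(msg, paste0("overlapping exons within: ",
                           paste(g$gene_id[!disj], collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Configuration for the synthetic genome and library generator
#'
#' Bundles every knob of the synthetic-data module: genome geometry, the
#' planted gene classes and their tag rates, stalling configuration,
#' intergenic enhancer-like and lncRNA-like features, the input artifact
#' region, and the auxiliary conservation / transcription-factor tracks.
#' All randomness downstream of a `SimConfig` is fixed by its `seed`.
#'
#' Rates are expressed as expected tags per base pair per million library
#' tags, so planted signal is comparable across libraries of different
#' depths. See [simConfig()] for the defaults and their rationale.
#'
#' @seealso [simConfig()], [buildGenome()], [simulateLibrary()].
#' @export
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- NULL
  need <- c("seed", "nChroms", "chromLength", "tagLength", "depth",
            "backgroundRate", "nGenes", "classRates", "rateJitterSd",
            "geneLengthRange", "exonFraction", "nExonsRange",
            "splicingFraction", "interGeneGapRange",
            "nStall", "stallFactor", "stallNucBoost",
            "nEnhancers", "enhancerWidth", "enhancerRate",
            "nLncRNA", "nLncDecoys", "lncLengthRange", "lncNucRate",
            "decoyRates", "nLncOverlapping",
            "nArtifacts", "artifactWidth", "artifactRate",
            "consBlock", "consBgHighProb", "consCoreWidth",
            "tfNames", "tfPeakWidth", "tfBackgroundPeaks", "fishC")
  missing <- setdiff(need, names(p))
  if (length(missing))
    return(paste("missing SimConfig parameters:",
                 paste(missing, collapse = ", ")))
  if (p$splicingFraction < 0 || p$splicingFraction > 1)
    msg <- c(msg, "splicingFraction must be in [0, 1]")
  if (any(p$backgroundRate < 0) ||
      !all(c("nucRNA", "RNAPII", "input") %in% names(p$backgroundRate)))
    msg <- c(msg, "backgroundRate must be a non-negative vector named nucRNA/RNAPII/input")
  if (!all(c("BT", "B", "T", "loBT") %in% names(p$nGenes)))
    msg <- c(msg, "nGenes must be named BT/B/T/loBT")
  if (!all(c("promoter", "three_prime", "double") %in% names(p$nStall)))
    msg <- c(msg, "nStall must be named promoter/three_prime/double")
  if (any(unlist(p$classRates) < 0))
    msg <- c(msg, "class rates must be non-negative")
  if (is.null(msg)) TRUE else msg
})
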