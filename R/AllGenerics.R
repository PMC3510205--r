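#' @include AllClasses.R
NULL

#' Accessors for CoverageTrack and GeneModelSet objects
#'
#' `trackCoverage()` returns the per-chromosome depth [IRanges::RleList];
#' `librarySize()` the aligned tag count used for per-million scaling;
#' `libraryId()` the library label; `chromSizes()` the named chromosome
#' lengths implied by the track. For a [GeneModelSet], `genes()` returns the
#' gene spans, `exonRanges()` the per-gene exon [GenomicRanges::GRangesList],
#' `geneIds()` the identifiers, and `tssPositions()` / `tesPositions()` the
#' strand-aware transcription start / end sites (1-based positions).
#'
#' @param x A [CoverageTrack] or [GeneModelSet] object.
#' @return See individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackCoverage", function(x) standardGeneric("trackCoverage"))

#' @rdname accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))

#' @rdname accessors
#' @export
setGeneric("tesPositions", function(x) standardGeneric("tesPositions"))

#' @rdname accessors
setMethod("trackCoverage", "CoverageTrack", function(x) x@coverage)

#' @rdname accessors
setMethod("librarySize", "CoverageTrack", function(x) x@librarySize)

#' @rdname accessors
setMethod("libraryId", "CoverageTrack", function(x) x@libraryId)

#' @rdname accessors
setMethod("chromSizes", "CoverageTrack", function(x) {
  s <- lengths(x@coverage)
  stats::setNames(as.integer(s), names(x@coverage))
})

#' @rdname accessors
setMethod("genes", "GeneModelSet", function(x) x@genes)

#' @rdname accessors
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @rdname accessors
setMethod("geneIds", "GeneModelSet", function(x) as.character(x@genes$gene_id))

#' @rdname accessors
setMethod("tssPositions", "GeneModelSet", function(x) {
  ifelse(as.character(strand(x@genes)) == "+", start(x@genes), end(x@genes))
})

#' @rdname accessors
setMethod("tesPositions", "GeneModelSet", function(x) {
  ifelse(as.character(strand(x@genes)) == "+", end(x@genes), start(x@genes))
})

#' @rdname accessors
setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "CoverageTrack", function(object) {
  cs <- chromSizes(object)
  cat("CoverageTrack '", object@libraryId, "'\n", sep = "")
  cat("  chromosomes: ", length(cs), " (",
      format(sum(as.numeric(cs)), big.mark = ","), " bp)\n", sep = "")
  cat("  library size: ", format(object@librarySize, big.mark = ","),
      " aligned tags\n", sep = "")
  tot <- sum(vapply(object@coverage, function(r) sum(as.numeric(runValue(r)) *
                                                     runLength(r)), numeric(1)))
  cat("  total aligned bases: ", format(tot, big.mark = ","), "\n", sep = "")
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with ", length(object@genes), " genes on ",
      length(unique(as.character(seqnames(object@genes)))),
      " chromosome(s)\n", sep = "")
  if (length(object@genes)) {
    cat("  median span: ", stats::median(width(object@genes)), " bp; ",
        "median exons/gene: ", stats::median(lengths(object@exons)),
        "\n", sep = "")
  }
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig (seed ", p$seed, ")\n", sep = "")
  cat("  genome: ", p$nChroms, " x ", format(p$chromLength, big.mark = ","),
      " bp; tag length ", p$tagLength, " bp\n", sep = "")
  cat("  genes: ", paste(names(p$nGenes), p$nGenes, sep = "=",
                         collapse = " "), "\n", sep = "")
  cat("  stall: ", paste(names(p$nStall), p$nStall, sep = "=",
                         collapse = " "),
      " (factor ", p$stallFactor, "x)\n", sep = "")
  cat("  intergenic: ", p$nEnhancers, " enhancer-like, ", p$nLncRNA,
      " lncRNA units, ", p$nLncDecoys, " decoy units\n", sep = "")
})
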