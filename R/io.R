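#' Read aligned tags from SAM or BED
#'
#' Loads aligned sequencing tags into a [GenomicRanges::GRanges] with one
#' range per tag (aligned span on the reference, strand from the alignment).
#' BED input is taken as-is (each line one tag); SAM input is converted
#' through [Rsamtools::asBam()] and read with
#' [GenomicAlignments::readGAlignments()], dropping unmapped and secondary
#' records (the number skipped is reported). Both routes land in the same
#' 1-based closed GRanges convention, so SAM and BED encodings of the same
#' tags produce identical coverage downstream.
#'
#' @param path Path to a SAM (`.sam`) or BED file.
#' @param format `"auto"` (from extension), `"SAM"` or `"BED"`.
#' @param chromSizes Optional named vector of chromosome lengths; tags on
#'   unknown chromosomes are skipped (`onUnknownChrom = "skip"`, with a
#'   message) or are an error.
#' @param onUnknownChrom `"skip"` or `"error"`.
#' @return A `GRanges` of tags. `metadata(x)$skipped` records how many
#'   records were dropped.
#' @seealso [coverageTrack()], [writeBed()]
#' @export
readAlignments <- function(path, format = c("auto", "SAM", "BED"),
                           chromSizes = NULL,
                           onUnknownChrom = c("skip", "error")) {
  format <- match.arg(format)
  onUnknownChrom <- match.arg(onUnknownChrom)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "SAM" else "BED"
  }
  skipped <- 0L
  if (format == "BED") {
    n <- length(readLines(path))
    if (n == 0L) {
      tags <- GRanges()
    } else {
      tags <- rtracklayer::import(path, format = "BED")
      tags <- granges(tags)
    }
  } else {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    total <- Rsamtools::countBam(bam)$records
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flags))
    tags <- granges(ga)
    skipped <- total - length(tags)
    if (skipped > 0L)
      message("readAlignments: skipped ", skipped,
              " unaligned/secondary record(s)")
  }
  if (!is.null(chromSizes)) {
    .checkChromSizes(chromSizes)
    unknown <- !(as.character(seqnames(tags)) %in% names(chromSizes))
    if (any(unknown)) {
      if (onUnknownChrom == "error")
        stop(sum(unknown), " tag(s) on chromosomes absent from the genome")
      message("readAlignments: skipped ", sum(unknown),
              " tag(s) on unknown chromosomes")
      skipped <- skipped + sum(unknown)
      tags <- tags[!unknown]
    }
    tags <- GRanges(seqnames(tags), ranges(tags), strand = strand(tags))
    seqlevels(tags) <- names(chromSizes)
    seqlengths(tags) <- chromSizes
  }
  S4Vectors::metadata(tags)$skipped <- skipped
  tags
}

#' Read gene annotation from GTF/GFF
#'
#' Builds a [GeneModelSet] from `gene` and `exon` features. Overlapping
#' exons of the same gene are merged; genes are returned in deterministic
#' order (chromosome, start, gene_id). A gene without exons, or an exon
#' outside its gene span, is an error naming the offending gene.
#'
#' @param path Path to a GTF or GFF file with `gene` and `exon` rows carrying
#'   a `gene_id` attribute.
#' @return A [GeneModelSet].
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  feats <- rtracklayer::import(path)
  if (is.null(feats$type) || is.null(feats$gene_id))
    stop("annotation must carry 'type' and 'gene_id' attributes")
  g <- feats[feats$type == "gene"]
  e <- feats[feats$type == "exon"]
  if (length(g) == 0L) stop("no 'gene' features found")
  spans <- granges(g)
  names(spans) <- NULL
  spans$gene_id <- as.character(g$gene_id)
  exons <- split(granges(e), factor(as.character(e$gene_id),
                                    levels = unique(spans$gene_id)))
  geneModelSet(genes = spans, exons = exons)
}

#' Construct a GeneModelSet
#'
#' @param genes A `GRanges` of gene spans with a `gene_id` column and
#'   strand `+`/`-`.
#' @param exons A `GRangesList` named by gene_id (order need not match;
#'   missing names are an error). Overlapping exons are merged.
#' @return A validated [GeneModelSet], ordered by (chromosome, start,
#'   gene_id).
#' @export
geneModelSet <- function(genes, exons) {
  if (is.null(genes$gene_id)) stop("genes must carry gene_id")
  ids <- as.character(genes$gene_id)
  if (length(ids) == 0L)
    return(new("GeneModelSet", genes = genes, exons = GRangesList()))
  if (!all(ids %in% names(exons)))
    stop("exons missing for: ",
         paste(setdiff(ids, names(exons)), collapse = ", "))
  exons <- exons[ids]
  if (!is(exons, "GRangesList")) exons <- GRangesList(exons)
  exons <- reduce(exons)
  names(exons) <- ids
  ord <- order(as.character(seqnames(genes)), start(genes), ids)
  genes <- granges(genes)[ord]
  genes$gene_id <- ids[ord]
  obj <- new("GeneModelSet", genes = genes, exons = exons[ids[ord]])
  validObject(obj)
  obj
}

#' Intron ranges of a GeneModelSet
#'
#' Introns are each gene span minus its exons.
#'
#' @param x A [GeneModelSet].
#' @return A `GRangesList` parallel to the genes (possibly with empty
#'   elements for single-exon genes spanning their whole span).
#' @export
intronRanges <- function(x) {
  g <- genes(x)
  if (length(g) == 0L) return(GRangesList())
  spans <- granges(g)
  strand(spans) <- "*"
  ex <- exonRanges(x)
  uex <- unlist(ex, use.names = FALSE)
  strand(uex) <- "*"
  ex <- relist(uex, ex)
  out <- psetdiff(spans, ex)
  names(out) <- geneIds(x)
  out
}

#' Read a per-base score track (fixedStep wiggle or bedGraph)
#'
#' Returns a per-base [IRanges::RleList] in which bases absent from the file
#' score 0 and present values are preserved exactly. Overlapping intervals
#' (which would make per-base values ambiguous) are an error.
#'
#' @param path Path to a wiggle or bedGraph file.
#' @param format `"auto"` (from extension), `"wig"` or `"bedGraph"`.
#' @param chromSizes Optional named chromosome lengths; when given, the
#'   track is padded with zeros to the chromosome ends.
#' @return A named `RleList` of numeric scores.
#' @export
readWiggle <- function(path, format = c("auto", "wig", "bedGraph"),
                       chromSizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = format)
  if (!isDisjoint(gr)) stop("overlapping score intervals in ", path)
  if (!is.null(chromSizes)) {
    .checkChromSizes(chromSizes)
    seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
  }
  coverage(gr, weight = "score")
}

#' Write genomic regions as BED
#'
#' Coordinates round-trip bit-identically through [readAlignments()] /
#' [rtracklayer::import()].
#'
#' @param regions A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' Write / read a tabular report
#'
#' Plain TSV with header, no quoting surprises; numeric columns survive a
#' round trip exactly (values are written with full precision).
#'
#' @param records A data.frame.
#' @param path File path.
#' @return `writeFeatureTable` invisibly returns `path`;
#'   `readFeatureTable` returns the data.frame.
#' @export
writeFeatureTable <- function(records, path) {
  utils::write.table(format(records, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write aligned tags as SAM
#'
#' Minimal single-end SAM export (36M-style CIGAR from the tag width) used by
#' the synthetic-data module so that the SAM reading path can be exercised
#' without binary fixtures.
#'
#' @param tags A `GRanges` of tags with strand.
#' @param path Output path.
#' @param chromSizes Named chromosome lengths for the header.
#' @return Invisibly, `path`.
#' @export
writeSam <- function(tags, path, chromSizes) {
  .checkChromSizes(chromSizes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chromSizes),
                     as.integer(chromSizes)), con)
  if (length(tags)) {
    flag <- ifelse(as.character(strand(tags)) == "-", 16L, 0L)
    w <- width(tags)
    lines <- sprintf("tag%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     seq_along(tags), flag, as.character(seqnames(tags)),
                     start(tags), w, strrep("N", w))
    writeLines(lines, con)
  }
  invisible(path)
}
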