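#' Run the full comparative analysis on a synthetic dataset
#'
#' Orchestrates every stage in dependency order on a genome generated from
#' a [SimConfig]: library simulation, coverage tracks, 10 kb window and
#' gene scores, BT/B/T/loBT classification with efficiency ratios, stalling
#' indices and categories (when stall genes are planted), RNAPII peak
#' calling with nucRNA subtraction, positional / conservation / TF
#' enrichment of the candidate regulatory regions, and contig-based lncRNA
#' discovery with ratio selection. Re-running with the same config
#' reproduces the results exactly. When `outdir` is given, each stage's
#' table is written as TSV/BED together with the config seed.
#'
#' @param config A [SimConfig].
#' @param outdir Optional output directory for the report files.
#' @param windowSize Window width for genome-wide scores (default 10 kb).
#' @return A named list with elements `genome`, `tracks`, `windows`,
#'   `geneClassification`, `efficiency`, `stalling` (NULL when no stall
#'   genes are planted), `peaks`, `candidates`, `positional`,
#'   `conservation`, `tf`, `lncrna`.
#' @export
runPipeline <- function(config, outdir = NULL, windowSize = 1e4) {
  genome <- buildGenome(config)
  cs <- genome$chromSizes
  nucTags <- simulateLibrary(genome, "nucRNA", config)
  polTags <- simulateLibrary(genome, "RNAPII", config)
  inpTags <- simulateLibrary(genome, "input", config)
  tracks <- simulateTracks(genome, config)
  nuc <- coverageTrack(nucTags, cs, "nucRNA")
  pol <- coverageTrack(polTags, cs, "RNAPII")
  inp <- coverageTrack(inpTags, cs, "input")

  win <- windowScores(nuc, pol, inp, windowSize, geneset = genome$genes)
  gs <- geneScores(genome$genes, nuc, pol, inp)
  cls <- classifyExpression(gs)
  eff <- efficiencyRatio(cls)

  stall <- NULL
  cfg <- simParams(config)
  if (sum(cfg$nStall) > 0) {
    st <- stallingTable(genome$genes, pol, inp, nucTrack = nuc)
    stall <- categorizeStalling(st)
  }

  peaks <- callPeaks(polTags, cs)
  nr <- nucrnaRegions(nucTags)
  candidates <- subtractTranscribed(peaks, nr)
  positional <- positionalClassify(candidates, genome$genes)
  conservation <- conservationEnrichment(candidates, tracks$conservation,
                                         cs, seed = cfg$seed)
  tf <- tfOverlapEnrichment(candidates, tracks$tfPeaks, cs)

  contigs <- discoverContigs(nucTags, genome$genes)
  lnc <- selectStable(contigs, nuc, pol)

  res <- list(genome = genome, tracks = tracks, windows = win,
              geneClassification = cls, efficiency = eff, stalling = stall,
              peaks = peaks, candidates = candidates,
              positional = positional, conservation = conservation,
              tf = tf, lncrna = lnc)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(as.data.frame(win), file.path(outdir, "windows.tsv"))
    writeFeatureTable(as.data.frame(cls$regions),
                      file.path(outdir, "gene_classes.tsv"))
    if (!is.null(stall))
      writeFeatureTable(stall, file.path(outdir, "stalling.tsv"))
    writeBed(granges(candidates), file.path(outdir, "candidates.bed"))
    writeFeatureTable(as.data.frame(lnc), file.path(outdir, "lncrna.tsv"))
    writeFeatureTable(
      data.frame(stage = "config", seed = cfg$seed,
                 windowSize = windowSize),
      file.path(outdir, "run_info.tsv"))
  }
  res
}
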