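test_that("generator output is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 5L)
  g1 <- buildGenome(cfg)
  g2 <- buildGenome(cfg)
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  expect_identical(as.data.frame(genes(g1$genes)),
                   as.data.frame(genes(g2$genes)))
  t1 <- simulateLibrary(g1, "nucRNA", cfg)
  t2 <- simulateLibrary(g2, "nucRNA", cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  k1 <- simulateTracks(g1, cfg)
  k2 <- simulateTracks(g2, cfg)
  expect_identical(as.list(k1$conservation), as.list(k2$conservation))
  expect_identical(as.data.frame(unname(unlist(k1$tfPeaks))),
                   as.data.frame(unname(unlist(k2$tfPeaks))))
  # different seeds give different draws
  t3 <- simulateLibrary(buildGenome(simConfig(seed = 6L)), "nucRNA",
                        simConfig(seed = 6L))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("planted features are non-overlapping and genome capacity is enforced", {
  cfg <- simConfig(seed = 2L)
  genome <- buildGenome(cfg)
  expect_true(isDisjoint(genome$truth))
  expect_error(buildGenome(simConfig(seed = 1L, chromLength = 2e5,
                                     nChroms = 1L)),
               "capacity")
})

test_that("tag counts follow the Poisson expectation from the planted rates", {
  cfg <- simConfig(seed = 9L)
  genome <- buildGenome(cfg)
  truth <- genome$truth
  tags <- simulateLibrary(genome, "RNAPII", cfg)
  p <- simParams(cfg)
  # expected count over a planted decoy unit: (bg + rate) * L * N / 1e6
  dec <- truth[truth$feature_kind == "lnc_decoy"]
  for (i in seq_len(3)) {
    lam <- (p$backgroundRate[["RNAPII"]] + dec$polRate[i]) * width(dec)[i] *
      p$depth[["RNAPII"]] / 1e6
    obs <- sum(start(tags) >= start(dec)[i] & start(tags) <= end(dec)[i] &
               as.character(seqnames(tags)) ==
                 as.character(seqnames(dec))[i])
    expect_lt(abs(obs - lam), 4 * sqrt(lam))
  }
})

test_that("splicing fraction controls intronic nucRNA tags", {
  cfg <- simConfig(seed = 3L, splicingFraction = 1)
  genome <- buildGenome(cfg)
  tags <- simulateLibrary(genome, "nucRNA", cfg)
  introns <- unlist(intronRanges(genome$genes))
  hi <- genome$truth$feature_id[genome$truth$feature_kind == "gene" &
                                genome$truth$nucRate > 1]
  introns <- introns[names(introns) %in% hi]
  # tag *starts* in introns of expressed genes can only be background
  startsGR <- GRanges(seqnames(tags), IRanges(start(tags), width = 1))
  nIntronStarts <- sum(overlapsAny(startsGR, introns))
  p <- simParams(cfg)
  bgExp <- p$backgroundRate[["nucRNA"]] * sum(width(introns)) *
    p$depth[["nucRNA"]] / 1e6
  expect_lte(nIntronStarts, stats::qpois(0.9999, bgExp))
})

test_that("zero depth gives an empty library", {
  cfg <- simConfig(seed = 4L, depth = c(nucRNA = 0, RNAPII = 1e5,
                                        input = 1e5))
  genome <- buildGenome(cfg)
  expect_length(simulateLibrary(genome, "nucRNA", cfg), 0)
})

test_that("conservation and TF tracks encode the planted enhancer structure", {
  cfg <- simConfig(seed = 8L)
  genome <- buildGenome(cfg)
  tracks <- simulateTracks(genome, cfg)
  p <- simParams(cfg)
  enh <- genome$truth[genome$truth$feature_kind == "enhancer_like"]
  for (i in seq_along(enh)) {
    ch <- as.character(seqnames(enh))[i]
    v <- as.numeric(tracks$conservation[[ch]][start(enh)[i]:end(enh)[i]])
    expect_gte(sum(v > 0.8), p$consCoreWidth)
  }
  # background conservation is mostly below the cut
  bgFrac <- mean(as.numeric(tracks$conservation$chrS1[1:5000]) > 0.8)
  expect_lt(bgFrac, 0.25)
  # every enhancer carries at least one TF peak
  allTF <- unlist(tracks$tfPeaks)
  expect_true(all(overlapsAny(enh, allTF)))
  # k = 0 TFs -> no planted peak sets
  cfg0 <- simConfig(seed = 8L, tfNames = character(0),
                    tfBackgroundPeaks = 0L)
  tr0 <- simulateTracks(buildGenome(cfg0), cfg0)
  expect_length(tr0$tfPeaks, 0)
})

test_that("planted class rank order is recovered by enrichment scores", {
  cfg <- simConfig(seed = 12L)
  genome <- buildGenome(cfg)
  cs <- genome$chromSizes
  nuc <- coverageTrack(simulateLibrary(genome, "nucRNA", cfg), cs, "nucRNA")
  pol <- coverageTrack(simulateLibrary(genome, "RNAPII", cfg), cs, "RNAPII")
  inp <- coverageTrack(simulateLibrary(genome, "input", cfg), cs, "input")
  gs <- geneScores(genome$genes, nuc, pol, inp)
  truth <- genome$truth
  cls <- truth$planted_class[match(gs$gene_id, truth$feature_id)]
  nucMed <- tapply(gs$nucScore, cls, median)
  polMed <- tapply(gs$polScore, cls, median)
  expect_gt(nucMed[["BT"]], 3 * nucMed[["loBT"]])
  expect_gt(nucMed[["T"]], 3 * nucMed[["B"]])
  expect_gt(polMed[["BT"]], 3 * polMed[["loBT"]])
  expect_gt(polMed[["B"]], 3 * polMed[["T"]])
})

test_that("synthetic transcription frequencies follow the saturation model", {
  cfg <- simConfig(seed = 2L)
  genome <- buildGenome(cfg)
  ff <- fishFrequencies(genome, cfg)
  truth <- genome$truth
  gi <- match(ff$gene_id, truth$feature_id)
  expect_equal(ff$frequency,
               100 * (1 - exp(-simParams(cfg)$fishC * truth$nucRate[gi])))
  expect_true(all(ff$frequency >= 0 & ff$frequency <= 100))
})

test_that("a written simulation can be read back through the io layer", {
  cfg <- simConfig(seed = 6L, nChroms = 1L, chromLength = 1e6,
                   nGenes = c(BT = 2L, B = 2L, T = 2L, loBT = 6L),
                   nEnhancers = 2L, nLncRNA = 1L, nLncDecoys = 2L,
                   depth = c(nucRNA = 5e4, RNAPII = 5e4, input = 5e4))
  genome <- buildGenome(cfg)
  out <- tempfile()
  paths <- writeSimulation(genome, cfg, out, alignmentFormat = "SAM")
  tags <- readAlignments(paths[["nucRNA"]], chromSizes = genome$chromSizes)
  orig <- simulateLibrary(genome, "nucRNA", cfg)
  expect_equal(length(tags), length(orig))
  expect_identical(sort(ranges(tags)), sort(ranges(orig)))
  gms <- readAnnotation(paths[["annotation"]])
  expect_equal(geneIds(gms), geneIds(genome$genes))
  expect_equal(start(genes(gms)), start(genes(genome$genes)))
  cons <- readWiggle(paths[["conservation"]], chromSizes = genome$chromSizes)
  tr <- simulateTracks(genome, cfg)
  expect_equal(as.numeric(cons$chrS1[1:1000]),
               as.numeric(tr$conservation$chrS1[1:1000]), tolerance = 1e-6)
})
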