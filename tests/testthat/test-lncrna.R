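test_that("contig passes merge, secondary-merge and size-filter correctly", {
  # two read blocks at (1,2000) and (3501,6500): strict pass bridges the
  # 1500 bp gap and keeps the 6.5 kb contig
  blocks <- c(makeTags(c(seq(1, 1929, by = 30), 1965), w = 36),
              makeTags(c(seq(3501, 6429, by = 30), 6465), w = 36))
  strict <- contigPass(blocks, maxGap = 2000, minSize = 4500)
  expect_length(strict, 1)
  expect_equal(start(strict), 1)
  expect_equal(end(strict), 6500)
  # sensitive pass: the 1 kb gap rule keeps them apart, the <5 kb
  # candidate merge joins them again
  sens <- contigPass(blocks, maxGap = 1000, minSize = 2500,
                     mergeWithin = 5000)
  expect_length(sens, 1)
  expect_equal(width(sens), 6500)
  # a lone tag never survives the size filter
  expect_length(contigPass(makeTags(500), 2000, 4500), 0)
  expect_length(contigPass(makeTags(500), 1000, 2500, 5000), 0)
  expect_error(contigPass(blocks, -1, 100), "non-negative")
})

test_that("contig passes equal the brute-force merge oracle", {
  set.seed(73)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    starts <- sample(20000, n, replace = TRUE)
    w <- sample(20:50, n, replace = TRUE)
    tags <- makeTags(starts, w = w)
    mw <- sample(c(NA, 300), 1)
    got <- contigPass(tags, maxGap = 80, minSize = 200,
                      mergeWithin = if (is.na(mw)) NULL else mw)
    exp <- oracleMerge(starts, starts + w - 1L, 80, 200,
                       mergeWithin = if (is.na(mw)) NULL else mw)
    expect_equal(start(got), unname(exp[, "start"]))
    expect_equal(end(got), unname(exp[, "end"]))
  }
})

test_that("discovery excludes annotated overlap by any base pair", {
  g <- GRanges("chr1", IRanges(10001, 15000), strand = "+")
  g$gene_id <- "g1"
  gms <- geneModelSet(g, GRangesList(g1 = GRanges("chr1",
                                                  IRanges(10001, 15000))))
  # candidate block overlapping the gene by exactly 1 bp (last tag ends
  # at the gene start)
  tags1 <- c(makeTags(seq(4001, 9941, by = 30), w = 36),
             makeTags(9966, w = 36))
  cand1 <- discoverContigs(tags1, gms)
  expect_length(cand1, 0)
  expect_equal(S4Vectors::metadata(cand1)$nExcluded, 1)
  # shifted 1 bp left: no overlap, kept
  tags2 <- GenomicRanges::shift(tags1, -1)
  cand2 <- discoverContigs(tags2, gms)
  expect_length(cand2, 1)
  # extra exclusion sets apply too
  rrna <- GRanges("chr1", IRanges(5000, 5100))
  expect_length(discoverContigs(tags2, gms, exclusions = rrna), 0)
})

test_that("discovery is invariant to tag order and never overlaps exclusions", {
  cfg <- simConfig(seed = 14L)
  genome <- buildGenome(cfg)
  tags <- simulateLibrary(genome, "nucRNA", cfg)
  cand <- discoverContigs(tags, genome$genes)
  set.seed(79)
  shuffled <- tags[sample(length(tags))]
  cand2 <- discoverContigs(shuffled, genome$genes)
  expect_equal(as.data.frame(cand), as.data.frame(cand2))
  # independent post-hoc overlap scan against gene spans, per chromosome
  gg <- genes(genome$genes)
  for (ch in unique(as.character(seqnames(cand)))) {
    ci <- as.character(seqnames(cand)) == ch
    gi <- as.character(seqnames(gg)) == ch
    if (!any(gi)) next
    cnt <- oracleOverlapCount(start(cand)[ci], end(cand)[ci],
                              start(gg)[gi], end(gg)[gi])
    expect_true(all(cnt == 0))
  }
})

test_that("planted intergenic units are recovered; genic units are invisible", {
  recovered <- 0; total <- 0
  for (seed in 15:16) {
    cfg <- simConfig(seed = seed)
    genome <- buildGenome(cfg)
    tags <- simulateLibrary(genome, "nucRNA", cfg)
    cand <- discoverContigs(tags, genome$genes)
    units <- genome$truth[genome$truth$feature_kind == "lncRNA_unit"]
    total <- total + length(units)
    hits <- findOverlaps(units, cand)
    for (i in unique(queryHits(hits))) {
      j <- subjectHits(hits)[queryHits(hits) == i]
      ov <- width(pintersect(rep(units[i], length(j)), cand[j]))
      recip <- max(ov / pmax(width(units[i]), width(cand[j])))
      if (recip >= 0.8) recovered <- recovered + 1
    }
  }
  expect_gte(recovered / total, 0.9)

  # a unit planted inside a gene body yields no candidate
  cfgOv <- simConfig(seed = 17L, nLncOverlapping = 2L)
  genomeOv <- buildGenome(cfgOv)
  tagsOv <- simulateLibrary(genomeOv, "nucRNA", cfgOv)
  candOv <- discoverContigs(tagsOv, genomeOv$genes)
  truthOv <- genomeOv$truth
  genic <- truthOv[truthOv$feature_kind == "lncRNA_unit" &
                   overlapsAny(truthOv, genes(genomeOv$genes))]
  expect_gt(length(genic), 0)
  expect_false(any(overlapsAny(genic, candOv)))
})

test_that("ratio computation and selection rules behave as specified", {
  cand <- GRanges("chr1", IRanges(c(1, 3001), width = 1000))
  nuc <- makeTrack(list(chr1 = c(rep(10, 1000), rep(0, 2000),
                                 rep(2, 1000))), 1e6)
  pol <- makeTrack(list(chr1 = c(rep(2, 1000), rep(0, 2000),
                                 rep(2, 1000))), 1e6)
  sel <- selectStable(cand, nuc, pol, rule = "min_ratio", minRatio = 4)
  expect_equal(sel$ratio, c(5, 1))
  expect_equal(sel$selected, c(TRUE, FALSE))
  # top_n keeps exactly n
  sel2 <- selectStable(cand, nuc, pol, rule = "top_n", n = 1)
  expect_equal(sel2$selected, c(TRUE, FALSE))
  # all ratios equal: the boxplot fence selects nothing
  candEq <- GRanges("chr1", IRanges(c(1, 1001, 2001, 3001), width = 500))
  flatN <- makeTrack(list(chr1 = rep(4, 4000)), 1e6)
  flatP <- makeTrack(list(chr1 = rep(2, 4000)), 1e6)
  sel3 <- selectStable(candEq, flatN, flatP)
  expect_equal(sel3$ratio, rep(2, 4))
  expect_false(any(sel3$selected))
})

test_that("ratio selection separates planted units from B-like decoys", {
  unitsSel <- 0; unitsTot <- 0; decSel <- 0; decTot <- 0
  for (seed in 18:19) {
    cfg <- simConfig(seed = seed)
    genome <- buildGenome(cfg)
    cs <- genome$chromSizes
    nucTags <- simulateLibrary(genome, "nucRNA", cfg)
    nuc <- coverageTrack(nucTags, cs, "n")
    pol <- coverageTrack(simulateLibrary(genome, "RNAPII", cfg), cs, "p")
    sel <- selectStable(discoverContigs(nucTags, genome$genes), nuc, pol)
    units <- genome$truth[genome$truth$feature_kind == "lncRNA_unit"]
    dec <- genome$truth[genome$truth$feature_kind == "lnc_decoy"]
    unitsSel <- unitsSel + sum(overlapsAny(units, sel[sel$selected]))
    unitsTot <- unitsTot + length(units)
    decSel <- decSel + sum(overlapsAny(dec, sel[sel$selected]))
    decTot <- decTot + length(dec)
  }
  expect_gte(unitsSel / unitsTot, 0.9)
  expect_lte(decSel / decTot, 0.1)
})

test_that("overlap annotation counts and consolidation flags are exact", {
  cand <- GRanges("chr1", IRanges(c(1, 5001, 10001), width = 3000))
  refA <- GRanges("chr1", IRanges(c(100, 1500, 11000), width = 200))
  refB <- GRanges("chr1", IRanges(20000, 20100))
  r <- annotateOverlaps(cand, list(A = refA, B = refB))
  expect_equal(r$summary$nOverlap, c(2, 0))
  expect_equal(r$summary$fraction, c(2 / 3, 0))
  # candidate 1 covers two A intervals -> consolidation
  expect_equal(r$summary$nConsolidating, c(1, 0))
  expect_equal(r$perCandidate$A_overlap, c(TRUE, FALSE, TRUE))
  expect_equal(r$perCandidate$A_consolidates, c(TRUE, FALSE, FALSE))

  set.seed(83)
  for (i in 1:20) {
    cs <- sample(5000, 10); rs <- sample(5000, 15)
    cands <- makeTags(cs, w = 200); refs <- makeTags(rs, w = 50)
    got <- annotateOverlaps(cands, list(R = refs))
    cnt <- oracleOverlapCount(cs, cs + 199, rs, rs + 49)
    expect_equal(got$summary$nOverlap, sum(cnt > 0))
    expect_equal(got$perCandidate$R_consolidates, cnt >= 2)
  }
})
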