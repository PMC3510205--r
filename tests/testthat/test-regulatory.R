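test_that("a constructed strand-imbalanced site yields one summit", {
  cs <- c(chr1 = 50000L)
  x <- 25000L
  set.seed(51)
  # 50 forward tags ending near x, 50 reverse tags starting near x + 60
  fwd <- GRanges("chr1", IRanges(end = x - sample(0:10, 50, TRUE),
                                 width = 36), strand = "+")
  rev <- GRanges("chr1", IRanges(start = x + 60 + sample(0:10, 50, TRUE),
                                 width = 36), strand = "-")
  bg <- makeTags(sample(49000, 200), strand = sample(c("+", "-"), 200, TRUE))
  pk <- callPeaks(c(fwd, rev, bg), cs)
  hit <- pk[abs(pk$summit - x) < 500]
  expect_equal(length(hit), 1)
  expect_gte(hit$summit, x - 60)
  expect_lte(hit$summit, x + 120)
  expect_lt(hit$p, 0.001)
  expect_true(start(hit) <= hit$summit && hit$summit <= end(hit))
})

test_that("peak calling is conservative on strand-balanced background", {
  set.seed(53)
  cs <- c(chr1 = 1000000L)
  fp <- 0
  for (i in 1:3) {
    tags <- makeTags(sample(999900, 100000, replace = TRUE),
                     strand = sample(c("+", "-"), 100000, replace = TRUE))
    fp <- fp + length(callPeaks(tags, cs))
  }
  # expected false positives bounded by pCut x number of tested boundaries
  expect_lte(fp / 3, 0.001 * (1e6 / 20))
})

test_that("no tags means no peaks; unstranded input is refused", {
  cs <- c(chr1 = 10000L)
  expect_length(callPeaks(GRanges(), cs), 0)
  expect_error(callPeaks(makeTags(c(100, 200)), cs), "unstranded")
})

test_that("nucRNA region merging follows the gap/size rules", {
  # gap 64 <= 100 -> merged; 136 bp < 1000 -> discarded
  expect_length(nucrnaRegions(makeTags(c(1, 101))), 0)
  # 30 abutting tags spanning 1080 bp -> one region kept
  tags <- makeTags(seq(1, by = 36, length.out = 30))
  r <- nucrnaRegions(tags)
  expect_length(r, 1)
  expect_equal(width(r), 1080)
  expect_length(nucrnaRegions(GRanges()), 0)

  # random instances against the merge oracle
  set.seed(59)
  for (i in 1:40) {
    n <- sample(1:60, 1)
    starts <- sample(5000, n, replace = TRUE)
    w <- sample(20:60, n, replace = TRUE)
    got <- nucrnaRegions(makeTags(starts, w = w), maxGap = 50,
                         minSize = 150)
    exp <- oracleMerge(starts, starts + w - 1L, 50, 150)
    expect_equal(start(got), unname(exp[, "start"]))
    expect_equal(end(got), unname(exp[, "end"]))
  }
})

test_that("transcribed-region subtraction uses any-overlap semantics", {
  peaks <- GRanges("chr1", IRanges(c(100, 300, 502), width = 50))
  region <- GRanges("chr1", IRanges(90, 200))
  expect_equal(start(subtractTranscribed(peaks, region)), c(300, 502))
  # peak 1 bp outside is retained; 1 bp overlap removes
  r2 <- GRanges("chr1", IRanges(349, 501))
  kept <- subtractTranscribed(peaks, r2)
  expect_equal(start(kept), c(100, 502))
  # identities
  expect_equal(length(subtractTranscribed(peaks, GRanges())), 3)
  expect_length(subtractTranscribed(GRanges(), region), 0)

  set.seed(61)
  for (i in 1:30) {
    ps <- sample(2000, 20); rs <- sample(2000, 8)
    pk <- makeTags(ps, w = 30); rg <- makeTags(rs, w = 100)
    keep <- oracleOverlapCount(ps, ps + 29, rs, rs + 99) == 0
    expect_equal(start(subtractTranscribed(pk, rg)), ps[keep])
  }
})

test_that("positional classification matches the precedence oracle", {
  toy <- makeToyGenes()   # gA + [10001,18000], gB - [40001,52000]
  peaks <- GRanges("chr1", IRanges(c(
    10051,   # midpoint at TSS+75 of gA -> TSS
    14001,   # inside gA body -> gene_body
    5001,    # 5 kb 5' of gA -> upstream_10kb
    57001,   # 5 kb past gB's span end = 5' of "-" gene -> upstream_10kb
    35001,   # 5 kb before gB's span start = 3' side -> downstream_10kb
    80001),  # > 10 kb from anything -> intergenic
    width = 50))
  got <- positionalClassify(peaks, toy)
  expect_equal(as.character(got$positionalClass),
               c("TSS", "gene_body", "upstream_10kb", "upstream_10kb",
                 "downstream_10kb", "intergenic"))
  fr <- attr(got, "fractions")
  expect_equal(sum(fr), 1)

  # empty annotation: everything intergenic
  emptyG <- geneModelSet(GRanges(gene_id = character(0)), GRangesList())
  got0 <- positionalClassify(peaks, emptyG)
  expect_true(all(got0$positionalClass == "intergenic"))

  # permutation invariance + oracle on random peaks
  set.seed(67)
  gdf <- data.frame(start = start(genes(toy)), end = end(genes(toy)),
                    strand = as.character(strand(genes(toy))))
  mids <- sample(seq(25, 99000), 120)
  pk <- GRanges("chr1", IRanges(mids - 24, mids + 25))
  res <- positionalClassify(pk, toy)
  want <- vapply(floor((start(pk) + end(pk)) / 2), oracleClassify,
                 character(1), genes = gdf)
  expect_equal(as.character(res$positionalClass), want)
  perm <- sample(length(pk))
  res2 <- positionalClassify(pk[perm], toy)
  expect_equal(as.character(res2$positionalClass),
               as.character(res$positionalClass)[perm])
})

test_that("conservation enrichment recovers a planted contrast", {
  cs <- c(chr1 = 200000L)
  # candidates sit on conserved blocks, the rest of the track is low
  score <- rep(0.1, 200000)
  cand <- GRanges("chr1", IRanges(seq(10001, 90001, by = 10000),
                                  width = 200))
  for (i in seq_along(cand))
    score[(start(cand)[i] - 400):(end(cand)[i] + 400)] <- 0.95
  trk <- IRanges::RleList(chr1 = S4Vectors::Rle(score))
  r <- conservationEnrichment(cand, trk, cs, seed = 3L)
  expect_gt(r$logOdds, 1)
  expect_lt(r$p, 0.01)

  # null: candidates drawn from the same homogeneous track
  set.seed(71)
  flat <- IRanges::RleList(chr1 = S4Vectors::Rle(
    runif(200000) ))           # scores uniform in (0,1): 20% conserved
  los <- vapply(1:5, function(s) {
    rndCand <- GRanges("chr1", IRanges(sample(180000, 9) + 1000,
                                       width = 200))
    conservationEnrichment(rndCand, flat, cs, seed = s)$logOdds
  }, numeric(1))
  expect_lt(max(abs(los)), 0.25)
  expect_lt(abs(mean(los)), 0.1)
})

test_that("TF overlap enrichment matches hand arithmetic on a tiny genome", {
  cs <- c(chrT = 10000L)   # 10 bins of 1 kb
  cand <- GRanges("chrT", IRanges(c(101, 3101), width = 200))  # bins 1, 4
  tf <- GRanges("chrT", IRanges(c(151, 8101), width = 100))    # bins 1, 9
  r <- tfOverlapEnrichment(cand, list(TFX = tf), cs, bin = 1000)
  # table: a=1 (bin 1), b=1 (bin 4), c=1 (bin 9), d=7
  expect_equal(unlist(r$perTF[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 1, 1, 7))
  expect_equal(r$perTF$logOdds, log(7))
  expect_equal(r$subset, c(TRUE, FALSE))
  expect_warning(
    tfOverlapEnrichment(cand, list(TFX = tf, EMPTY = GRanges()), cs),
    "EMPTY")
})

test_that("planted enhancers drive positive conservation and TF enrichment", {
  okEnh <- 0; totEnh <- 0; inter <- 0; rec <- 0
  for (seed in 4:5) {
    cfg <- simConfig(seed = seed)
    genome <- buildGenome(cfg)
    cs <- genome$chromSizes
    polTags <- simulateLibrary(genome, "RNAPII", cfg)
    nucTags <- simulateLibrary(genome, "nucRNA", cfg)
    tracks <- simulateTracks(genome, cfg)
    cand <- subtractTranscribed(callPeaks(polTags, cs),
                                nucrnaRegions(nucTags))
    enh <- genome$truth[genome$truth$feature_kind == "enhancer_like"]
    hit <- overlapsAny(enh, cand)
    okEnh <- okEnh + sum(hit); totEnh <- totEnh + length(enh)
    recovered <- cand[overlapsAny(cand, enh)]
    pc <- positionalClassify(recovered, genome$genes)
    inter <- inter + sum(pc$positionalClass == "intergenic")
    rec <- rec + length(recovered)
    ce <- conservationEnrichment(cand, tracks$conservation, cs, seed = seed)
    expect_gt(ce$logOdds, 0)
    expect_lt(ce$p, 0.01)
    te <- tfOverlapEnrichment(cand, tracks$tfPeaks, cs)
    expect_gt(te$combined$logOdds, 0)
    expect_lt(te$combined$p, 0.01)
    expect_gte(sum(te$subset), sum(hit) - 1)
  }
  expect_gte(okEnh / totEnh, 0.8)
  expect_gte(inter / rec, 0.8)
})
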