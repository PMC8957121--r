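fx <- fixtureTiny()

test_that("gene percent methylation matches hand-computed fixture values", {
  mlt <- genePercentMethylation(fx$cpgReports, fx$genes, minGeneCov = 10)
  p <- pctMeth(mlt)
  # g1 in w1: six CpGs of (1,9) -> 6/60 = 10%
  expect_equal(p["g1", "w1"], 10)
  expect_equal(p["g1", "w3"], 20)
  # g2: 24/40 = 60% in condition A, 16/40 = 40% in condition B
  expect_equal(unname(p["g2", c("w1", "w2", "w3", "w4")]), c(60, 60, 40, 40))
  expect_equal(unname(p["g3", ]), rep(5, 4))
  expect_equal(unname(p["g4", ]), rep(50, 4))
  # gene with no CpG inside its bounds is missing everywhere
  expect_true(all(is.na(p["g_nil", ])))
  mp <- meanPctMeth(mlt)
  expect_equal(unname(mp[c("g1", "g2", "g3", "g4")]), c(15, 50, 5, 50))
  expect_true(is.na(mp["g_nil"]))
  # summed counts retained
  expect_equal(methCounts(mlt)["g1", "w1"], 6L)
  expect_equal(totalCoverage(mlt)["g1", "w1"], 60L)
})

test_that("two CpGs of (3,10) and (1,10) coverage pool to 20 percent", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 150), width = 1),
                               meth = c(3L, 1L), unmeth = c(7L, 9L))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 200), gene_id = "g1")
  names(genes) <- "g1"
  expect_equal(unname(pctMeth(genePercentMethylation(gr, genes, 0))[1, 1]), 20)
})

test_that("coverage filter and missing contigs produce missing cells", {
  mlt <- genePercentMethylation(fx$cpgReports, fx$genes, minGeneCov = 30)
  # g4 has summed coverage 20 per sample -> filtered at 30
  expect_true(all(is.na(pctMeth(mlt)["g4", ])))
  expect_equal(totalCoverage(mlt)["g4", "w1"], 20L)  # counts kept
  genes2 <- c(fx$genes, GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 100),
                                               gene_id = "gz"))
  names(genes2)[6] <- "gz"
  expect_warning(m2 <- genePercentMethylation(fx$cpgReports, genes2, 10),
                 "chrZ")
  expect_true(all(is.na(pctMeth(m2)["gz", ])))
})

test_that("quantification agrees with the quadratic brute-force oracle", {
  set.seed(421)
  for (rep in 1:25) {
    inst <- randomMethInstance()
    minCov <- sample(c(0, 5, 10), 1)
    mlt <- genePercentMethylation(inst$gr, inst$genes, minGeneCov = minCov)
    expect_equal(unname(pctMeth(mlt)[, 1]),
                 unname(oraclePctMeth(inst$cpgDf, inst$genes, minCov)))
  }
})

test_that("CpG input order never changes percent methylation", {
  set.seed(99)
  inst <- randomMethInstance()
  ref <- pctMeth(genePercentMethylation(inst$gr, inst$genes, 0))
  for (rep in 1:5) {
    perm <- sample(length(inst$gr))
    expect_equal(pctMeth(genePercentMethylation(inst$gr[perm], inst$genes, 0)),
                 ref)
  }
})

test_that("adding a methylated read never decreases a gene's percent", {
  set.seed(7)
  for (rep in 1:10) {
    inst <- randomMethInstance()
    before <- pctMeth(genePercentMethylation(inst$gr, inst$genes, 0))[, 1]
    i <- sample(length(inst$gr), 1)
    gr2 <- inst$gr
    S4Vectors::mcols(gr2)$meth[i] <- S4Vectors::mcols(gr2)$meth[i] + 1L
    after <- pctMeth(genePercentMethylation(gr2, inst$genes, 0))[, 1]
    both <- !is.na(before) & !is.na(after)
    expect_true(all(after[both] >= before[both] - 1e-12))
  }
})

test_that("log2 zero rule substitutes the dataset minimum non-zero value", {
  expect_equal(log2WithZeroRule(c(0, 2, 50)), c(1, 1, log2(50)))
  expect_equal(log2WithZeroRule(c(0, 0.5)), c(-1, -1))
  expect_equal(log2WithZeroRule(c(4, 8)), c(2, 3))     # no zeros: plain log2
  expect_equal(log2WithZeroRule(c(0, NA, 4)), c(2, NA, 2))
  expect_error(log2WithZeroRule(c(0, 0)), "all values are zero")
  expect_error(log2WithZeroRule(c(-1, 2)), "non-negative")
})

test_that("promoter windows are strand-aware, clipped, and disjoint from bodies", {
  genes <- GenomicRanges::GRanges(
    c("c1", "c1", "c1"), IRanges::IRanges(c(5000, 2000, 500), c(6000, 8000, 900)),
    strand = c("+", "-", "+"), gene_id = c("gp", "gm", "gclip"),
    seqlengths = c(c1 = 8500))
  names(genes) <- c("gp", "gm", "gclip")
  expect_warning(w <- promoterWindows(genes, 1000), NA)
  expect_equal(GenomicRanges::start(w["gp"]), 4000)
  expect_equal(GenomicRanges::end(w["gp"]), 4999)
  # minus strand: window downstream in coordinates, clipped at contig end
  expect_equal(GenomicRanges::start(w["gm"]), 8001)
  expect_equal(GenomicRanges::end(w["gm"]), 8500)
  expect_equal(GenomicRanges::start(w["gclip"]), 1)
  expect_equal(GenomicRanges::end(w["gclip"]), 499)
  # own-body disjointness
  ov <- GenomicRanges::findOverlaps(w, genes, ignore.strand = TRUE)
  same <- names(w)[S4Vectors::queryHits(ov)] ==
    names(genes)[S4Vectors::subjectHits(ov)]
  expect_false(any(same))
  # fully clipped window dropped with warning
  g0 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100), strand = "+",
                               gene_id = "g0")
  names(g0) <- "g0"
  expect_warning(w0 <- promoterWindows(g0, 1000), "dropped")
  expect_equal(length(w0), 0)
})

test_that("promoter quantification treats windows as independent intervals", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(4500, 7000), width = 1),
                               meth = c(5L, 2L), unmeth = c(5L, 2L))
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(5000, 4400), c(6000, 4600)),
                                  strand = "+", gene_id = c("gA", "gB"))
  names(genes) <- c("gA", "gB")
  w <- promoterWindows(genes, 1000)
  p <- pctMeth(promoterPercentMethylation(gr, w, minCov = 0))
  expect_equal(unname(p["gA", 1]), 50)   # gA window [4000,4999] holds the CpG
  expect_true(is.na(p["gB", 1]))         # gB window [3400,4399] empty
  # the CpG also sits inside gB's BODY: body and window counted independently
  pb <- pctMeth(genePercentMethylation(gr, genes, 0))
  expect_equal(unname(pb["gB", 1]), 50)
})

test_that("RPKM matches its closed form and is column-scale invariant", {
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 3001), c(2000, 4000)),
                                  gene_id = c("g1", "g2"))
  names(genes) <- c("g1", "g2")
  counts <- matrix(c(100L, 999900L, 7L, 999993L), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  r <- rpkm(counts, genes)
  expect_equal(r["g1", "s1"], 50)  # 100 / (2kb * 1M/1e6)
  expect_equal(rpkm(counts * 0L + c(0L, 10L), genes)["g1", ], c(s1 = 0, s2 = 0))
  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(rpois(20, 50) + 1L, 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(seq(1, 5e4, 1e4),
                                                      width = sample.int(5000, 5) + 100),
                                gene_id = rownames(m))
    names(g) <- rownames(m)
    r1 <- rpkm(m, g)
    m2 <- m; m2[, 2] <- m2[, 2] * 3L
    expect_equal(rpkm(m2, g)[, 2], r1[, 2])
    expect_equal(oracleRpkm(m, GenomicRanges::width(g)), r1)
  }
  expect_error(rpkm(matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "s")), genes),
               "zero library size")
})

test_that("MBD-score is the mean log2 captured/unbound RPKM ratio", {
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 2001), width = 1000),
                                  gene_id = c("g1", "g2"))
  names(genes) <- c("g1", "g2")
  # equal library sizes; captured = 4x unbound for g1, equal for g2
  counts <- matrix(c(80L, 120L, 20L, 180L), 2,
                   dimnames = list(c("g1", "g2"), c("m1.captured", "m1.unbound")))
  sc <- mbdScore(counts, genes, pseudocount = 0)
  expect_equal(sc$mbd_score[1], 2)
  expect_equal(sc$mbd_score[2], log2(120 / 180))
  # identical fractions -> all-zero scores, any pseudocount
  same <- cbind(counts[, 1, drop = FALSE],
                "m1.unbound" = counts[, 1])
  expect_equal(mbdScore(same, genes, pseudocount = 1)$mbd_score, c(0, 0))
  # all-zero counts with equal library sizes: pseudocount cancels -> 0
  z <- matrix(0L, 2, 2, dimnames = list(c("g1", "g2"),
                                        c("m1.captured", "m1.unbound")))
  expect_equal(mbdScore(z, genes, pseudocount = 1)$mbd_score, c(0, 0))
  # oracle equivalence with multiple pairs
  set.seed(5)
  cm <- matrix(rpois(8, 40), 2, 4,
               dimnames = list(c("g1", "g2"),
                               c("a.captured", "a.unbound",
                                 "b.captured", "b.unbound")))
  got <- mbdScore(cm, genes, pseudocount = 1)$mbd_score
  want <- oracleMbdScore(cm[, c(1, 3)], cm[, c(2, 4)],
                         GenomicRanges::width(genes), 1)
  expect_equal(got, unname(want))
  expect_error(mbdScore(cm[, 1:3], genes), "unpaired")
})

test_that("genomic coverage estimate is the scaled read-length ratio", {
  expect_equal(estimateGenomicCoverage(1e6, 200, 2e8), 1)
  expect_equal(estimateGenomicCoverage(5e6, 300, 3e8), 5)
  expect_equal(estimateGenomicCoverage(2e6, 200, 2e8),
               2 * estimateGenomicCoverage(1e6, 200, 2e8))
  expect_error(estimateGenomicCoverage(1e6, 200, 0), "positive")
})
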