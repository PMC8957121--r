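condMap <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")

mltFrom <- function(meth, cov, minCov = 0) {
  dimnames(meth) <- dimnames(cov) <-
    list(paste0("g", seq_len(nrow(meth))), names(condMap)[seq_len(ncol(meth))])
  MethLevelTable(meth, cov, minCov = minCov)
}

test_that("identical methylation in both conditions gives zero effect, p = 1", {
  meth <- matrix(5L, 3, 4); cov <- matrix(50L, 3, 4)
  res <- diffMethylation(mltFrom(meth, cov), condMap, "A", "B")
  expect_equal(res$meth_diff, rep(0, 3))
  expect_equal(res$log2_meth_ratio, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_true(all(res$tested))
})

test_that("pooled 10/100 vs 20/100 gives +10 points and the binomial LRT p", {
  meth <- matrix(c(10L, 20L), 1)
  cov <- matrix(c(100L, 100L), 1)
  dimnames(meth) <- dimnames(cov) <- list("g1", c("s1", "s3"))
  mlt <- MethLevelTable(meth, cov, minCov = 0)
  res <- diffMethylation(mlt, condMap, "A", "B")
  expect_equal(res$meth_diff, 10)
  expect_equal(res$log2_meth_ratio,
               log2((20.5 / 101) / (10.5 / 101)))
  # independent glm-based LRT
  expect_equal(res$p_value, oracleBinomLrtP(10L, 100L, 20L, 100L),
               tolerance = 1e-8)
  # order of magnitude agrees with Fisher's exact test on the pooled 2x2
  fp <- fisher.test(matrix(c(10, 90, 20, 80), 2))$p.value
  expect_lt(abs(log10(res$p_value) - log10(fp)), 1)
})

test_that("binomial LRT matches the glm oracle on random instances", {
  set.seed(314)
  for (rep in 1:20) {
    cov <- matrix(rpois(8, 40) + 1L, 2, 4)
    meth <- matrix(rbinom(8, as.vector(cov), runif(2)), 2, 4)
    res <- diffMethylation(mltFrom(meth, cov), condMap, "A", "B")
    for (g in 1:2) {
      # at complete separation the bounded-logit convention and glm's own
      # convergence bound differ in the far tail; elsewhere they agree
      tol <- if (res$boundary[g]) 1e-3 else 1e-6
      expect_equal(res$p_value[g],
                   oracleBinomLrtP(meth[g, 1:2], cov[g, 1:2],
                                   meth[g, 3:4], cov[g, 3:4]),
                   tolerance = tol)
    }
  }
})

test_that("complete separation yields a finite flagged p-value", {
  meth <- matrix(c(0L, 0L, 30L, 30L), 1)
  cov <- matrix(30L, 1, 4)
  res <- diffMethylation(mltFrom(meth, cov), condMap, "A", "B")
  expect_true(res$boundary)
  expect_true(is.finite(res$p_value) && res$p_value > 0)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$meth_diff, 100)
})

test_that("a condition without eligible samples leaves the gene untested", {
  meth <- matrix(c(1L, 1L, 5L, 5L), 1)
  cov <- matrix(c(4L, 4L, 50L, 50L), 1)   # condition A below min cov 10
  res <- diffMethylation(mltFrom(meth, cov, minCov = 10), condMap, "A", "B")
  expect_false(res$tested)
  expect_true(is.na(res$p_value) && is.na(res$q_value) &&
                is.na(res$meth_diff))
})

test_that("swapping contrast labels negates effects, p-values unchanged", {
  set.seed(8)
  cov <- matrix(rpois(40, 60) + 1L, 10, 4)
  meth <- matrix(rbinom(40, as.vector(cov), rep(runif(10, 0.05, 0.8), 4)), 10, 4)
  a <- diffMethylation(mltFrom(meth, cov), condMap, "A", "B")
  b <- diffMethylation(mltFrom(meth, cov), condMap, "B", "A")
  expect_equal(a$meth_diff, -b$meth_diff, tolerance = 1e-12)
  expect_equal(a$log2_meth_ratio, -b$log2_meth_ratio, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  # expression side
  cnt <- matrix(rnbinom(40, mu = 100, size = 5), 10, 4,
                dimnames = list(paste0("g", 1:10), names(condMap)))
  ea <- diffExpression(cnt, condMap, "A", "B")
  eb <- diffExpression(cnt, condMap, "B", "A")
  expect_equal(ea$log2_fold_change, -eb$log2_fold_change, tolerance = 1e-9)
  expect_equal(ea$p_value, eb$p_value, tolerance = 1e-9)
})

test_that("pearson overdispersion correction shrinks the test statistic", {
  set.seed(21)
  # strongly overdispersed per-sample proportions
  p <- matrix(runif(4 * 50, 0.05, 0.6), 50, 4)
  cov <- matrix(200L, 50, 4)
  meth <- matrix(rbinom(200, 200, as.vector(p)), 50, 4)
  none <- diffMethylation(mltFrom(meth, cov), condMap, "A", "B", "none")
  pear <- diffMethylation(mltFrom(meth, cov), condMap, "A", "B", "pearson")
  expect_true(all(pear$p_value >= none$p_value - 1e-12))
  expect_gt(mean(pear$p_value), mean(none$p_value))
})

test_that("size factors match the median-of-ratios closed form", {
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(sizeFactors(m)), c(1 / sqrt(2), sqrt(2)))
  same <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  expect_equal(unname(sizeFactors(same)), rep(1, 3))
  # scaling one column by 3 triples its factor relative to the others
  # (the absolute factors all shift because the row geometric means move
  # by 3^(1/n))
  m3 <- m; m3[, 2] <- m3[, 2] * 3L
  sf <- sizeFactors(m); sf3 <- sizeFactors(m3)
  expect_equal(sf3[[2]] / sf3[[1]], 3 * sf[[2]] / sf[[1]])
})

test_that("size factors agree with the independent oracle and DESeq2", {
  set.seed(2024)
  for (rep in 1:10) {
    m <- matrix(rnbinom(200, mu = 80, size = 2) + 1L, 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
    sf <- sizeFactors(m)
    expect_equal(unname(sf), unname(oracleSizeFactors(m)))
  }
  # odd gene count: the ratio-scale median then coincides exactly with
  # DESeq2's exp(median(log ratio)) convention
  m <- matrix(rnbinom(404, mu = 100, size = 2) + 1L, 101, 4,
              dimnames = list(paste0("g", 1:101), paste0("s", 1:4)))
  expect_equal(unname(sizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-9)
})

test_that("differential expression null identity and log-fold arithmetic", {
  cnt <- matrix(rep(c(30L, 80L, 0L), 4), 3, 4,
                dimnames = list(paste0("g", 1:3), names(condMap)))
  res <- diffExpression(cnt, condMap, "A", "B", minTotal = 10)
  expect_equal(res$log2_fold_change[1:2], c(0, 0))
  expect_equal(res$p_value[1:2], c(1, 1))
  expect_false(res$tested[3])  # total 0 < minTotal and both means zero
  # condition means 10 vs 40 with pseudocount 0 -> log2FC exactly 2
  # (a flat background keeps the size factors at 1 so normalized means
  # equal raw means)
  flat <- matrix(rep(c(50L, 200L, 35L), 4), 3, 4)
  cnt2 <- rbind(flat, c(10L, 10L, 40L, 40L))
  dimnames(cnt2) <- list(paste0("g", 1:4), names(condMap))
  r2 <- diffExpression(cnt2, condMap, "A", "B", pseudocount = 0)
  expect_equal(unname(sizeFactors(cnt2)), rep(1, 4))
  expect_equal(r2$log2_fold_change[4], 2)
})

test_that("differential expression recovers planted fold changes", {
  set.seed(77)
  G <- 2000; n <- 6
  # mostly-null transcriptome with 10% planted |log2FC| = 1 genes, so the
  # median-of-ratios normalization is anchored by unchanged genes
  lfc <- rep(0, G)
  lfc[seq_len(G / 10)] <- sample(c(-1, 1), G / 10, replace = TRUE)
  mu1 <- rep(100, G); mu2 <- mu1 * 2^lfc
  cnt <- cbind(matrix(rnbinom(G * n, mu = mu1, size = 5), G),
               matrix(rnbinom(G * n, mu = mu2, size = 5), G))
  dimnames(cnt) <- list(paste0("g", 1:G),
                        paste0("s", 1:(2 * n)))
  cm <- setNames(rep(c("A", "B"), each = n), colnames(cnt))
  res <- diffExpression(cnt, cm, "A", "B")
  planted <- lfc != 0
  # estimator bias (mean error within each planted direction) is small even
  # though single-gene estimates carry NB sampling noise
  expect_lt(abs(mean(res$log2_fold_change[lfc == 1] - 1)), 0.1)
  expect_lt(abs(mean(res$log2_fold_change[lfc == -1] + 1)), 0.1)
  # planted genes are detected, null genes essentially are not
  expect_gt(mean(res$q_value[planted] < 0.1), 0.1)
  expect_lt(mean(res$q_value[!planted] < 0.1, na.rm = TRUE), 0.02)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bhFDR(0.037), 0.037)
  expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFDR(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
  set.seed(600)
  for (rep in 1:100) {
    p <- runif(sample.int(200, 1))
    expect_equal(bhFDR(p), oracleBH(p))
  }
})

test_that("q-values never fall below p-values and never select more genes", {
  set.seed(61)
  for (rep in 1:10) {
    p <- runif(100)^2
    q <- bhFDR(p)
    expect_true(all(q >= p - 1e-12))
    for (a in c(0.01, 0.05, 0.1)) {
      expect_lte(sum(q <= a), sum(p <= a))
    }
  }
})
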