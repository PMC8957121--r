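# Independent brute-force oracles, deliberately written in the most direct
# style possible (loops, closed forms) so they share no code path with the
# package implementation.

# quadratic scan: every CpG checked against every interval
oraclePctMeth <- function(cpgDf, genes, minCov) {
  # cpgDf: data.frame(chrom, pos, meth, unmeth) for ONE sample
  chrom <- as.character(GenomicRanges::seqnames(genes))
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  out <- rep(NA_real_, length(genes))
  for (g in seq_along(genes)) {
    inG <- cpgDf$chrom == chrom[g] & cpgDf$pos >= gs[g] & cpgDf$pos <= ge[g]
    m <- sum(cpgDf$meth[inG])
    cv <- m + sum(cpgDf$unmeth[inG])
    if (cv > 0 && cv >= minCov) out[g] <- 100 * m / cv
  }
  names(out) <- names(genes)
  out
}

# step-up enumeration of the BH adjustment
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q
}

oracleRpkm <- function(counts, lengths) {
  out <- counts * NA_real_
  lib <- colSums(counts)
  for (g in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      out[g, s] <- counts[g, s] / ((lengths[g] / 1000) * (lib[s] / 1e6))
    }
  }
  out
}

oracleSizeFactors <- function(counts) {
  gm <- apply(counts, 1, function(r) exp(mean(log(r))))
  use <- is.finite(gm) & gm > 0
  apply(counts, 2, function(cnt) median((cnt / gm)[use & cnt > 0]))
}

oracleMbdScore <- function(capt, unb, lengths, pseudocount) {
  # capt/unb: gene x pair matrices of counts, same pairing order
  rp <- function(m) oracleRpkm(m + pseudocount, lengths)
  rc <- rp(capt); ru <- rp(unb)
  rowMeans(log2(rc) - log2(ru))
}

# per-gene binomial GLM LRT via stats::glm, the reference implementation
oracleBinomLrtP <- function(meth1, cov1, meth2, cov2) {
  m <- c(meth1, meth2)
  cv <- c(cov1, cov2)
  cond <- factor(rep(c("a", "b"), c(length(meth1), length(meth2))))
  keep <- cv > 0
  fit1 <- suppressWarnings(glm(cbind(m, cv - m)[keep, , drop = FALSE] ~
                                 cond[keep], family = binomial))
  fit0 <- suppressWarnings(glm(cbind(m, cv - m)[keep, , drop = FALSE] ~ 1,
                               family = binomial))
  pchisq(fit0$deviance - fit1$deviance, df = 1, lower.tail = FALSE)
}

# build a MethLevelTable straight from summed count matrices
makeMlt <- function(meth, cov, minCov = 0) {
  MethLevelTable(meth, cov, minCov = minCov)
}

# random small CpG/gene instance for oracle-equivalence checks
randomMethInstance <- function(nGenes = 8, nCpg = 80, nContigs = 2) {
  contigs <- paste0("c", seq_len(nContigs))
  gs <- sample.int(5000, nGenes)
  genes <- GenomicRanges::GRanges(
    sample(contigs, nGenes, replace = TRUE),
    IRanges::IRanges(gs, width = sample.int(800, nGenes) + 50),
    strand = sample(c("+", "-"), nGenes, replace = TRUE),
    gene_id = paste0("g", seq_len(nGenes))
  )
  names(genes) <- paste0("g", seq_len(nGenes))
  cpgDf <- data.frame(
    chrom = sample(contigs, nCpg, replace = TRUE),
    pos = sample.int(6000, nCpg, replace = TRUE),
    meth = rpois(nCpg, 3), unmeth = rpois(nCpg, 7)
  )
  gr <- GenomicRanges::GRanges(cpgDf$chrom,
                               IRanges::IRanges(cpgDf$pos, width = 1),
                               strand = "+",
                               meth = cpgDf$meth, unmeth = cpgDf$unmeth)
  list(genes = genes, cpgDf = cpgDf, gr = gr)
}
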