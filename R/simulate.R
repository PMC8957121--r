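# Synthetic methylome-transcriptome studies with planted, recoverable
# parameters: per-CpG bisulfite counts, gene models, RNA-seq / MBD-seq /
# mdRAD count matrices, a sample sheet, and a truth table.

#' Construct a synthetic-study configuration
#'
#' All arguments have defaults describing the study conditions the analysis
#' assumes: bimodal gene body methylation (a lowly methylated class, Beta
#' mean 1\% with concentration 50, and a highly methylated class, Beta mean
#' 60\% with concentration 10, in proportion \code{propHigh}), expression
#' increasing with methylation, negative-binomial dispersion (hence
#' transcriptional variability) decreasing with methylation, and optional
#' condition-2 effects: per-gene methylation shifts on the logit scale and
#' expression shifts on the log2 scale, each the sum of a class-level
#' "seesaw" mean and gene-level noise, with a latent-Gaussian coupling of
#' strength \code{deltaCouplingRho} between the two (each loads
#' \code{sqrt(|rho|)} on a shared standard normal, so the planted
#' change-change correlation converges to \code{rho}).
#'
#' @param nGenes number of genes (default 2000).
#' @param nContigs contigs genes are spread over (default 10).
#' @param geneLengthMedian,geneLengthLogSd log-normal gene length
#'   parameters (median 2000 bp, log-sd 0.6).
#' @param cpgsPerKb mean CpG density within genes (default 20 per kb).
#' @param intergenicFrac fraction of all CpGs placed between genes
#'   (default 0.1), exercising window logic against off-gene records.
#' @param propHigh fraction of genes in the highly methylated class
#'   (default 0.4).
#' @param lowMethMean,lowMethConc,highMethMean,highMethConc Beta mean and
#'   concentration of the class baseline methylation probabilities.
#' @param coveragePerCpg Poisson mean per-CpG per-sample coverage
#'   (default 30).
#' @param nPerCondition samples per condition per assay (default 3).
#' @param exprIntercept mean log2 RPKM at the average methylation level
#'   (default 5).
#' @param exprSlopeVsGbm log2 RPKM per log2(percent methylation)
#'   (default 0.3).
#' @param exprBaselineSd gene-level log2 RPKM noise sd (default 1).
#' @param exprDispersionLow,exprDispersionHigh NB dispersions of the low
#'   and high class (defaults 0.2 and 0.05, making expression variability
#'   fall with methylation).
#' @param rnaLibSize nominal RNA library size used to scale counts
#'   (default 2e6).
#' @param deltaCouplingRho planted correlation between per-gene methylation
#'   and expression changes, in [-1, 1] (default 0, the null).
#' @param deltaGbmSd,deltaExprSd gene-level sd of the condition-2 shifts
#'   (logit scale, default 0.5, and log2 scale, default 1). On the logit
#'   scale 0.5 moves a 60\%-methylated gene by roughly 12 percentage
#'   points at one sd, already a generous per-gene response; see the
#'   methods vignette for how this choice trades off against recovery of
#'   the planted change-change coupling.
#' @param seesawDeltaGbmHigh,seesawDeltaGbmLow class-level mean methylation
#'   shifts, logit scale (defaults 0). The canonical planted seesaw used in
#'   validation is (-0.4, +0.4): the high class loses and the low class
#'   gains methylation, as in the transplant observation the seesaw
#'   hypothesis came from.
#' @param seesawDeltaExprHigh,seesawDeltaExprLow class-level mean
#'   expression shifts, log2 scale (defaults 0; canonical planted values
#'   (+0.5, -0.5)).
#' @param mbdDepth,mdradDepth Poisson depth scale for the MBD fractions and
#'   mdRAD counts (defaults 50 and 30 reads per kb).
#' @param seed single integer seed driving all randomness (default 1).
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000, nContigs = 10,
                      geneLengthMedian = 2000, geneLengthLogSd = 0.6,
                      cpgsPerKb = 20, intergenicFrac = 0.1,
                      propHigh = 0.4,
                      lowMethMean = 0.01, lowMethConc = 50,
                      highMethMean = 0.6, highMethConc = 10,
                      coveragePerCpg = 30, nPerCondition = 3,
                      exprIntercept = 5, exprSlopeVsGbm = 0.3,
                      exprBaselineSd = 1,
                      exprDispersionLow = 0.2, exprDispersionHigh = 0.05,
                      rnaLibSize = 2e6,
                      deltaCouplingRho = 0,
                      deltaGbmSd = 0.5, deltaExprSd = 1,
                      seesawDeltaGbmHigh = 0, seesawDeltaGbmLow = 0,
                      seesawDeltaExprHigh = 0, seesawDeltaExprLow = 0,
                      mbdDepth = 50, mdradDepth = 30,
                      seed = 1) {
  new("SimConfig", nGenes = as.integer(nGenes),
      nContigs = as.integer(nContigs),
      geneLengthMedian = geneLengthMedian, geneLengthLogSd = geneLengthLogSd,
      cpgsPerKb = cpgsPerKb, intergenicFrac = intergenicFrac,
      propHigh = propHigh,
      lowMethMean = lowMethMean, lowMethConc = lowMethConc,
      highMethMean = highMethMean, highMethConc = highMethConc,
      coveragePerCpg = coveragePerCpg,
      nPerCondition = as.integer(nPerCondition),
      exprIntercept = exprIntercept, exprSlopeVsGbm = exprSlopeVsGbm,
      exprBaselineSd = exprBaselineSd,
      exprDispersionLow = exprDispersionLow,
      exprDispersionHigh = exprDispersionHigh,
      rnaLibSize = rnaLibSize,
      deltaCouplingRho = deltaCouplingRho,
      deltaGbmSd = deltaGbmSd, deltaExprSd = deltaExprSd,
      seesawDeltaGbmHigh = seesawDeltaGbmHigh,
      seesawDeltaGbmLow = seesawDeltaGbmLow,
      seesawDeltaExprHigh = seesawDeltaExprHigh,
      seesawDeltaExprLow = seesawDeltaExprLow,
      mbdDepth = mbdDepth, mdradDepth = mdradDepth,
      seed = as.integer(seed))
}

# deterministic sub-seed for one generator component
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

betaAB <- function(mean, conc) c(a = mean * conc, b = (1 - mean) * conc)

#' Simulate a full synthetic study
#'
#' Places non-overlapping genes on contigs, draws each gene's methylation
#' class and baseline methylation probability, plants condition-2 shifts
#' (class seesaw mean + coupled gene noise; see [simConfig()]), and emits
#' per-sample per-CpG binomial bisulfite counts, negative-binomial RNA-seq
#' counts, Poisson MBD captured/unbound and mdRAD counts, a sample sheet,
#' and the truth table used by parameter-recovery tests. All randomness
#' derives from \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outdir optional directory; when given, every component is written
#'   in the file dialects the readers consume (cytosine reports, GFF3,
#'   count TSVs, sample sheet, truth table, resolved YAML config).
#' @return invisibly when writing, else directly: a list with elements
#'   \code{genes} (GRanges), \code{cpgReports} (named list of GRanges, one
#'   per WGBS sample), \code{counts} (list: rnaseq, mbd, mdrad matrices),
#'   \code{sampleSheet}, \code{truth}, \code{config}.
#' @export
simulateStudy <- function(config, outdir = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nG <- config@nGenes; nC <- config@nContigs
  n <- config@nPerCondition

  # --- structure: lengths, placement, classes, baselines, deltas ---------
  str <- withSeed(subSeed(config@seed, 1), {
    len <- pmax(200L, as.integer(round(rlnorm(nG, log(config@geneLengthMedian),
                                              config@geneLengthLogSd))))
    contig <- rep_len(seq_len(nC), nG)
    gap <- as.integer(runif(nG, 500, 2000))
    start <- integer(nG)
    for (ct in seq_len(nC)) {
      i <- which(contig == ct)
      start[i] <- cumsum(c(1500L, head(len[i] + gap[i], -1))) + 1000L
    }
    cls <- ifelse(runif(nG) < config@propHigh, "high", "low")
    lo <- betaAB(config@lowMethMean, config@lowMethConc)
    hi <- betaAB(config@highMethMean, config@highMethConc)
    p0 <- ifelse(cls == "high", rbeta(nG, hi["a"], hi["b"]),
                 rbeta(nG, lo["a"], lo["b"]))
    p0 <- pmin(pmax(p0, 1e-5), 1 - 1e-5)
    rho <- config@deltaCouplingRho
    z <- rnorm(nG); e1 <- rnorm(nG); e2 <- rnorm(nG)
    lg <- sqrt(abs(rho))
    dG <- ifelse(cls == "high", config@seesawDeltaGbmHigh,
                 config@seesawDeltaGbmLow) +
      config@deltaGbmSd * (lg * z + sqrt(1 - abs(rho)) * e1)
    dE <- ifelse(cls == "high", config@seesawDeltaExprHigh,
                 config@seesawDeltaExprLow) +
      config@deltaExprSd * (sign(rho) * lg * z + sqrt(1 - abs(rho)) * e2)
    list(len = len, contig = contig, start = start, cls = cls, p0 = p0,
         dG = dG, dE = dE)
  })
  geneIds <- sprintf("g%05d", seq_len(nG))
  contigNames <- sprintf("contig%02d", str$contig)
  contigLens <- vapply(seq_len(nC), function(ct) {
    i <- which(str$contig == ct)
    max(str$start[i] + str$len[i]) + 2000L
  }, 0)
  names(contigLens) <- sprintf("contig%02d", seq_len(nC))
  genes <- GRanges(contigNames,
                   IRanges(str$start, width = str$len),
                   strand = rep_len(c("+", "-"), nG),
                   gene_id = geneIds,
                   seqlengths = contigLens)
  names(genes) <- geneIds
  p2 <- plogis(qlogis(str$p0) + str$dG)

  # --- CpG map: fixed positions shared by all samples --------------------
  cpgMap <- withSeed(subSeed(config@seed, 2), {
    nCpg <- pmax(1L, rpois(nG, str$len / 1000 * config@cpgsPerKb))
    pos <- unlist(lapply(seq_len(nG), function(g) {
      str$start[g] - 1L + sort(sample.int(str$len[g], min(nCpg[g], str$len[g])))
    }))
    geneIdx <- rep(seq_len(nG), pmin(nCpg, str$len))
    nInter <- round(sum(nCpg) * config@intergenicFrac /
                      (1 - config@intergenicFrac))
    ict <- sample.int(nC, nInter, replace = TRUE)
    ipos <- as.integer(runif(nInter, 1, contigLens[ict]))
    igr <- GRanges(names(contigLens)[ict], IRanges(ipos, width = 1))
    igr <- igr[!IRanges::overlapsAny(igr, genes, ignore.strand = TRUE)]
    lo <- betaAB(config@lowMethMean, config@lowMethConc)
    ip <- pmin(pmax(rbeta(length(igr), lo["a"], lo["b"]), 1e-5), 1 - 1e-5)
    gr <- c(GRanges(contigNames[geneIdx], IRanges(pos, width = 1)), igr)
    pA <- c(str$p0[geneIdx], ip)
    pB <- c(p2[geneIdx], ip)
    o <- order(as.character(seqnames(gr)), start(gr))
    list(gr = gr[o], pA = pA[o], pB = pB[o])
  })
  strand(cpgMap$gr) <- rep_len(c("+", "-"), length(cpgMap$gr))

  # --- WGBS counts per sample --------------------------------------------
  wgbsIds <- c(sprintf("wgbs_ctrl_%d", seq_len(n)),
               sprintf("wgbs_trt_%d", seq_len(n)))
  cpgReports <- withSeed(subSeed(config@seed, 3), {
    nS <- length(cpgMap$gr)
    out <- lapply(seq_along(wgbsIds), function(s) {
      p <- if (s <= n) cpgMap$pA else cpgMap$pB
      cov <- rpois(nS, config@coveragePerCpg)
      meth <- rbinom(nS, cov, p)
      gr <- cpgMap$gr
      mcols(gr)$meth <- meth
      mcols(gr)$unmeth <- cov - meth
      gr
    })
    setNames(out, wgbsIds)
  })

  # --- RNA-seq counts ----------------------------------------------------
  rnaIds <- c(sprintf("rna_ctrl_%d", seq_len(n)),
              sprintf("rna_trt_%d", seq_len(n)))
  lenKb <- str$len / 1000
  log2rpkm0 <- withSeed(subSeed(config@seed, 4), {
    lp <- log2(100 * str$p0)
    config@exprIntercept + config@exprSlopeVsGbm * (lp - mean(lp)) +
      rnorm(nG, 0, config@exprBaselineSd)
  })
  disp <- ifelse(str$cls == "high", config@exprDispersionHigh,
                 config@exprDispersionLow)
  rnaCounts <- withSeed(subSeed(config@seed, 5), {
    m <- vapply(seq_along(rnaIds), function(s) {
      lfc <- if (s <= n) 0 else str$dE
      mu <- 2^(log2rpkm0 + lfc) * lenKb * config@rnaLibSize / 1e6
      rnbinom(nG, mu = mu, size = 1 / disp)
    }, numeric(nG))
    dimnames(m) <- list(geneIds, rnaIds)
    storage.mode(m) <- "integer"
    m
  })

  truth <- data.frame(
    gene_id = geneIds, true_class = str$cls,
    true_baseline_meth = str$p0, true_delta_meth = str$dG,
    true_log2_expr = log2rpkm0, true_delta_log2_expr = str$dE,
    row.names = NULL
  )

  mbdCounts <- withSeed(subSeed(config@seed, 6),
                        simulateMbdCounts(truth, genes, config))
  mdradCounts <- withSeed(subSeed(config@seed, 7), {
    ids <- c(sprintf("mdrad_ctrl_%d", seq_len(n)),
             sprintf("mdrad_trt_%d", seq_len(n)))
    m <- vapply(seq_along(ids), function(s) {
      p <- if (s <= n) str$p0 else p2
      rpois(nG, config@mdradDepth * lenKb * (0.02 + p))
    }, numeric(nG))
    dimnames(m) <- list(geneIds, ids)
    storage.mode(m) <- "integer"
    m
  })

  mbdBio <- c(sprintf("mbd_ctrl_%d", seq_len(n)),
              sprintf("mbd_trt_%d", seq_len(n)))
  sampleSheet <- rbind(
    data.frame(sample_id = wgbsIds,
               condition = rep(c("ctrl", "trt"), each = n),
               assay = "wgbs", fraction = "none",
               is_control = rep(c(TRUE, FALSE), each = n)),
    data.frame(sample_id = rnaIds,
               condition = rep(c("ctrl", "trt"), each = n),
               assay = "rnaseq", fraction = "none",
               is_control = rep(c(TRUE, FALSE), each = n)),
    data.frame(sample_id = rep(mbdBio, 2),
               condition = rep(rep(c("ctrl", "trt"), each = n), 2),
               assay = "mbd",
               fraction = rep(c("captured", "unbound"), each = 2 * n),
               is_control = rep(rep(c(TRUE, FALSE), each = n), 2)),
    data.frame(sample_id = colnames(mdradCounts),
               condition = rep(c("ctrl", "trt"), each = n),
               assay = "mdrad", fraction = "none",
               is_control = rep(c(TRUE, FALSE), each = n))
  )

  study <- list(genes = genes, cpgReports = cpgReports,
                counts = list(rnaseq = rnaCounts, mbd = mbdCounts,
                              mdrad = mdradCounts),
                sampleSheet = sampleSheet, truth = truth, config = config)
  if (is.null(outdir)) return(study)
  writeStudy(study, outdir)
  invisible(study)
}

#' Simulate MBD-seq captured/unbound count pairs
#'
#' Captured-fraction means rise with the gene's methylation probability and
#' length; unbound-fraction means fall with it; counts are Poisson. The
#' expected MBD-score ([mbdScore()]) is therefore monotone increasing in
#' the true baseline methylation.
#'
#' @param truth truth table from [simulateStudy()] (columns
#'   \code{true_baseline_meth}, \code{true_delta_meth}).
#' @param genes gene models (for lengths), named as \code{truth$gene_id}.
#' @param config a \linkS4class{SimConfig}.
#' @return integer matrix with columns \code{<sample>.captured} /
#'   \code{<sample>.unbound} for \code{nPerCondition} samples per condition.
#' @export
simulateMbdCounts <- function(truth, genes, config) {
  n <- config@nPerCondition
  lenKb <- width(genes)[match(truth$gene_id, names(genes))] / 1000
  p0 <- truth$true_baseline_meth
  p2 <- plogis(qlogis(p0) + truth$true_delta_meth)
  ids <- c(sprintf("mbd_ctrl_%d", seq_len(n)),
           sprintf("mbd_trt_%d", seq_len(n)))
  cols <- c(paste0(ids, ".captured"), paste0(ids, ".unbound"))
  m <- matrix(0L, nrow(truth), length(cols),
              dimnames = list(truth$gene_id, cols))
  for (s in seq_along(ids)) {
    p <- if (s <= n) p0 else p2
    muC <- config@mbdDepth * lenKb * (0.05 + 0.95 * p)
    muU <- config@mbdDepth * lenKb * (1.05 - 0.95 * p)
    m[, paste0(ids[s], ".captured")] <- rpois(nrow(truth), muC)
    m[, paste0(ids[s], ".unbound")] <- rpois(nrow(truth), muU)
  }
  m
}

#' Write a simulated study to disk in the standard dialects
#'
#' @param study list from [simulateStudy()].
#' @param outdir output directory (created if needed).
#' @return invisibly, \code{outdir}.
#' @export
writeStudy <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeGeneModels(study$genes, file.path(outdir, "genes.gff3"))
  for (s in names(study$cpgReports)) {
    writeCytosineReport(study$cpgReports[[s]],
                        file.path(outdir, paste0(s, ".cytosine_report.tsv")))
  }
  for (assay in intersect(c("rnaseq", "mbd", "mdrad"), names(study$counts))) {
    writeCountMatrix(study$counts[[assay]],
                     file.path(outdir, paste0(assay, "_counts.tsv")))
  }
  writeResultTable(study$sampleSheet, file.path(outdir, "sample_sheet.tsv"))
  if (!is.null(study$truth)) {
    writeResultTable(study$truth, file.path(outdir, "truth.tsv"))
  }
  if (!is.null(study$config)) {
    sns <- slotNames(study$config)
    cfg <- setNames(lapply(sns, function(sn) methods::slot(study$config, sn)),
                    sns)
    yaml::write_yaml(cfg, file.path(outdir, "sim_config.yaml"))
  }
  invisible(outdir)
}

#' Read a simulated study back from disk
#'
#' @param dir directory written by [simulateStudy()] / [writeStudy()].
#' @return a study list as returned by [simulateStudy()] (without config).
#' @export
readStudy <- function(dir) {
  genes <- readGeneModels(file.path(dir, "genes.gff3"), "gff3")
  sheet <- readSampleSheet(file.path(dir, "sample_sheet.tsv"))
  wgbs <- sheet$sample_id[sheet$assay == "wgbs"]
  reports <- lapply(file.path(dir, paste0(wgbs, ".cytosine_report.tsv")),
                    readCytosineReport)
  names(reports) <- wgbs
  counts <- list()
  for (assay in c("rnaseq", "mbd", "mdrad")) {
    f <- file.path(dir, paste0(assay, "_counts.tsv"))
    if (file.exists(f)) counts[[assay]] <- readCountMatrix(f)
  }
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath)) readResultTable(truthPath) else NULL
  list(genes = genes, cpgReports = reports, counts = counts,
       sampleSheet = sheet, truth = truth)
}

#' A hand-enumerable micro-study
#'
#' Five genes (one, \code{g_nil}, with no CpGs at all), 18 CpG sites, and
#' 2 + 2 samples per assay, with every count written out by hand so each
#' intermediate value of the pipeline can be verified against mental
#' arithmetic. Used as the brute-force anchor for the quantification
#' operations.
#'
#' @return a study list shaped like [simulateStudy()] output (no truth
#'   table, \code{config = NULL}).
#' @export
fixtureTiny <- function() {
  contigLens <- c(chrA = 20000, chrB = 10000)
  genes <- GRanges(c("chrA", "chrA", "chrB", "chrB", "chrA"),
                   IRanges(start = c(1001, 5001, 1001, 3001, 9001),
                           end = c(2000, 7000, 1500, 4000, 9500)),
                   strand = c("+", "-", "+", "-", "+"),
                   gene_id = c("g1", "g2", "g3", "g4", "g_nil"),
                   seqlengths = contigLens)
  names(genes) <- mcols(genes)$gene_id
  # CpG positions (fixed across samples): 6 in g1, 4 in g2, 4 in g3,
  # 2 in g4, 2 intergenic (chrA 4000, chrB 9000)
  pos <- list(chrA = c(1100, 1200, 1300, 1400, 1500, 1600,
                       5100, 5200, 5300, 5400, 4000),
              chrB = c(1050, 1150, 1250, 1350, 3100, 3200, 9000))
  mk <- function(meth, unmeth) {
    gr <- c(GRanges("chrA", IRanges(pos$chrA, width = 1)),
            GRanges("chrB", IRanges(pos$chrB, width = 1)))
    strand(gr) <- "+"
    mcols(gr)$meth <- as.integer(meth)
    mcols(gr)$unmeth <- as.integer(unmeth)
    gr[order(as.character(seqnames(gr)), start(gr))]
  }
  # order follows pos above: chrA genes' CpGs then intergenic, then chrB
  cpgReports <- list(
    # condition A: g1 lowly methylated (10%), g2 highly (60%),
    # g3 low (5%), g4 high (50%)
    w1 = mk(meth   = c(1, 1, 1, 1, 1, 1, 6, 6, 6, 6, 0,
                       1, 0, 1, 0, 5, 5, 0),
            unmeth = c(9, 9, 9, 9, 9, 9, 4, 4, 4, 4, 10,
                       9, 10, 9, 10, 5, 5, 10)),
    w2 = mk(meth   = c(2, 0, 2, 0, 2, 0, 5, 7, 5, 7, 1,
                       0, 1, 0, 1, 4, 6, 1),
            unmeth = c(8, 10, 8, 10, 8, 10, 5, 3, 5, 3, 9,
                       10, 9, 10, 9, 6, 4, 9)),
    # condition B: g1 up to 20%, g2 down to 40%, g3/g4 unchanged
    w3 = mk(meth   = c(2, 2, 2, 2, 2, 2, 4, 4, 4, 4, 0,
                       1, 0, 1, 0, 5, 5, 0),
            unmeth = c(8, 8, 8, 8, 8, 8, 6, 6, 6, 6, 10,
                       9, 10, 9, 10, 5, 5, 10)),
    w4 = mk(meth   = c(3, 1, 3, 1, 3, 1, 5, 3, 5, 3, 1,
                       0, 1, 0, 1, 6, 4, 1),
            unmeth = c(7, 9, 7, 9, 7, 9, 5, 7, 5, 7, 9,
                       10, 9, 10, 9, 4, 6, 9))
  )
  rna <- matrix(c(
    # r1   r2   r3   r4
    100, 120, 210, 190,   # g1: up in condition B
    400, 380, 200, 210,   # g2: down in condition B
    50,  60,  55,  52,    # g3: flat
    800, 780, 820, 790,   # g4: flat
    0,   0,   0,   0      # g_nil: unexpressed
  ), nrow = 5, byrow = TRUE,
  dimnames = list(c("g1", "g2", "g3", "g4", "g_nil"),
                  c("rna_a1", "rna_a2", "rna_b1", "rna_b2")))
  storage.mode(rna) <- "integer"
  sheet <- rbind(
    data.frame(sample_id = c("w1", "w2", "w3", "w4"),
               condition = c("A", "A", "B", "B"), assay = "wgbs",
               fraction = "none", is_control = c(TRUE, TRUE, FALSE, FALSE)),
    data.frame(sample_id = c("rna_a1", "rna_a2", "rna_b1", "rna_b2"),
               condition = c("A", "A", "B", "B"), assay = "rnaseq",
               fraction = "none", is_control = c(TRUE, TRUE, FALSE, FALSE))
  )
  list(genes = genes, cpgReports = cpgReports,
       counts = list(rnaseq = rna), sampleSheet = sheet,
       truth = NULL, config = NULL)
}
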