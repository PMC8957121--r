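# Gene-body and promoter methylation levels, MBD-scores, mdRAD RPKM, the
# log2 transform with the zero rule, and the genomic coverage estimate.

# normalize per-sample CpG input to a named list of GRanges
asCpgList <- function(cpgs) {
  if (is(cpgs, "GRanges")) cpgs <- list(sample1 = cpgs)
  if (!is.list(cpgs) || !all(vapply(cpgs, is, TRUE, "GRanges"))) {
    stop("cpgs must be a GRanges or a named list of GRanges (one per sample)")
  }
  if (is.null(names(cpgs)) || any(!nzchar(names(cpgs)))) {
    names(cpgs) <- paste0("sample", seq_along(cpgs))
  }
  cpgs
}

sumCountsOverIntervals <- function(cpgs, intervals, minCov) {
  cpgs <- asCpgList(cpgs)
  n <- length(intervals)
  ids <- names(intervals)
  meth <- matrix(0L, n, length(cpgs), dimnames = list(ids, names(cpgs)))
  cov <- meth
  missingContigs <- character(0)
  for (s in seq_along(cpgs)) {
    gr <- cpgs[[s]]
    # both strands pooled: ignore strand in the overlap
    hits <- findOverlaps(granges(gr), intervals, ignore.strand = TRUE)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ms <- rowsum(as.numeric(mcols(gr)$meth[qi]), si)
      cs <- rowsum(as.numeric(mcols(gr)$meth[qi] + mcols(gr)$unmeth[qi]), si)
      idx <- as.integer(rownames(ms))
      meth[idx, s] <- as.integer(ms[, 1])
      cov[idx, s] <- as.integer(cs[, 1])
    }
    missingContigs <- union(missingContigs,
      setdiff(unique(as.character(seqnames(intervals))),
              unique(as.character(seqnames(gr)))))
  }
  if (length(missingContigs)) {
    warning("no CpG records on contig(s): ",
            paste(sort(missingContigs), collapse = ", "),
            "; affected features are missing")
  }
  MethLevelTable(meth, cov, minCov = minCov, rowRanges = intervals)
}

#' Gene body percent methylation
#'
#' For each gene and sample, sums methylated and total read counts over all
#' CpG records falling within the gene bounds (both strands pooled), and
#' reports the percent methylation 100 * meth / coverage. Cells whose summed
#' coverage is below \code{minGeneCov} are set missing; genes on contigs
#' absent from the CpG data are missing with a single warning per contig.
#' \code{mean_pct_meth} averages the per-sample percentages over non-missing
#' samples.
#'
#' @param cpgs a [GenomicRanges::GRanges] of CpG records (metadata columns
#'   \code{meth}, \code{unmeth}), or a named list of such objects, one per
#'   sample (see [readCytosineReport()]).
#' @param genes gene models from [readGeneModels()].
#' @param minGeneCov minimum summed coverage per gene and sample (default
#'   10; 0 disables the filter).
#' @return a \linkS4class{MethLevelTable}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 150), width = 1),
#'                              meth = c(3L, 1L), unmeth = c(7L, 9L))
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 200), gene_id = "g1")
#' names(genes) <- "g1"
#' pctMeth(genePercentMethylation(gr, genes, minGeneCov = 0))  # 20%
#' @export
genePercentMethylation <- function(cpgs, genes, minGeneCov = 10) {
  sumCountsOverIntervals(cpgs, genes, minCov = minGeneCov)
}

#' Promoter percent methylation
#'
#' Identical to [genePercentMethylation()] but sums over promoter windows
#' (see [promoterWindows()]) instead of gene bodies. Windows are treated as
#' independent intervals: a window sharing coordinates with another gene's
#' body is still counted in full.
#'
#' @param cpgs per-sample CpG records as in [genePercentMethylation()].
#' @param windows promoter windows from [promoterWindows()].
#' @param minCov minimum summed coverage per window and sample.
#' @return a \linkS4class{MethLevelTable} over the windows.
#' @export
promoterPercentMethylation <- function(cpgs, windows, minCov = 10) {
  sumCountsOverIntervals(cpgs, windows, minCov = minCov)
}

#' log2 with the dataset-wide zero rule
#'
#' Replaces every zero with the smallest non-zero value of the dataset, then
#' takes log2, so that fully unmethylated genes can be drawn on the log
#' scale. Missing values stay missing.
#'
#' @param values non-negative numeric vector (e.g. per-gene mean percent
#'   methylation for one dataset); at least one value must be non-zero.
#' @return log2-transformed vector of the same length and names.
#' @examples
#' log2WithZeroRule(c(0, 2, 50))  # zeros become log2(2) = 1
#' @export
log2WithZeroRule <- function(values) {
  v <- values
  nz <- v[!is.na(v) & v > 0]
  if (any(!is.na(v) & v < 0)) stop("values must be non-negative")
  if (!length(nz)) stop("all values are zero: zero substitution undefined")
  v[!is.na(v) & v == 0] <- min(nz)
  log2(v)
}

#' Strand-aware promoter windows upstream of genes
#'
#' For a plus-strand gene \code{[s, e]} the window is \code{[s-width, s-1]};
#' for a minus-strand gene it is \code{[e+1, e+width]}. Windows are clipped
#' to \code{[1, contig length]} (contig lengths are taken from
#' \code{seqlengths(genes)} when present, otherwise clipping happens only at
#' coordinate 1); genes whose window is empty after clipping are dropped
#' with a warning. A gene's window never overlaps its own body.
#'
#' @param genes gene models ([readGeneModels()]).
#' @param width window width in bases (default 1000).
#' @return a [GenomicRanges::GRanges] of windows named by gene_id.
#' @export
promoterWindows <- function(genes, width = 1000) {
  stopifnot(width >= 1)
  st <- as.character(strand(genes))
  if (any(st == "*")) stop("promoter windows need stranded gene models")
  ws <- ifelse(st == "+", start(genes) - width, end(genes) + 1L)
  we <- ifelse(st == "+", start(genes) - 1L, end(genes) + width)
  ws <- pmax(ws, 1L)
  sl <- seqlengths(genes)[as.character(seqnames(genes))]
  if (!all(is.na(sl))) we <- ifelse(is.na(sl), we, pmin(we, sl))
  keep <- we >= ws
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) dropped: promoter window empty after clipping")
  }
  out <- GRanges(seqnames(genes)[keep], IRanges(ws[keep], we[keep]),
                 strand = st[keep],
                 gene_id = mcols(genes)$gene_id[keep])
  suppressWarnings(seqlengths(out) <- seqlengths(genes)[seqlevels(out)])
  names(out) <- mcols(out)$gene_id
  out
}

#' Reads per kilobase of gene length per million reads
#'
#' \code{rpkm[g, s] = counts[g, s] / (length_kb(g) * libsize(s) / 1e6)},
#' with library size the column sum of the count matrix.
#'
#' @param counts integer gene x sample matrix ([readCountMatrix()]).
#' @param genes gene models; every row of \code{counts} must have one.
#' @return numeric matrix of RPKM values, same dimnames as \code{counts}.
#' @export
rpkm <- function(counts, genes) {
  miss <- setdiff(rownames(counts), names(genes))
  if (length(miss)) stop("no gene model for: ", paste(head(miss, 5), collapse = ", "))
  len <- width(genes)[match(rownames(counts), names(genes))]
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  sweep(counts / (len / 1000), 2, lib / 1e6, "/")
}

#' MBD-seq methylation score
#'
#' Per paired captured/unbound library, the score is the log2 ratio of
#' captured-fraction RPKM to unbound-fraction RPKM after adding a
#' pseudocount to every cell; a gene's score is the mean over pairs. Higher
#' scores indicate stronger methyl-CpG binding-domain capture, i.e. higher
#' methylation.
#'
#' @param counts gene x column matrix holding both fractions' counts.
#' @param genes gene models (for lengths).
#' @param sampleSheet data.frame with \code{sample_id} and \code{fraction}
#'   (\code{captured}/\code{unbound}) identifying \code{colnames(counts)}
#'   as \code{"<sample_id>.<fraction>"}, or NULL to pair columns named that
#'   way directly.
#' @param pseudocount reads added to every cell before RPKM (default 1).
#' @return data.frame with \code{gene_id} and \code{mbd_score}.
#' @export
mbdScore <- function(counts, genes, sampleSheet = NULL, pseudocount = 1) {
  cols <- colnames(counts)
  parts <- strsplit(cols, ".", fixed = TRUE)
  frac <- vapply(parts, function(p) p[length(p)], "")
  base <- vapply(parts, function(p) paste(p[-length(p)], collapse = "."), "")
  if (!all(frac %in% c("captured", "unbound"))) {
    stop("count columns must be named '<sample>.captured' / '<sample>.unbound'")
  }
  pairs <- unique(base)
  for (b in pairs) {
    if (!all(c("captured", "unbound") %in% frac[base == b])) {
      stop("unpaired MBD fraction for sample '", b, "'")
    }
  }
  r <- rpkm(counts + pseudocount, genes)
  scores <- vapply(pairs, function(b) {
    log2(r[, cols[base == b & frac == "captured"]]) -
      log2(r[, cols[base == b & frac == "unbound"]])
  }, numeric(nrow(counts)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(counts))
  data.frame(gene_id = rownames(counts), mbd_score = rowMeans(scores))
}

#' Estimate mean genomic coverage of a bisulfite experiment
#'
#' Mean deduplicated read (pair) count times the combined paired-end read
#' length, divided by the summed reference genome length.
#'
#' @param meanDedupReads mean number of deduplicated read pairs per sample.
#' @param combinedPairLength combined length of a read pair in bases.
#' @param genomeLength summed reference genome length in bases.
#' @return fold coverage (a single number).
#' @examples
#' estimateGenomicCoverage(1e6, 200, 2e8)  # 1x
#' @export
estimateGenomicCoverage <- function(meanDedupReads, combinedPairLength,
                                    genomeLength) {
  if (genomeLength <= 0) stop("genome length must be positive")
  if (meanDedupReads <= 0 || combinedPairLength <= 0) {
    stop("read count and read length must be positive")
  }
  meanDedupReads * combinedPairLength / genomeLength
}
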