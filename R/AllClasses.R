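#' MethLevelTable: gene x sample methylation levels
#'
#' A \linkS4class{SummarizedExperiment} holding, per gene (or promoter
#' window) and sample, the summed methylated read counts (assay
#' \code{"meth"}), the summed total coverage (assay \code{"cov"}), and the
#' percent methylation (assay \code{"pct"}; \code{NA} where coverage is
#' below the minimum). \code{rowData} carries \code{mean_pct_meth}, the
#' percent methylation averaged across samples with non-missing values.
#'
#' @slot minCov minimum summed coverage per gene and sample below which the
#'   percent value is set missing.
#' @seealso [genePercentMethylation()], [promoterPercentMethylation()]
#' @export
setClass("MethLevelTable",
  contains = "SummarizedExperiment",
  representation(minCov = "numeric")
)

setValidity("MethLevelTable", function(object) {
  an <- names(assays(object))
  if (!all(c("meth", "cov", "pct") %in% an)) {
    return("assays must include 'meth', 'cov' and 'pct'")
  }
  m <- assay(object, "meth"); cv <- assay(object, "cov")
  p <- assay(object, "pct")
  if (any(m < 0, na.rm = TRUE) || any(cv < 0, na.rm = TRUE)) {
    return("counts must be non-negative")
  }
  if (any(m > cv, na.rm = TRUE)) {
    return("methylated counts cannot exceed coverage")
  }
  if (any(p < 0 | p > 100, na.rm = TRUE)) {
    return("percent methylation must lie in [0, 100]")
  }
  ok <- !is.na(p) & cv > 0
  if (any(abs(p[ok] - 100 * m[ok] / cv[ok]) > 1e-8)) {
    return("pct must equal 100 * meth / cov where defined")
  }
  if (!"mean_pct_meth" %in% colnames(rowData(object))) {
    return("rowData must contain mean_pct_meth")
  }
  TRUE
})

#' Construct a MethLevelTable
#'
#' @param meth,cov integer gene x sample matrices of summed methylated
#'   counts and summed coverage, with identical dimnames.
#' @param minCov cells with summed coverage below this are set missing.
#' @param rowRanges optional [GenomicRanges::GRanges] of the quantified
#'   intervals (genes or promoter windows), parallel to the rows.
#' @return a \linkS4class{MethLevelTable}.
#' @export
MethLevelTable <- function(meth, cov, minCov = 10, rowRanges = NULL) {
  stopifnot(identical(dim(meth), dim(cov)))
  pct <- ifelse(cov >= max(minCov, 1L) & cov > 0, 100 * meth / cov, NA_real_)
  if (minCov <= 0) pct <- ifelse(cov > 0, 100 * meth / cov, NA_real_)
  mean_pct <- rowMeans(pct, na.rm = TRUE)
  mean_pct[is.nan(mean_pct)] <- NA_real_
  rd <- DataFrame(mean_pct_meth = mean_pct)
  a <- list(meth = meth, cov = cov, pct = pct)
  if (is.null(rowRanges)) {
    se <- SummarizedExperiment(assays = a, rowData = rd)
    rownames(se) <- rownames(meth)
  } else {
    mcols(rowRanges)$mean_pct_meth <- mean_pct
    se <- SummarizedExperiment(assays = a, rowRanges = rowRanges)
    rownames(se) <- rownames(meth)
  }
  new("MethLevelTable", se, minCov = minCov)
}

#' @describeIn MethLevelTable summed methylated counts matrix.
#' @param x a MethLevelTable.
#' @export
methCounts <- function(x) assay(x, "meth")

#' @describeIn MethLevelTable summed coverage matrix.
#' @export
totalCoverage <- function(x) assay(x, "cov")

#' @describeIn MethLevelTable percent methylation matrix (NA below minCov).
#' @export
pctMeth <- function(x) assay(x, "pct")

#' @describeIn MethLevelTable named vector of per-gene mean percent
#'   methylation across samples.
#' @export
meanPctMeth <- function(x) {
  setNames(rowData(x)$mean_pct_meth, rownames(x))
}

setMethod("show", "MethLevelTable", function(object) {
  cat("MethLevelTable:", nrow(object), "features x", ncol(object),
      "samples (min coverage ", object@minCov, ")\n", sep = " ")
  mp <- rowData(object)$mean_pct_meth
  cat("  mean_pct_meth: ", sum(!is.na(mp)), " non-missing, median ",
      signif(median(mp, na.rm = TRUE), 4), "%\n", sep = "")
})

#' SeesawSummary: class-level shift estimates and component verdicts
#'
#' Per methylation class (low, high) and variable (differential GBM,
#' differential expression): the mean per-gene shift, a gene-resampling
#' percentile bootstrap 95\% confidence interval, and a sign verdict
#' (\code{positive}, \code{negative}, \code{null}, or \code{inconclusive}
#' when the class is below the minimum size). The three seesaw component
#' checks are each \code{supported}, \code{not_supported}, or
#' \code{inconclusive}:
#' \enumerate{
#'   \item the two classes shift reciprocally (opposite signs) in GBM;
#'   \item the two classes shift reciprocally in transcription;
#'   \item within each class, the transcription shift opposes the GBM shift.
#' }
#'
#' @slot stats data.frame with columns class, variable, n, mean, ci_lo,
#'   ci_hi, verdict.
#' @slot components named character of the three component verdicts.
#' @slot nBoot bootstrap replicate count.
#' @slot seed seed used for the bootstrap (NA if none supplied).
#' @slot minClassSize classes smaller than this give inconclusive verdicts.
#' @seealso [seesawTest()]
#' @export
setClass("SeesawSummary",
  representation(stats = "data.frame", components = "character",
                 nBoot = "integer", seed = "numeric",
                 minClassSize = "integer")
)

setValidity("SeesawSummary", function(object) {
  need <- c("class", "variable", "n", "mean", "ci_lo", "ci_hi", "verdict")
  if (!all(need %in% colnames(object@stats))) {
    return("stats must have class/variable/n/mean/ci_lo/ci_hi/verdict")
  }
  cmp <- c("c1_reciprocal_gbm", "c2_reciprocal_expression",
           "c3_opposite_directions")
  if (!all(cmp %in% names(object@components))) {
    return("components must name c1_reciprocal_gbm, c2_reciprocal_expression, c3_opposite_directions")
  }
  if (!all(object@components %in%
           c("supported", "not_supported", "inconclusive"))) {
    return("component verdicts must be supported/not_supported/inconclusive")
  }
  TRUE
})

#' @describeIn SeesawSummary the three component verdicts as a named
#'   character vector.
#' @param x a SeesawSummary.
#' @export
seesawComponents <- function(x) x@components

#' @describeIn SeesawSummary the per-class shift table (mean, bootstrap CI,
#'   verdict for each class x variable).
#' @export
classShifts <- function(x) x@stats

setMethod("show", "SeesawSummary", function(object) {
  cat("SeesawSummary (", object@nBoot, " bootstrap replicates)\n", sep = "")
  st <- object@stats
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-4s %-6s n=%-6d mean %+.4f  [%+.4f, %+.4f]  %s\n",
                st$class[i], st$variable[i], st$n[i], st$mean[i],
                st$ci_lo[i], st$ci_hi[i], st$verdict[i]))
  }
  cmp <- object@components
  cat("  components:\n")
  for (nm in names(cmp)) cat(sprintf("    %-26s %s\n", nm, cmp[[nm]]))
})

#' SimConfig: parameters of a synthetic methylome-transcriptome study
#'
#' Holds every tunable of the synthetic-study generator. Defaults describe a
#' desk-scale invertebrate-like study: a bimodal gene body methylation (GBM)
#' landscape (a lowly methylated class around 1\% and a highly methylated
#' class around 60\%), expression increasing with GBM, expression
#' variability (negative-binomial dispersion) decreasing with GBM, and
#' optional planted condition effects: a latent-Gaussian coupling
#' \code{deltaCouplingRho} between per-gene methylation and expression
#' changes, and class-level mean "seesaw" shifts.
#'
#' @seealso [simConfig()] for construction with defaults, [simulateStudy()]
#' @export
setClass("SimConfig", representation(
  nGenes = "integer", nContigs = "integer",
  geneLengthMedian = "numeric", geneLengthLogSd = "numeric",
  cpgsPerKb = "numeric", intergenicFrac = "numeric",
  propHigh = "numeric",
  lowMethMean = "numeric", lowMethConc = "numeric",
  highMethMean = "numeric", highMethConc = "numeric",
  coveragePerCpg = "numeric", nPerCondition = "integer",
  exprIntercept = "numeric", exprSlopeVsGbm = "numeric",
  exprBaselineSd = "numeric",
  exprDispersionLow = "numeric", exprDispersionHigh = "numeric",
  rnaLibSize = "numeric",
  deltaCouplingRho = "numeric",
  deltaGbmSd = "numeric", deltaExprSd = "numeric",
  seesawDeltaGbmHigh = "numeric", seesawDeltaGbmLow = "numeric",
  seesawDeltaExprHigh = "numeric", seesawDeltaExprLow = "numeric",
  mbdDepth = "numeric", mdradDepth = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  probs <- c(object@propHigh, object@lowMethMean, object@highMethMean,
             object@intergenicFrac)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  if (object@lowMethConc <= 0 || object@highMethConc <= 0) {
    return("Beta concentrations must be positive")
  }
  if (abs(object@deltaCouplingRho) > 1) {
    return("deltaCouplingRho must lie in [-1, 1]")
  }
  if (object@nGenes < 1 || object@nContigs < 1) {
    return("nGenes and nContigs must be positive")
  }
  if (object@nPerCondition < 1) return("nPerCondition must be >= 1")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes on", object@nContigs,
      "contigs;", 2L * object@nPerCondition, "samples per assay\n")
  cat(sprintf("  classes: %.0f%% high; low ~ Beta(mean %.3g, conc %.3g), high ~ Beta(mean %.3g, conc %.3g)\n",
              100 * object@propHigh, object@lowMethMean, object@lowMethConc,
              object@highMethMean, object@highMethConc))
  cat(sprintf("  coupling rho = %.2f; seesaw dGBM(high,low) = (%.2f, %.2f), dExpr(high,low) = (%.2f, %.2f); seed = %d\n",
              object@deltaCouplingRho, object@seesawDeltaGbmHigh,
              object@seesawDeltaGbmLow, object@seesawDeltaExprHigh,
              object@seesawDeltaExprLow, object@seed))
})
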