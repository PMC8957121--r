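# End-to-end orchestration: quantify -> classify -> differential ->
# correlations -> seesaw, with deterministic seeding and provenance.

#' Default analysis parameters
#'
#' One place holding every tunable's default: methylation class cutoff
#' (percent), FDR threshold, minimum per-gene coverage, promoter window
#' width, pseudocounts, minimum expression total, bootstrap replicates and
#' minimum class size for the seesaw test, and the analysis seed.
#'
#' @return named list of defaults.
#' @export
defaultParams <- function() {
  list(cutoff = 2.5, alpha_fdr = 0.1, min_gene_cov = 10,
       promoter_width = 1000, expr_pseudocount = 0.5, min_total = 10,
       mbd_pseudocount = 1, n_boot = 2000, min_class_size = 20,
       overdispersion = "none", cor_method = "pearson", seed = 1)
}

resolveParams <- function(params) {
  p <- defaultParams()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(params)] <- params
  p
}

#' Analyze one study (in memory)
#'
#' Runs the full analysis over an in-memory study (from [simulateStudy()],
#' [readStudy()], or assembled by hand): gene-body and promoter percent
#' methylation, log2 levels (dataset-wide zero rule), methylation classes,
#' RPKM / mean expression / coefficient of variation, differential
#' methylation (gene body and promoter) and differential expression for
#' the two conditions in the sample sheet, baseline and change-change
#' correlations, MBD-scores and mdRAD RPKM when those assays are present,
#' and the three-component seesaw test.
#'
#' @param study list with \code{genes}, \code{cpgReports},
#'   \code{counts$rnaseq} (optionally \code{counts$mbd},
#'   \code{counts$mdrad}) and \code{sampleSheet}.
#' @param params named list overriding [defaultParams()].
#' @param condition1,condition2 contrast labels; default: the control
#'   condition (per \code{is_control}) vs the other.
#' @return a list of results: \code{gbm} and \code{promoter}
#'   (\linkS4class{MethLevelTable}s), \code{gbm_log2}, \code{classes},
#'   \code{rpkm}, \code{mean_log2_rpkm}, \code{cv}, \code{diff_gbm},
#'   \code{diff_promoter}, \code{diff_expr}, \code{baseline_correlations},
#'   \code{delta_correlations}, \code{seesaw}
#'   (\linkS4class{SeesawSummary}), optional \code{mbd_scores} /
#'   \code{mdrad_rpkm}, and \code{params}.
#' @export
analyzeStudy <- function(study, params = list(),
                         condition1 = NULL, condition2 = NULL) {
  p <- resolveParams(params)
  sheet <- validateSampleSheet(study$sampleSheet)
  conds <- unique(sheet$condition)
  if (is.null(condition1)) {
    condition1 <- unique(sheet$condition[sheet$is_control])[1]
    condition2 <- setdiff(conds, condition1)[1]
  }
  if (length(conds) != 2 || anyNA(c(condition1, condition2))) {
    stop("the analysis contrasts exactly two conditions")
  }
  condOf <- function(assay) {
    ss <- sheet[sheet$assay == assay & sheet$fraction %in% c("none", "captured"), ]
    setNames(ss$condition, ss$sample_id)
  }

  genes <- study$genes
  gbm <- genePercentMethylation(study$cpgReports, genes,
                                minGeneCov = p$min_gene_cov)
  gbm_log2 <- log2WithZeroRule(meanPctMeth(gbm))
  windows <- promoterWindows(genes, width = p$promoter_width)
  prom <- promoterPercentMethylation(study$cpgReports, windows,
                                     minCov = p$min_gene_cov)
  classes <- assignClasses(gbm, cutoff = p$cutoff)

  rna <- study$counts$rnaseq
  rnaCond <- condOf("rnaseq")
  rk <- rpkm(rna, genes)
  meanRpkm <- rowMeans(rk)
  mean_log2_rpkm <- log2WithZeroRule(meanRpkm)
  ctrl <- sheet$sample_id[sheet$assay == "rnaseq" & sheet$is_control]
  cv <- coefficientOfVariation(rk[, ctrl, drop = FALSE])

  wgbsCond <- condOf("wgbs")
  diff_gbm <- diffMethylation(gbm, wgbsCond, condition1, condition2,
                              overdispersion = p$overdispersion)
  diff_promoter <- diffMethylation(prom, wgbsCond, condition1, condition2,
                                   overdispersion = p$overdispersion)
  diff_expr <- diffExpression(rna, rnaCond, condition1, condition2,
                              minTotal = p$min_total,
                              pseudocount = p$expr_pseudocount)

  absLfc <- setNames(abs(diff_expr$log2_fold_change), diff_expr$gene_id)
  cvv <- setNames(cv$cv, cv$gene_id)
  baseline <- rbind(
    baselineCorrelation(gbm_log2, mean_log2_rpkm, method = p$cor_method,
                        xlab = "log2_gbm_pct", ylab = "mean_log2_rpkm"),
    baselineCorrelation(gbm_log2, absLfc, method = p$cor_method,
                        xlab = "log2_gbm_pct", ylab = "abs_log2_fold_change"),
    baselineCorrelation(gbm_log2, cvv, method = p$cor_method,
                        xlab = "log2_gbm_pct", ylab = "cv_rpkm")
  )

  delta <- rbind(
    cbind(deltaCorrelation(diff_gbm, diff_expr, "all",
                           alpha = p$alpha_fdr, method = p$cor_method),
          region = "gene_body"),
    cbind(deltaCorrelation(diff_gbm, diff_expr, "de_only",
                           alpha = p$alpha_fdr, method = p$cor_method),
          region = "gene_body"),
    cbind(deltaCorrelation(diff_gbm, diff_expr, "dm_only",
                           alpha = p$alpha_fdr, method = p$cor_method),
          region = "gene_body"),
    cbind(deltaCorrelation(diff_promoter, diff_expr, "all",
                           alpha = p$alpha_fdr, method = p$cor_method),
          region = "promoter")
  )

  seesaw <- seesawTest(classes, diff_gbm, diff_expr, nBoot = p$n_boot,
                       seed = p$seed, minClassSize = p$min_class_size)

  res <- list(gbm = gbm, promoter = prom, gbm_log2 = gbm_log2,
              classes = classes, rpkm = rk,
              mean_log2_rpkm = mean_log2_rpkm, cv = cv,
              diff_gbm = diff_gbm, diff_promoter = diff_promoter,
              diff_expr = diff_expr,
              baseline_correlations = baseline,
              delta_correlations = delta, seesaw = seesaw,
              contrast = c(condition1 = condition1,
                           condition2 = condition2),
              params = p)
  if (!is.null(study$counts$mbd)) {
    res$mbd_scores <- mbdScore(study$counts$mbd, genes,
                               pseudocount = p$mbd_pseudocount)
  }
  if (!is.null(study$counts$mdrad)) {
    res$mdrad_rpkm <- rpkm(study$counts$mdrad, genes)
  }
  res
}

#' Run a study from a configuration
#'
#' Reads the inputs named in the configuration, runs [analyzeStudy()], and
#' writes every result table (with provenance comment headers naming the
#' package version and resolved parameters) plus a run log to the output
#' directory. Reruns with an identical configuration and inputs are
#' byte-identical.
#'
#' @param config path to a YAML file or an equivalent named list with
#'   elements \code{input_dir} (a directory written by [simulateStudy()])
#'   or explicit paths (\code{genes}, \code{counts}, \code{sample_sheet},
#'   cytosine reports found via the sample sheet), optional
#'   \code{condition1}/\code{condition2}, an \code{outdir}, and any
#'   parameter from [defaultParams()].
#' @return invisibly, the [analyzeStudy()] result list.
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$input_dir)) stop("config must name input_dir")
  if (!dir.exists(config$input_dir)) {
    stop("input directory not found: ", config$input_dir)
  }
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must name outdir")
  pnames <- intersect(names(config), names(defaultParams()))
  params <- config[pnames]
  study <- readStudy(config$input_dir)
  res <- analyzeStudy(study, params = params,
                      condition1 = config$condition1,
                      condition2 = config$condition2)
  writeResults(res, outdir)
  invisible(res)
}

#' Write an analysis result bundle as TSV tables
#'
#' @param res result list from [analyzeStudy()].
#' @param outdir output directory (created if needed).
#' @return invisibly, \code{outdir}.
#' @export
writeResults <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenanceLines(c(res$params,
                            as.list(res$contrast)))
  lv <- function(x) {
    data.frame(gene_id = rownames(x), methCounts(x), totalCoverage(x),
               pct = pctMeth(x),
               mean_pct_meth = rowData(x)$mean_pct_meth,
               check.names = FALSE)
  }
  gbmTab <- lv(res$gbm)
  gbmTab$log2_pct_meth <- unname(res$gbm_log2)
  writeResultTable(gbmTab, file.path(outdir, "gbm_levels.tsv"), prov)
  writeResultTable(lv(res$promoter),
                   file.path(outdir, "promoter_levels.tsv"), prov)
  writeResultTable(res$classes, file.path(outdir, "classes.tsv"), prov)
  writeResultTable(res$cv, file.path(outdir, "cv.tsv"), prov)
  writeResultTable(res$diff_gbm, file.path(outdir, "diff_gbm.tsv"), prov)
  writeResultTable(res$diff_promoter,
                   file.path(outdir, "diff_promoter.tsv"), prov)
  writeResultTable(res$diff_expr, file.path(outdir, "diff_expr.tsv"), prov)
  allCor <- rbind(
    cbind(res$baseline_correlations, region = "gene_body", kind = "baseline"),
    cbind(res$delta_correlations, kind = "delta")
  )
  writeResultTable(allCor, file.path(outdir, "correlations.tsv"), prov)
  st <- classShifts(res$seesaw)
  cmp <- seesawComponents(res$seesaw)
  writeResultTable(st, file.path(outdir, "seesaw_shifts.tsv"), prov)
  writeResultTable(data.frame(component = names(cmp), verdict = unname(cmp)),
                   file.path(outdir, "seesaw_summary.tsv"), prov)
  if (!is.null(res$mbd_scores)) {
    writeResultTable(res$mbd_scores, file.path(outdir, "mbd_scores.tsv"), prov)
  }
  if (!is.null(res$mdrad_rpkm)) {
    writeResultTable(data.frame(gene_id = rownames(res$mdrad_rpkm),
                                res$mdrad_rpkm, check.names = FALSE),
                     file.path(outdir, "mdrad_rpkm.tsv"), prov)
  }
  log <- c(provenanceLines(),
           paste0("contrast: ", res$contrast[1], " vs ", res$contrast[2]),
           paste0("parameters: ", paste(names(res$params),
                  vapply(res$params, function(v) paste(format(v), collapse = ","), ""),
                  sep = "=", collapse = "; ")),
           paste0("genes quantified: ", nrow(res$gbm)),
           paste0("genes classified: ", nrow(res$classes)),
           paste0("genes tested (GBM): ", sum(res$diff_gbm$tested)),
           paste0("genes tested (expression): ", sum(res$diff_expr$tested)))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(outdir)
}
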