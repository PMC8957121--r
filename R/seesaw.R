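# Methylation-class assignment, baseline and change-change correlations,
# transcriptional variability, and the three-component class-level seesaw
# test.

#' Assign genes to methylation classes by a hard cutoff
#'
#' Invertebrate gene body methylation is bimodal; genes are split into a
#' lowly and a highly methylated class at a hard percent-methylation
#' cutoff (default 2.5\%). A gene is \code{high} iff its basis value is
#' greater than or equal to the cutoff (ties go to the high class so the
#' upper class is closed). Genes with a missing basis are omitted.
#'
#' @param levels a \linkS4class{MethLevelTable}, or a named numeric vector
#'   of per-gene mean percent methylation.
#' @param cutoff percent methylation separating the classes (default 2.5).
#' @return data.frame with \code{gene_id}, \code{meth_class} (factor
#'   low/high) and \code{basis} (the mean percent methylation used).
#' @export
assignClasses <- function(levels, cutoff = 2.5) {
  basis <- if (is(levels, "MethLevelTable")) meanPctMeth(levels) else levels
  if (is.null(names(basis))) stop("levels must carry gene names")
  keep <- !is.na(basis)
  data.frame(
    gene_id = names(basis)[keep],
    meth_class = factor(ifelse(basis[keep] >= cutoff, "high", "low"),
                        levels = c("low", "high")),
    basis = unname(basis[keep]), row.names = NULL
  )
}

#' Correlation between baseline methylation and an expression summary
#'
#' Correlates per-gene methylation level (typically log2 percent
#' methylation, MBD-score, or log2 mdRAD RPKM) with a per-gene expression
#' summary (mean log2 RPKM, |log2 fold change| between conditions, or the
#' coefficient of variation), over genes with both values non-missing.
#'
#' @param x,y named numeric vectors; genes are matched by name.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param xlab,ylab axis names recorded in the result.
#' @return one-row data.frame: \code{variable_x}, \code{variable_y},
#'   \code{n}, \code{r}, \code{method}, \code{subset}.
#' @export
baselineCorrelation <- function(x, y, method = c("pearson", "spearman"),
                                xlab = deparse(substitute(x)),
                                ylab = deparse(substitute(y))) {
  method <- match.arg(method)
  if (is.null(names(x)) || is.null(names(y))) {
    stop("x and y must be named by gene")
  }
  g <- intersect(names(x), names(y))
  xv <- x[g]; yv <- y[g]
  ok <- !is.na(xv) & !is.na(yv) & is.finite(xv) & is.finite(yv)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 genes with both values (got ", n, ")")
  r <- if (sd(xv[ok]) == 0 || sd(yv[ok]) == 0) {
    warning("zero variance in one axis; correlation undefined")
    NA_real_
  } else {
    cor(xv[ok], yv[ok], method = method)
  }
  data.frame(variable_x = xlab, variable_y = ylab, n = n, r = r,
             method = method, subset = "all")
}

#' Coefficient of variation of expression across control replicates
#'
#' Per gene, the sample standard deviation (n-1 denominator) of RPKM across
#' the control replicates divided by their mean; missing when the mean is
#' zero.
#'
#' @param rpkmControls numeric gene x control-sample matrix of RPKM values
#'   (>= 2 columns).
#' @return data.frame with \code{gene_id} and \code{cv}.
#' @export
coefficientOfVariation <- function(rpkmControls) {
  if (is.null(dim(rpkmControls)) || ncol(rpkmControls) < 2) {
    stop("need >= 2 control samples")
  }
  m <- rowMeans(rpkmControls)
  s <- sqrt(rowSums((rpkmControls - m)^2) / (ncol(rpkmControls) - 1))
  cv <- ifelse(m > 0, s / m, NA_real_)
  data.frame(gene_id = rownames(rpkmControls), cv = cv, row.names = NULL)
}

#' Correlation between differential methylation and differential expression
#'
#' Correlates the per-gene methylation effect (default
#' \code{log2_meth_ratio}) with the expression \code{log2_fold_change} on
#' the genes present and tested in both tables, optionally restricted to
#' significantly differentially expressed (\code{de_only}) or methylated
#' (\code{dm_only}) genes at FDR \code{alpha}.
#'
#' @param dm differential methylation table ([diffMethylation()]), gene
#'   body or promoter.
#' @param de differential expression table ([diffExpression()]).
#' @param subset \code{"all"}, \code{"de_only"}, or \code{"dm_only"}.
#' @param alpha FDR threshold used by the subsets (default 0.1).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param effect methylation effect column, \code{"log2_meth_ratio"}
#'   (default) or \code{"meth_diff"}.
#' @return one-row data.frame as in [baselineCorrelation()]; when fewer
#'   than 3 genes survive the subset, \code{r} is NA and \code{n} reports
#'   the count.
#' @export
deltaCorrelation <- function(dm, de, subset = c("all", "de_only", "dm_only"),
                             alpha = 0.1, method = c("pearson", "spearman"),
                             effect = c("log2_meth_ratio", "meth_diff")) {
  subset <- match.arg(subset)
  method <- match.arg(method)
  effect <- match.arg(effect)
  g <- intersect(dm$gene_id[dm$tested], de$gene_id[de$tested])
  di <- dm[match(g, dm$gene_id), ]
  ei <- de[match(g, de$gene_id), ]
  keep <- switch(subset,
    all = rep(TRUE, length(g)),
    de_only = !is.na(ei$q_value) & ei$q_value <= alpha,
    dm_only = !is.na(di$q_value) & di$q_value <= alpha
  )
  xv <- di[[effect]][keep]; yv <- ei$log2_fold_change[keep]
  ok <- !is.na(xv) & !is.na(yv) & is.finite(xv) & is.finite(yv)
  n <- sum(ok)
  r <- if (n >= 3 && sd(xv[ok]) > 0 && sd(yv[ok]) > 0) {
    cor(xv[ok], yv[ok], method = method)
  } else NA_real_
  data.frame(variable_x = paste0("delta_meth(", effect, ")"),
             variable_y = "delta_log2_expression", n = n, r = r,
             method = method, subset = subset)
}

#' Check bimodality of a methylation-level distribution
#'
#' Kernel-density diagnostic for the characteristic two-class shape of
#' invertebrate gene body methylation on the log2 scale: the distribution
#' is called bimodal when the density has two local maxima separated by at
#' least \code{minSeparation} (log2 units) with a valley between them no
#' higher than \code{valleyFrac} of the smaller peak.
#'
#' @param values numeric vector (typically log2 mean percent methylation);
#'   NA dropped.
#' @param minSeparation minimum distance between the two modes (default 2
#'   log2 units).
#' @param valleyFrac maximum valley density relative to the smaller peak
#'   (default 0.5).
#' @return list with \code{bimodal} (logical), \code{modes} (positions of
#'   the two highest separated peaks) and \code{valley} (minimum density
#'   between them, relative to the smaller peak).
#' @export
checkBimodality <- function(values, minSeparation = 2, valleyFrac = 0.5) {
  v <- values[is.finite(values)]
  d <- density(v)
  y <- d$y; x <- d$x
  i <- which(diff(sign(diff(y))) < 0) + 1L  # local maxima
  if (length(i) < 2) {
    return(list(bimodal = FALSE, modes = x[i], valley = NA_real_))
  }
  i <- i[order(y[i], decreasing = TRUE)]
  # two highest maxima far enough apart
  best <- NULL
  for (a in seq_along(i)) {
    for (b in seq_along(i)) {
      if (b <= a) next
      if (abs(x[i[a]] - x[i[b]]) >= minSeparation) { best <- c(i[a], i[b]); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    return(list(bimodal = FALSE, modes = x[i[1:2]], valley = NA_real_))
  }
  rng <- sort(best)
  valley <- min(y[rng[1]:rng[2]]) / min(y[best])
  list(bimodal = valley <= valleyFrac, modes = sort(x[best]),
       valley = valley)
}

# run expr with a deterministic, restored RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

bootMeanCI <- function(v, nBoot, level = 0.95) {
  v <- unname(v)  # avoid copying names across n * nBoot resampled values
  n <- length(v)
  idx <- sample.int(n, n * nBoot, replace = TRUE)
  bm <- .colMeans(v[idx], n, nBoot)
  quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

signVerdict <- function(lo, hi) {
  if (is.na(lo) || is.na(hi)) "inconclusive"
  else if (lo > 0) "positive"
  else if (hi < 0) "negative"
  else "null"
}

#' Three-component class-level seesaw test
#'
#' For each methylation class (low, high) and each variable (differential
#' GBM effect, differential expression log2 fold change), computes the mean
#' per-gene shift with a gene-resampling percentile bootstrap 95\%
#' confidence interval, then evaluates the three seesaw components:
#' \enumerate{
#'   \item reciprocal GBM shifts: both classes' GBM CIs exclude zero, with
#'     opposite signs;
#'   \item reciprocal transcription shifts: likewise for expression;
#'   \item opposite directions: within each class, the GBM and expression
#'     verdicts are non-null and opposite.
#' }
#' A component is \code{inconclusive} when any class it needs has fewer
#' than \code{minClassSize} genes with non-missing effects; otherwise it is
#' \code{supported} or \code{not_supported}.
#'
#' @param classes class assignment from [assignClasses()].
#' @param dm differential methylation table; the \code{effect} column is
#'   the GBM shift variable.
#' @param de differential expression table.
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed seed for the bootstrap (restored afterwards); NULL uses the
#'   current RNG state.
#' @param minClassSize minimum class size for a verdict (default 20).
#' @param effect methylation effect column (default \code{log2_meth_ratio}).
#' @return a \linkS4class{SeesawSummary}.
#' @export
seesawTest <- function(classes, dm, de, nBoot = 2000, seed = NULL,
                       minClassSize = 20,
                       effect = c("log2_meth_ratio", "meth_diff")) {
  effect <- match.arg(effect)
  vals <- list(
    gbm = setNames(dm[[effect]], dm$gene_id),
    expr = setNames(de$log2_fold_change, de$gene_id)
  )
  stats <- do.call(rbind, withSeed(seed, lapply(c("low", "high"), function(cl) {
    genes <- classes$gene_id[classes$meth_class == cl]
    do.call(rbind, lapply(names(vals), function(vn) {
      v <- vals[[vn]][intersect(genes, names(vals[[vn]]))]
      v <- v[!is.na(v) & is.finite(v)]
      n <- length(v)
      if (n < minClassSize) {
        data.frame(class = cl, variable = vn, n = n, mean = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_,
                   verdict = "inconclusive")
      } else {
        ci <- bootMeanCI(v, nBoot)
        data.frame(class = cl, variable = vn, n = n, mean = mean(v),
                   ci_lo = ci[1], ci_hi = ci[2],
                   verdict = signVerdict(ci[1], ci[2]))
      }
    }))
  })))
  getv <- function(cl, vn) stats$verdict[stats$class == cl & stats$variable == vn]
  reciprocal <- function(vn) {
    v <- c(getv("low", vn), getv("high", vn))
    if (any(v == "inconclusive")) "inconclusive"
    else if (all(v %in% c("positive", "negative")) && v[1] != v[2]) "supported"
    else "not_supported"
  }
  opposite <- function() {
    per <- vapply(c("low", "high"), function(cl) {
      g <- getv(cl, "gbm"); e <- getv(cl, "expr")
      if (g == "inconclusive" || e == "inconclusive") "inconclusive"
      else if (all(c(g, e) %in% c("positive", "negative")) && g != e)
        "supported"
      else "not_supported"
    }, "")
    if (any(per == "inconclusive")) "inconclusive"
    else if (all(per == "supported")) "supported"
    else "not_supported"
  }
  comps <- c(c1_reciprocal_gbm = reciprocal("gbm"),
             c2_reciprocal_expression = reciprocal("expr"),
             c3_opposite_directions = opposite())
  new("SeesawSummary", stats = stats, components = comps,
      nBoot = as.integer(nBoot),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      minClassSize = as.integer(minClassSize))
}
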