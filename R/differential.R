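# Differential methylation (binomial GLM likelihood-ratio test) and
# differential expression (median-of-ratios normalization + negative
# binomial Wald test), both with Benjamini-Hochberg FDR. These are fully
# specified, dependency-free statistical procedures whose output schema
# mirrors the popular methylation/expression packages so externally
# produced tables can be ingested alongside.

# logit bound used when a pooled proportion is 0 or 1 (separation)
.LOGIT_CAP <- 15

boundProp <- function(p) pmin(pmax(p, plogis(-.LOGIT_CAP)), plogis(.LOGIT_CAP))

binomLogLik <- function(m, c, p) {
  ifelse(c > 0, m * log(p) + (c - m) * log1p(-p), 0)
}

#' Per-gene differential methylation (binomial likelihood-ratio test)
#'
#' For each gene, per-sample (methylated, coverage) count pairs are modeled
#' as binomial with a condition effect on the logit scale; the maximum
#' likelihood fit of this two-group model reduces to the condition-pooled
#' proportions. The p-value comes from the likelihood-ratio test against
#' the intercept-only model (chi-square, 1 df). With
#' \code{overdispersion = "pearson"}, the LRT statistic is divided by the
#' null-model Pearson dispersion whenever that exceeds 1.
#'
#' Effects are reported on two scales: \code{meth_diff}, the difference in
#' condition-pooled percent methylation (condition2 - condition1, in
#' percentage points), and \code{log2_meth_ratio}, the log2 ratio of the
#' pooled percents after adding 0.5 reads to each pooled methylated and
#' unmethylated count. Genes are untested when either condition has no
#' sample passing the coverage filter (percent value missing in the
#' \linkS4class{MethLevelTable}). Complete separation (pooled 0\% vs 100\%)
#' is handled by capping the fitted logits at \code{+/-15}; such genes are
#' flagged in the \code{boundary} column.
#'
#' @param levels a \linkS4class{MethLevelTable} with per-sample count pairs.
#' @param sampleConditions named character (or factor) mapping the table's
#'   sample (column) names to condition labels.
#' @param condition1,condition2 the two contrast labels; effects are
#'   condition2 vs condition1.
#' @param overdispersion \code{"none"} or \code{"pearson"}.
#' @return a data.frame with columns \code{gene_id}, \code{meth_diff},
#'   \code{log2_meth_ratio}, \code{p_value}, \code{q_value} (BH over tested
#'   genes), \code{tested}, \code{boundary}.
#' @export
diffMethylation <- function(levels, sampleConditions, condition1, condition2,
                            overdispersion = c("none", "pearson")) {
  overdispersion <- match.arg(overdispersion)
  stopifnot(is(levels, "MethLevelTable"))
  if (condition1 == condition2) stop("contrast labels must differ")
  cond <- sampleConditions[colnames(levels)]
  if (anyNA(cond)) stop("sampleConditions must cover every sample column")
  s1 <- which(cond == condition1); s2 <- which(cond == condition2)
  if (!length(s1) || !length(s2)) stop("both conditions need samples")
  M <- methCounts(levels); C <- totalCoverage(levels)
  eligible <- !is.na(pctMeth(levels))
  # a sample contributes only when it passes the coverage filter
  Me <- M; Ce <- C
  Me[!eligible] <- 0L; Ce[!eligible] <- 0L
  n1 <- rowSums(eligible[, s1, drop = FALSE])
  n2 <- rowSums(eligible[, s2, drop = FALSE])
  tested <- n1 >= 1 & n2 >= 1
  M1 <- rowSums(Me[, s1, drop = FALSE]); C1 <- rowSums(Ce[, s1, drop = FALSE])
  M2 <- rowSums(Me[, s2, drop = FALSE]); C2 <- rowSums(Ce[, s2, drop = FALSE])

  p1 <- boundProp(M1 / pmax(C1, 1))
  p2 <- boundProp(M2 / pmax(C2, 1))
  p0 <- boundProp((M1 + M2) / pmax(C1 + C2, 1))
  boundary <- tested & (M1 == 0 | M1 == C1 | M2 == 0 | M2 == C2)
  lrt <- 2 * (binomLogLik(M1, C1, p1) + binomLogLik(M2, C2, p2) -
                binomLogLik(M1 + M2, C1 + C2, p0))
  lrt <- pmax(lrt, 0)
  if (overdispersion == "pearson") {
    nEff <- rowSums(eligible)
    expM <- Ce * p0
    vr <- Ce * p0 * (1 - p0)
    pr <- (Me - expM)^2 / ifelse(vr > 0, vr, NA_real_)
    phi <- rowSums(pr, na.rm = TRUE) / pmax(nEff - 1, 1)
    lrt <- lrt / pmax(phi, 1)
  }
  p_value <- pchisq(lrt, df = 1, lower.tail = FALSE)
  meth_diff <- 100 * (M2 / pmax(C2, 1) - M1 / pmax(C1, 1))
  pct1 <- (M1 + 0.5) / (C1 + 1)
  pct2 <- (M2 + 0.5) / (C2 + 1)
  log2_meth_ratio <- log2(pct2) - log2(pct1)
  p_value[!tested] <- NA_real_
  meth_diff[!tested] <- NA_real_
  log2_meth_ratio[!tested] <- NA_real_
  q_value <- bhFDR(p_value)
  data.frame(gene_id = rownames(levels), meth_diff = meth_diff,
             log2_meth_ratio = log2_meth_ratio, p_value = p_value,
             q_value = q_value, tested = tested, boundary = boundary,
             row.names = NULL)
}

#' Median-of-ratios size factors
#'
#' Per sample, the median across genes (restricted to genes whose
#' geometric mean count over samples is positive) of the ratio of the
#' sample's count to the gene's geometric mean. When no gene has positive
#' counts in all samples, the geometric means fall back to being computed
#' over each gene's positive entries only, with a warning.
#'
#' @param counts integer gene x sample matrix.
#' @return named positive numeric vector of per-sample scale factors.
#' @export
sizeFactors <- function(counts) {
  if (any(colSums(counts > 0) == 0)) {
    stop("every sample needs at least one nonzero count")
  }
  lg <- log(counts)
  loggm <- rowMeans(lg)
  use <- is.finite(loggm)
  if (!any(use)) {
    warning("no gene has positive counts in every sample; ",
            "geometric means use positive entries only")
    lg[!is.finite(lg)] <- NA
    loggm <- rowMeans(lg, na.rm = TRUE)
    use <- is.finite(loggm)
  }
  sf <- apply(counts, 2, function(cnt) {
    r <- exp(log(cnt[use]) - loggm[use])
    median(r[is.finite(r) & r > 0])
  })
  setNames(sf, colnames(counts))
}

#' Per-gene differential expression (NB Wald test on normalized counts)
#'
#' Counts are normalized by median-of-ratios size factors
#' ([sizeFactors()]). The effect is
#' \code{log2((mean2 + pseudocount) / (mean1 + pseudocount))} of the
#' normalized condition means. A per-gene negative-binomial dispersion
#' \code{alpha} is estimated by method of moments on the normalized counts
#' pooled within conditions (floored at 1e-8), and the delta-method
#' standard error of the log2 ratio under NB(mean, alpha) with the observed
#' group sizes gives a Wald statistic. Because the moment dispersion
#' estimate carries only \code{n1 + n2 - 2} degrees of freedom, the
#' statistic is referred to a t distribution with that df (a normal
#' reference is markedly anticonservative at typical replicate numbers; see
#' the methods vignette).
#'
#' @param counts integer gene x sample matrix.
#' @param sampleConditions named character/factor mapping column names to
#'   condition labels.
#' @param condition1,condition2 contrast labels (effect: condition2 vs
#'   condition1); each needs >= 2 samples.
#' @param minTotal genes with total raw count below this are untested
#'   (default 10).
#' @param pseudocount added to each normalized condition mean inside the
#'   log ratio (default 0.5).
#' @return data.frame with \code{gene_id}, \code{base_mean},
#'   \code{log2_fold_change}, \code{p_value}, \code{q_value}, \code{tested}.
#' @export
diffExpression <- function(counts, sampleConditions, condition1, condition2,
                           minTotal = 10, pseudocount = 0.5) {
  cond <- sampleConditions[colnames(counts)]
  if (anyNA(cond)) stop("sampleConditions must cover every sample column")
  s1 <- which(cond == condition1); s2 <- which(cond == condition2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2 || n2 < 2) stop("each condition needs >= 2 samples")
  sf <- sizeFactors(counts[, c(s1, s2), drop = FALSE])
  y <- sweep(counts[, c(s1, s2), drop = FALSE], 2, sf, "/")
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  m1 <- rowMeans(y[, i1, drop = FALSE]); m2 <- rowMeans(y[, i2, drop = FALSE])
  v1 <- rowSums((y[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  # method-of-moments NB dispersion, residual variance pooled within
  # conditions: solve sum_k (n_k-1) v_k = sum_k (n_k-1)(m_k + a m_k^2)
  alpha <- ((n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)) /
    ((n1 - 1) * m1^2 + (n2 - 1) * m2^2)
  alpha <- pmax(alpha, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  tested <- rowSums(counts) >= minTotal & (m1 > 0 | m2 > 0)
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  se2 <- ((m1 + alpha * m1^2) / (n1 * (m1 + pseudocount)^2) +
            (m2 + alpha * m2^2) / (n2 * (m2 + pseudocount)^2)) / log(2)^2
  se <- sqrt(se2)
  z <- ifelse(se > 0, lfc / se, 0)
  p_value <- 2 * pt(-abs(z), df = n1 + n2 - 2)
  p_value[se == 0 & lfc == 0] <- 1
  lfc[!tested] <- NA_real_
  p_value[!tested] <- NA_real_
  q_value <- bhFDR(p_value)
  data.frame(gene_id = rownames(counts),
             base_mean = (n1 * m1 + n2 * m2) / (n1 + n2),
             log2_fold_change = lfc, p_value = p_value, q_value = q_value,
             tested = tested, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment \code{q_(i) = min_(j>=i) p_(j) * n / j} on the
#' ascending order statistics, capped at 1 and mapped back to input order.
#' Missing values are excluded from the adjustment and returned missing.
#'
#' @param p_values numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values, same length and order as the input.
#' @export
bhFDR <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}
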