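# Vectorised per-gene OLS shared by the two-group and age-association tests.
# Y: samples x genes; X: design. Returns coefficients, residual SS and df.
fitGeneOLS <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  list(coef = coef, rss = colSums(res^2), df = nrow(X) - ncol(X), qr = qrX)
}

#' Two-group differential expression with covariates
#'
#' Per gene, an ordinary least squares fit of log2 expression on a group
#' indicator (case vs control) plus additive covariates; the group
#' coefficient is the log2 fold change and its t statistic yields a
#' two-sided p-value on the residual degrees of freedom, adjusted across
#' genes by Benjamini-Hochberg. Genes with constant expression get
#' \code{log2FC = 0}, \code{p = 1} so the gene universe stays aligned
#' across cohorts.
#'
#' @param expr \code{SummarizedExperiment} with assay \code{logexpr} and a
#'   group column in colData.
#' @param groupColumn colData column with exactly two levels; the first
#'   level alphabetically is taken as reference unless the column is a
#'   factor, so with levels case/control the coefficient is case - control
#'   when \code{caseLevel} is "case".
#' @param covariates additional colData columns entering the design.
#' @param caseLevel which level is the case group (coefficient sign:
#'   case minus control).
#' @return \code{DataFrame} with columns gene, baseMean, log2FC, t, p,
#'   padj, ordered as the input genes.
#' @export
deTwoGroup <- function(expr, groupColumn = "group",
                       covariates = character(), caseLevel = "case") {
  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  g <- as.character(cd[[groupColumn]])
  lv <- unique(g)
  if (length(lv) != 2) stop("group column must have exactly two levels")
  if (!caseLevel %in% lv) stop("caseLevel not found in group column")
  if (min(table(g)) < 2) stop("need >= 2 samples per group")
  ind <- as.numeric(g == caseLevel)
  df <- data.frame(.group = ind)
  for (v in covariates)
    if (length(unique(cd[[v]])) > 1) df[[v]] <- cd[[v]]
  X <- stats::model.matrix(stats::reformulate(colnames(df)), data = df)
  Y <- t(SummarizedExperiment::assay(expr, "logexpr"))
  fit <- fitGeneOLS(X, Y)
  j <- match(".group", colnames(X))
  xtxi <- solve(crossprod(X))[j, j]
  sigma2 <- fit$rss / fit$df
  lfc <- fit$coef[j, ]
  se <- sqrt(sigma2 * xtxi)
  t <- lfc / se
  p <- 2 * pt(-abs(t), df = fit$df)
  constant <- matrixStats_colVars(Y) < 1e-24
  lfc[constant] <- 0
  t[constant] <- 0
  p[constant] <- 1
  p[!is.finite(p)] <- ifelse(abs(lfc[!is.finite(p)]) > 0, 0, 1)
  res <- S4Vectors::DataFrame(
    gene = colnames(Y), baseMean = colMeans(Y), log2FC = lfc, t = t,
    p = p, padj = p.adjust(p, method = "BH"), row.names = colnames(Y))
  S4Vectors::metadata(res) <- list(design = colnames(X),
                                   caseLevel = caseLevel, df = fit$df)
  res
}

# Column variances without an extra dependency.
matrixStats_colVars <- function(Y) {
  n <- nrow(Y)
  (colSums(Y^2) - n * colMeans(Y)^2) / (n - 1)
}

#' Call differentially expressed genes from a DE table
#'
#' Threshold rule of the discovery cohorts: significant when the (nominal
#' or adjusted) p-value is strictly below \code{pThreshold} and the linear
#' fold change strictly exceeds \code{fcThreshold}
#' (\code{2^|log2FC| > fcThreshold}). Setting \code{fcThreshold = NULL}
#' reproduces the p-value-only rule used for microarray validation cohorts
#' (typically with \code{pThreshold = 0.01}).
#'
#' @param de result of \code{\link{deTwoGroup}}.
#' @param pThreshold p-value cutoff (strict \code{<}).
#' @param fcThreshold linear fold-change cutoff (strict \code{>}), or
#'   \code{NULL} to disable the fold-change filter.
#' @param useAdjusted use \code{padj} instead of nominal \code{p}.
#' @param name prefix for the returned set names.
#' @return list with \code{up} and \code{down} \linkS4class{GeneSet}s.
#' @export
callDegs <- function(de, pThreshold = 0.05, fcThreshold = 1.2,
                     useAdjusted = FALSE, name = "DEG") {
  stopifnot(pThreshold > 0, is.null(fcThreshold) || fcThreshold > 0)
  pv <- if (useAdjusted) de$padj else de$p
  pass <- pv < pThreshold
  lfcCut <- if (is.null(fcThreshold)) 0 else log2(fcThreshold)
  up <- de$gene[pass & de$log2FC > lfcCut]
  down <- de$gene[pass & de$log2FC < -lfcCut]
  list(up = geneSet(up, name = paste0(name, "_up"), direction = "up"),
       down = geneSet(down, name = paste0(name, "_down"),
                      direction = "down"))
}

#' Write a DE table to TSV
#' @param de result of \code{\link{deTwoGroup}}.
#' @param path output file.
#' @export
writeDETable <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
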