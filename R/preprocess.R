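#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: each sample's factor is the median,
#' over usable genes, of its count divided by the gene's geometric mean
#' across samples. Usable genes are those with all-positive counts; if none
#' exist, genes positive in at least 90% of samples are used with ratios
#' taken over the samples where they are observed. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts counts matrix (genes x samples) or a
#'   \code{SummarizedExperiment} with a \code{counts} assay.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(2, 8, 4, 4, 16, 8), nrow = 3)
#' computeSizeFactors(m)   # proportional to (1, 2)
#' @export
computeSizeFactors <- function(counts) {
  m <- if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
  if (!length(m)) stop("empty count matrix")
  if (any(colSums(m > 0) == 0)) stop("a sample has no nonzero counts")
  allPos <- rowSums(m > 0) == ncol(m)
  if (any(allPos)) {
    sub <- m[allPos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub / geo, 2, median)
  } else {
    keep <- rowMeans(m > 0) >= 0.9
    if (!any(keep)) stop("no gene observed in >= 90% of samples")
    sub <- m[keep, , drop = FALSE]
    logm <- log(sub)
    logm[!is.finite(logm)] <- NA
    geo <- exp(rowMeans(logm, na.rm = TRUE))
    sf <- apply(sub / geo, 2, function(r) median(r[r > 0], na.rm = TRUE))
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(m)
  sf
}

#' Log-normalise counts
#'
#' \code{log2(count / size_factor + pseudocount)} per cell of the matrix. A
#' pseudocount of 1 keeps zero counts at exactly zero.
#'
#' @param counts counts \code{SummarizedExperiment} (or matrix plus
#'   \code{metadata}).
#' @param sizeFactors per-sample factors; computed by
#'   \code{\link{computeSizeFactors}} when missing.
#' @param pseudocount added after size-factor scaling.
#' @param metadata per-sample data.frame when \code{counts} is a bare matrix.
#' @return \code{SummarizedExperiment} with assay \code{logexpr}; the
#'   transformation provenance (size factors, pseudocount) is stored in
#'   \code{metadata()$provenance}.
#' @export
logNormalize <- function(counts, sizeFactors = NULL, pseudocount = 1,
                         metadata = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(counts, "counts")
    cd <- SummarizedExperiment::colData(counts)
  } else {
    m <- as.matrix(counts)
    cd <- S4Vectors::DataFrame(
      if (is.null(metadata)) data.frame(row.names = colnames(m)) else metadata,
      row.names = colnames(m))
  }
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(m)
  expr <- log2(sweep(m, 2, sizeFactors, "/") + pseudocount)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = expr), colData = cd)
  S4Vectors::metadata(se)$provenance <-
    list(size_factors = sizeFactors, pseudocount = pseudocount,
         adjusted_covariates = character())
  se
}

#' Remove covariate effects from log expression
#'
#' Per gene, ordinary least squares on the named covariates; the output is
#' the residual plus the gene's grand mean, so downstream fold changes stay
#' on the original log2 scale. The biological variables of interest
#' (\code{group}, \code{age}) are never allowed into the removal design.
#' Applying the removal twice equals applying it once.
#'
#' @param expr \code{SummarizedExperiment} with assay \code{logexpr}.
#' @param covariates colData column names to regress out (e.g.
#'   \code{c("sex", "batch", "library")}); additive main effects.
#' @return \code{SummarizedExperiment} of the same shape; the provenance
#'   records the adjusted covariates.
#' @export
removeCovariateEffects <- function(expr, covariates) {
  if (any(covariates %in% c("group", "age")))
    stop("'group' and 'age' must not be removed as covariates")
  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  missing <- setdiff(covariates, colnames(cd))
  if (length(missing))
    stop("unknown covariates: ", paste(missing, collapse = ", "))
  # single-level factors carry no effect and would break model.matrix
  usable <- covariates[vapply(covariates, function(v)
    length(unique(cd[[v]])) > 1, logical(1))]
  m <- SummarizedExperiment::assay(expr, "logexpr")
  if (length(usable)) {
    X <- stats::model.matrix(
      stats::reformulate(usable), data = cd[, usable, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
      stop("rank-deficient covariate design; collinear columns: ",
           paste(dropped, collapse = ", "))
    }
    fitted <- X %*% qr.coef(qrX, t(m))
    m <- m - t(fitted) + rowMeans(m)
  }
  out <- expr
  SummarizedExperiment::assay(out, "logexpr") <- m
  prov <- S4Vectors::metadata(out)$provenance
  prov$adjusted_covariates <- union(prov$adjusted_covariates, usable)
  S4Vectors::metadata(out)$provenance <- prov
  out
}
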