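#' Non-negative least squares cell-type deconvolution
#'
#' Per bulk sample, solves \code{min ||S x - b||_2} subject to
#' \code{x >= 0} over the genes shared between the bulk matrix and the
#' signature matrix, then normalises \code{x} to sum to 1. The active-set
#' solver returns exact zeros for excluded cell types, which downstream
#' filtering relies on. A sample solved as the all-zero vector is reported
#' as a uniform composition with a degenerate flag and warning.
#'
#' @param bulk genes x samples non-negative matrix.
#' @param signature genes x cell types signature matrix (LM22-style).
#' @param minSharedGenes minimum gene overlap required.
#' @param strict error (instead of warn) when fewer than 50% of signature
#'   genes are found in the bulk matrix.
#' @return A \linkS4class{ProportionEstimate}.
#' @export
nnlsProportions <- function(bulk, signature, minSharedGenes = 10,
                            strict = FALSE) {
  bulk <- as.matrix(bulk)
  signature <- as.matrix(signature)
  shared <- intersect(rownames(signature), rownames(bulk))
  if (length(shared) < minSharedGenes)
    stop("bulk and signature share fewer than ", minSharedGenes, " genes")
  cov <- length(shared) / nrow(signature)
  if (cov < 0.5) {
    msg <- sprintf("only %.0f%% of signature genes found in bulk", 100 * cov)
    if (strict) stop(msg) else warning(msg)
  }
  S <- signature[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank deficient over the shared genes")
  B <- bulk[shared, , drop = FALSE]
  k <- ncol(S)
  props <- matrix(0, ncol(B), k,
                  dimnames = list(colnames(B), colnames(S)))
  rnorm_ <- numeric(ncol(B))
  degen <- logical(ncol(B))
  for (j in seq_len(ncol(B))) {
    sol <- pracma::lsqnonneg(S, B[, j])
    x <- sol$x
    x[x < 1e-10] <- 0
    if (sum(x) == 0) {
      degen[j] <- TRUE
      x <- rep(1 / k, k)
    } else x <- x / sum(x)
    props[j, ] <- x
    rnorm_[j] <- sqrt(sol$resid.norm)
  }
  if (any(degen))
    warning(sum(degen), " sample(s) had an all-zero solution; ",
            "uniform proportions substituted")
  new("ProportionEstimate", proportions = props, residualNorm = rnorm_,
      degenerate = degen, method = "NNLS (active set), sum-to-one")
}

#' Drop cell types that are mostly absent
#'
#' Removes cell-type columns whose estimated proportion is zero in more
#' than \code{zeroFraction} of the samples, then renormalises each
#' sample's remaining proportions to 1 (preserving ratios among retained
#' types).
#'
#' @param estimates a \linkS4class{ProportionEstimate}.
#' @param zeroFraction drop threshold on the per-type zero fraction
#'   (strict \code{>}).
#' @return A filtered \linkS4class{ProportionEstimate}.
#' @export
filterCelltypes <- function(estimates, zeroFraction = 0.5) {
  p <- estimates@proportions
  zeroFrac <- colMeans(p <= 1e-10)
  keep <- zeroFrac <= zeroFraction
  if (!any(keep)) stop("all cell types would be filtered")
  q <- p[, keep, drop = FALSE]
  rs <- rowSums(q)
  degen <- estimates@degenerate | rs == 0
  q[rs == 0, ] <- 1 / ncol(q)
  q[rs > 0, ] <- q[rs > 0, , drop = FALSE] / rs[rs > 0]
  new("ProportionEstimate", proportions = q,
      residualNorm = estimates@residualNorm, degenerate = degen,
      method = paste0(estimates@method, "; zero-filtered >",
                      zeroFraction * 100, "%"))
}

#' Compare cell-type proportions between groups
#'
#' Per cell type, a two-sided Wilcoxon rank-sum test of the estimated
#' proportions between the two groups, Benjamini-Hochberg adjusted across
#' cell types.
#'
#' @param estimates a \linkS4class{ProportionEstimate}.
#' @param groups per-sample labels (two levels, each with >= 2 samples).
#' @return data.frame (cellType, medianA, medianB, delta, p, padj); delta
#'   is median(second level) - median(first level), levels sorted.
#' @export
compareProportions <- function(estimates, groups) {
  p <- estimates@proportions
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("need exactly two groups")
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  a <- groups == lv[1]
  rows <- lapply(colnames(p), function(ct) {
    w <- suppressWarnings(wilcox.test(p[!a, ct], p[a, ct]))
    data.frame(cellType = ct, medianA = median(p[a, ct]),
               medianB = median(p[!a, ct]),
               delta = median(p[!a, ct]) - median(p[a, ct]),
               p = w$p.value)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out
}
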