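#' Per-probe delta beta
#'
#' Mean beta of group B minus mean beta of group A per probe. With B the
#' long-lived group and A the middle-aged controls (the default
#' orientation), negative values indicate demethylation in the long-lived.
#'
#' @param a,b probes x samples beta matrices with identical probe sets.
#' @return named numeric vector of delta-beta values.
#' @export
deltaBeta <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("probe sets of the two groups must be identical")
  rowMeans(b) - rowMeans(a)
}

#' Fisher-Pearson skewness g1
#'
#' \code{g1 = m3 / m2^(3/2)} with central sample moments; exactly 0 for
#' symmetric samples. A strongly negative g1 of the delta-beta
#' distribution indicates a net hypomethylation trend.
#'
#' @param values numeric vector.
#' @return g1.
#' @export
skewnessG1 <- function(values) {
  x <- values[is.finite(values)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Call differentially methylated probes
#'
#' Per probe, a Welch t-test of beta values between the two groups (or of
#' M-values, \code{log2(beta/(1-beta))}, which stabilises the variance near
#' the bounds), Benjamini-Hochberg adjusted. A probe is called
#' \code{hyper} when \code{padj < pCut} and \code{delta_beta > dCut},
#' \code{hypo} symmetrically (strict inequalities), otherwise \code{ns}.
#'
#' @param a,b probes x samples beta matrices (>= 2 samples each).
#' @param dCut absolute delta-beta cutoff.
#' @param pCut adjusted p cutoff.
#' @param useMValues test on the logit (M-value) scale; delta beta is
#'   always reported on the beta scale.
#' @return data.frame (probe, delta_beta, t, p, padj, call).
#' @export
callDMPs <- function(a, b, dCut = 0.1, pCut = 0.01, useMValues = FALSE) {
  if (ncol(a) < 2 || ncol(b) < 2) stop("each group needs >= 2 samples")
  if (!identical(rownames(a), rownames(b)))
    stop("probe sets of the two groups must be identical")
  db <- deltaBeta(a, b)
  ta <- if (useMValues) log2(a / (1 - a)) else a
  tb <- if (useMValues) log2(b / (1 - b)) else b
  nA <- ncol(ta); nB <- ncol(tb)
  mA <- rowMeans(ta); mB <- rowMeans(tb)
  vA <- rowSums((ta - mA)^2) / (nA - 1)
  vB <- rowSums((tb - mB)^2) / (nB - 1)
  seSq <- vA / nA + vB / nB
  t <- (mB - mA) / sqrt(seSq)
  dfW <- seSq^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(-abs(t), dfW)
  bad <- !is.finite(p)
  t[bad] <- 0
  p[bad] <- 1
  padj <- p.adjust(p, "BH")
  call <- rep("ns", length(db))
  call[padj < pCut & db > dCut] <- "hyper"
  call[padj < pCut & db < -dCut] <- "hypo"
  data.frame(probe = rownames(a), delta_beta = unname(db), t = unname(t),
             p = unname(p), padj = unname(padj), call = call)
}

#' Map called probes to genes
#'
#' Unions the annotated genes of the hyper- and hypo-called probes,
#' deduplicated per direction. Genes hit in both directions are kept in
#' both sets and reported as conflicts; unannotated probes are skipped and
#' counted.
#'
#' @param dmps result of \code{\link{callDMPs}}.
#' @param annotation data.frame with columns \code{probe}, \code{gene}
#'   (450K-style probe annotation).
#' @return list with \code{hyper}, \code{hypo} \linkS4class{GeneSet}s,
#'   \code{conflicts} (genes in both), \code{nUnannotated}.
#' @export
mapProbesToGenes <- function(dmps, annotation) {
  gene <- annotation$gene[match(dmps$probe, annotation$probe)]
  pick <- function(dirn) {
    g <- gene[dmps$call == dirn]
    unique(g[!is.na(g) & g != ""])
  }
  nUnannot <- sum(dmps$call != "ns" & (is.na(gene) | gene == ""))
  hyper <- pick("hyper")
  hypo <- pick("hypo")
  list(hyper = geneSet(hyper, "hyper_methylated", "none"),
       hypo = geneSet(hypo, "hypo_methylated", "none"),
       conflicts = intersect(hyper, hypo), nUnannotated = nUnannot)
}

#' Methylation classification of LHA clusters
#'
#' Cross-tabulates the hyper-/hypo-methylated gene sets against the
#' labelled LHA clusters and attaches an upper-tail hypergeometric
#' enrichment p per cluster and direction over a shared gene universe.
#'
#' @param hyper,hypo \linkS4class{GeneSet}s from
#'   \code{\link{mapProbesToGenes}}.
#' @param lhaClusters named list of cluster \linkS4class{GeneSet}s.
#' @param universe character vector of background genes.
#' @return data.frame (cluster, direction, clusterSize, methylated,
#'   overlap, p, padj).
#' @export
classifyLhaMethylation <- function(hyper, hypo, lhaClusters, universe) {
  rows <- list()
  for (cl in names(lhaClusters)) {
    clGenes <- intersect(lhaClusters[[cl]]@members, universe)
    for (dirn in c("hyper", "hypo")) {
      mg <- intersect(if (dirn == "hyper") hyper@members else hypo@members,
                      universe)
      ov <- length(intersect(clGenes, mg))
      rows[[paste(cl, dirn)]] <- data.frame(
        cluster = cl, direction = dirn, clusterSize = length(clGenes),
        methylated = length(mg), overlap = ov,
        p = hypergeometricOverlapP(length(universe), length(clGenes),
                                   length(mg), ov))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- p.adjust(out$p, "BH")
  out
}
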