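#' Rank genes by cell-type specificity
#'
#' Score = mean log expression in the target cell type minus the mean over
#' all other cells; genes are returned in descending score order with ties
#' broken by gene id. When no other cells exist the score is the mean in
#' the target type.
#'
#' @param se genes x cells \code{SummarizedExperiment} with assay
#'   \code{logexpr} and a \code{cellType} colData column.
#' @param targetType cell-type label to rank for.
#' @return named numeric vector of scores, sorted descending.
#' @export
rankGenesForCelltype <- function(se, targetType) {
  labels <- SummarizedExperiment::colData(se)$cellType
  if (!targetType %in% labels) stop("unknown cell type: ", targetType)
  m <- SummarizedExperiment::assay(se, "logexpr")
  inT <- labels == targetType
  score <- rowMeans(m[, inT, drop = FALSE])
  if (any(!inT)) score <- score - rowMeans(m[, !inT, drop = FALSE])
  score[order(-score, names(score))]
}

# Core weighted KS running sum. positions: hit indices in the ranked list.
gseaRunningSum <- function(scores, hit, weightP) {
  N <- length(scores)
  isHit <- logical(N)
  isHit[hit] <- TRUE
  w <- abs(scores)^weightP
  wHit <- w * isHit
  denom <- sum(wHit)
  if (denom == 0) wHit[isHit] <- 1 / sum(isHit) else wHit <- wHit / denom
  missStep <- 1 / (N - sum(isHit))
  running <- cumsum(wHit - missStep * !isHit)
  mx <- max(running)
  mn <- min(running)
  # equal-magnitude positive/negative deviations resolve to the positive
  # extremum (tolerance guards float noise in exact ties)
  if (mx >= -mn - 1e-9) {
    list(ES = unname(mx), running = running, argmax = which.max(running))
  } else {
    list(ES = unname(mn), running = running, argmax = which.min(running))
  }
}

#' Gene set enrichment against a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: walking down the
#' ranked list, set members increment the sum by their |score|^p
#' (normalised over in-set scores) and non-members decrement it by
#' 1/(N - set size); the enrichment score (ES) is the signed maximal
#' deviation (equal-magnitude positive/negative deviations resolve to the
#' positive one). The null permutes gene labels (equivalently, draws random
#' sets of the same size); NES divides ES by the mean |null ES| of the same
#' sign and the p-value is the add-one same-sign tail. With fewer than 3
#' same-sign null scores, NES and p are NA with a warning.
#'
#' @param ranked named numeric vector, scores sorted descending
#'   (\code{\link{rankGenesForCelltype}}).
#' @param set \linkS4class{GeneSet} or character vector of members.
#' @param weightP score weight exponent (1 = conventional weighting; 0 =
#'   classic unweighted KS statistic).
#' @param nPerm permutations for the null.
#' @param seed integer seed.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
gsea <- function(ranked, set, weightP = 1, nPerm = 1000, seed = 1L) {
  memb <- if (is(set, "GeneSet")) set@members else unique(as.character(set))
  nm <- if (is(set, "GeneSet")) set@name else "set"
  hit <- which(names(ranked) %in% memb)
  N <- length(ranked)
  if (length(hit) == 0) stop("gene set is disjoint from the ranked list")
  if (length(hit) == N) stop("gene set covers the whole ranked list")
  obs <- gseaRunningSum(ranked, hit, weightP)
  obs$ES <- unname(obs$ES)
  lead <- if (obs$ES >= 0) {
    names(ranked)[intersect(seq_len(obs$argmax), hit)]
  } else {
    names(ranked)[intersect(seq(obs$argmax, N), hit)]
  }
  set.seed(seed)
  nullES <- vapply(seq_len(nPerm), function(i)
    gseaRunningSum(ranked, sample.int(N, length(hit)), weightP)$ES,
    numeric(1))
  same <- nullES[sign(nullES) == sign(obs$ES) & nullES != 0]
  if (length(same) < 3) {
    warning("fewer than 3 same-sign null enrichment scores; NES/p set NA")
    nes <- NA_real_
    p <- NA_real_
  } else {
    nes <- obs$ES / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$ES))) / (length(same) + 1)
  }
  new("EnrichmentResult", setName = nm, ES = unname(obs$ES), NES = nes,
      p = p, nPerm = as.integer(nPerm), leadingEdge = lead,
      nullES = nullES)
}

#' @describeIn gsea The enrichment score alone, without the permutation
#'   null (cheap; used for large-scale scoring and oracle comparisons).
#' @export
gseaES <- function(ranked, set, weightP = 1) {
  memb <- if (is(set, "GeneSet")) set@members else unique(as.character(set))
  hit <- which(names(ranked) %in% memb)
  if (length(hit) == 0) stop("gene set is disjoint from the ranked list")
  if (length(hit) == length(ranked))
    stop("gene set covers the whole ranked list")
  unname(gseaRunningSum(ranked, hit, weightP)$ES)
}

#' Gene x cell-type score matrix
#'
#' Each gene is z-scored across all cells; scores are then averaged within
#' each cell type, giving the gene's relative expression per type.
#'
#' @param se genes x cells \code{SummarizedExperiment} with assay
#'   \code{logexpr} and \code{cellType} colData.
#' @return genes x cell types numeric matrix.
#' @export
geneCellScores <- function(se) {
  labels <- SummarizedExperiment::colData(se)$cellType
  m <- SummarizedExperiment::assay(se, "logexpr")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  types <- sort(unique(labels))
  out <- vapply(types, function(tp)
    rowMeans(z[, labels == tp, drop = FALSE]), numeric(nrow(m)))
  colnames(out) <- types
  out
}

#' Cluster genes on their cell-type scores
#'
#' k-means on the rows of the gene x cell-type score matrix (10 restarts,
#' seeded). Cluster ids are relabelled by the cell type in which the
#' cluster centroid peaks (ties by descending peak score), so cluster 1 is
#' the cluster peaking in the first cell-type column, etc.
#'
#' @param scores matrix from \code{\link{geneCellScores}}.
#' @param k number of clusters (default 4, the LHA cluster count).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return named integer vector of cluster labels per gene.
#' @export
clusterGeneScores <- function(scores, k = 4, seed = 1L, nstart = 10) {
  if (k == 1) return(setNames(rep(1L, nrow(scores)), rownames(scores)))
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = nstart)
  peakCol <- apply(km$centers, 1, which.max)
  peakVal <- apply(km$centers, 1, max)
  relabel <- order(peakCol, -peakVal)
  newId <- match(seq_len(k), relabel)
  setNames(newId[km$cluster], rownames(scores))
}

#' Mean-z signature score
#'
#' Per sample (or cell): the mean of the per-gene z-scores over the set
#' members present in the matrix. Used e.g. for M1/M2 macrophage signature
#' scoring.
#'
#' @param expr \code{SummarizedExperiment} (assay \code{logexpr}) or a
#'   genes x samples matrix.
#' @param set \linkS4class{GeneSet} or character vector.
#' @return named numeric vector, one score per sample.
#' @export
signatureScore <- function(expr, set) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "logexpr") else as.matrix(expr)
  memb <- if (is(set, "GeneSet")) set@members else as.character(set)
  memb <- intersect(memb, rownames(m))
  if (!length(memb)) stop("no set member present in the expression matrix")
  sub <- m[memb, , drop = FALSE]
  mu <- rowMeans(sub)
  s <- apply(sub, 1, sd)
  z <- (sub - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  colMeans(z)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query set against each pathway of a
#' GMT collection, restricted to a gene universe, Benjamini-Hochberg
#' adjusted across pathways.
#'
#' @param query \linkS4class{GeneSet}.
#' @param pathways named list of \linkS4class{GeneSet}s (see
#'   \code{\link{readGMT}}).
#' @param universe character vector of background genes.
#' @return data.frame (pathway, size, overlap, p, padj) sorted by p.
#' @export
oraHypergeometric <- function(query, pathways, universe) {
  q <- intersect(query@members, universe)
  if (!length(q)) stop("query has no genes in the universe")
  rows <- lapply(pathways, function(pw) {
    pwU <- intersect(pw@members, universe)
    ov <- length(intersect(q, pwU))
    data.frame(pathway = pw@name, size = length(pwU), overlap = ov,
               p = hypergeometricOverlapP(length(universe), length(q),
                                          length(pwU), ov))
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out[order(out$p), ]
}

#' One-way ANOVA of scores across groups
#'
#' Fixed-effects one-way ANOVA (equal-variance), e.g. of an M2 signature
#' score across disease stages. With two groups, F equals the square of the
#' equal-variance t statistic.
#'
#' @param scores per-sample numeric values.
#' @param groups per-sample group labels (>= 2 levels).
#' @return named vector \code{c(F =, p =)}.
#' @export
anovaAcrossGroups <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  fit <- oneway.test(scores ~ groups, var.equal = TRUE)
  c(F = unname(fit$statistic), p = unname(fit$p.value))
}
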