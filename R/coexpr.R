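#' Soft-threshold power selection by scale-free fit
#'
#' For each candidate power, builds the unsigned adjacency
#' \code{|cor|^beta} between genes, computes each gene's connectivity
#' \code{k_i = sum_j a_ij}, bins k into 10 equal-occupancy bins, and
#' regresses \code{log10 p(k)} on \code{log10 k}. The scale-free fit R^2
#' is signed negative when the slope is positive. The chosen power is the
#' smallest one whose R^2 reaches \code{rsqCut}, else the power with the
#' maximum R^2.
#'
#' @param expr genes x samples matrix or \code{SummarizedExperiment}
#'   (assay \code{logexpr}).
#' @param powers candidate powers.
#' @param rsqCut target scale-free fit.
#' @param nBins connectivity histogram bins.
#' @return list with \code{power} and \code{fitTable} (power, rsq, slope,
#'   meanK).
#' @export
pickSoftThreshold <- function(expr, powers = 1:12, rsqCut = 0.8,
                              nBins = 10) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "logexpr") else as.matrix(expr)
  cc <- abs(suppressWarnings(cor(t(m))))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  rows <- lapply(powers, function(b) {
    a <- cc^b
    k <- rowSums(a)
    fit <- scaleFreeFit(k, nBins)
    data.frame(power = b, rsq = fit["rsq"], slope = fit["slope"],
               meanK = mean(k))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- which(tab$rsq >= rsqCut)
  power <- if (length(ok)) tab$power[ok[1]] else
    tab$power[which.max(tab$rsq)]
  list(power = power, fitTable = tab)
}

# log-log regression of the connectivity distribution.
scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(rsq = 0, slope = 0))
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(k, breaks, include.lowest = TRUE)
  pk <- as.numeric(table(bin)) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- pk > 0 & !is.na(mk) & mk > 0
  if (sum(keep) < 3) return(c(rsq = 0, slope = 0))
  x <- log10(mk[keep])
  y <- log10(pk[keep])
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit))$r.squared
  sl <- unname(stats::coef(fit)[2])
  c(rsq = if (sl > 0) -r2 else r2, slope = sl)
}

#' Unsigned adjacency from expression
#'
#' \code{|Pearson correlation|^power} between genes, diagonal zeroed.
#'
#' @param expr genes x samples matrix or \code{SummarizedExperiment}.
#' @param power soft-threshold power.
#' @return genes x genes adjacency in [0, 1].
#' @export
adjacencyMatrix <- function(expr, power = 8) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "logexpr") else as.matrix(expr)
  a <- abs(suppressWarnings(cor(t(m))))^power
  a[!is.finite(a)] <- 0
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with unit diagonal, where \code{k_i} is node i's connectivity. Two genes
#' overlap strongly when they share neighbours even without a direct edge.
#'
#' @param adjacency symmetric non-negative matrix with entries in [0, 1]
#'   (diagonal ignored).
#' @return symmetric TOM matrix with unit diagonal;
#'   dissimilarity = 1 - TOM.
#' @export
tomSimilarity <- function(adjacency) {
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  if (max(abs(adjacency - t(adjacency))) > 1e-8)
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a
  minK <- outer(k, k, pmin)
  tom <- (L + a) / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on \code{1 - TOM}, static tree
#' cut at \code{cutHeight}, assignment of clusters below \code{minSize} to
#' module 0 (unassigned), then iterative merging of modules whose
#' eigengenes correlate above \code{1 - mergeHeight}.
#'
#' @param dissimilarity symmetric \code{1 - TOM} matrix with gene
#'   dimnames.
#' @param expr genes x samples matrix (or \code{SummarizedExperiment})
#'   used for the eigengene merging step.
#' @param minSize minimum module size.
#' @param mergeHeight eigengene-dissimilarity threshold below which two
#'   modules are merged.
#' @param cutHeight static tree-cut height.
#' @return A \linkS4class{ModuleAssignment}; module ids are 1..K by
#'   decreasing size, 0 = unassigned.
#' @export
detectModules <- function(dissimilarity, expr, minSize = 30,
                          mergeHeight = 0.1, cutHeight = 0.99) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "logexpr") else as.matrix(expr)
  genes <- rownames(dissimilarity)
  hc <- hclust(as.dist(dissimilarity), method = "average")
  lab <- cutree(hc, h = cutHeight)
  sizes <- table(lab)
  lab[lab %in% as.integer(names(sizes)[sizes < minSize])] <- 0L
  lab <- relabelBySize(lab)
  # merge modules with near-identical eigengenes
  repeat {
    ids <- setdiff(sort(unique(lab)), 0L)
    if (length(ids) < 2) break
    eg <- vapply(ids, function(i)
      moduleEigengene(m[genes[lab == i], , drop = FALSE])$scores,
      numeric(ncol(m)))
    cc <- cor(eg)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= 1 - mergeHeight) break
    lab[lab == ids[max(top)]] <- ids[min(top)]
    lab <- relabelBySize(lab)
  }
  names(lab) <- genes
  new("ModuleAssignment", membership = as.integer(lab) |> setNames(genes),
      power = NA_real_, minSize = as.integer(minSize))
}

relabelBySize <- function(lab) {
  ids <- setdiff(unique(lab), 0L)
  if (!length(ids)) return(lab)
  sizes <- vapply(ids, function(i) sum(lab == i), integer(1))
  ord <- ids[order(-sizes, ids)]
  out <- lab
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

#' Module eigengene
#'
#' First principal component of the standardized module expression: genes
#' are centred and scaled across samples, and the leading right singular
#' vector gives one unit-norm score per sample. The sign is fixed so the
#' eigengene correlates non-negatively with the module's mean expression
#' profile, making results reproducible across linear-algebra backends.
#'
#' @param expr module genes x samples matrix (or
#'   \code{SummarizedExperiment} plus \code{genes}).
#' @param genes optional gene ids selecting the module rows.
#' @return list with \code{scores} (per sample, unit norm),
#'   \code{varianceExplained}, and \code{loadings} (per gene).
#' @export
moduleEigengene <- function(expr, genes = NULL) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "logexpr") else as.matrix(expr)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  sv <- svd(z)
  scores <- sv$v[, 1]
  ref <- colMeans(z)
  refCor <- if (sd(ref) > 0) cor(scores, ref) else NA_real_
  if ((!is.na(refCor) && refCor < 0) || (is.na(refCor) && sum(scores) < 0))
    scores <- -scores
  names(scores) <- colnames(m)
  list(scores = scores,
       varianceExplained = sv$d[1]^2 / sum(sv$d^2),
       loadings = setNames(sv$u[, 1], rownames(m)))
}

#' Correlate module eigengenes with a trait
#'
#' Pearson correlation of each module eigengene with a per-sample trait
#' (e.g. age), with a two-sided t-based p-value and Benjamini-Hochberg
#' adjustment across modules.
#'
#' @param eigengenes samples x modules matrix (or a list of eigengene
#'   score vectors).
#' @param trait per-sample numeric values; must not be constant.
#' @return data.frame (module, r, p, padj).
#' @export
correlateWithTrait <- function(eigengenes, trait) {
  if (is.list(eigengenes) && !is.matrix(eigengenes))
    eigengenes <- do.call(cbind, eigengenes)
  if (sd(trait) == 0) stop("trait is constant; correlation undefined")
  rows <- lapply(seq_len(ncol(eigengenes)), function(j) {
    ct <- stats::cor.test(eigengenes[, j], trait)
    data.frame(module = colnames(eigengenes)[j] %||% as.character(j),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag low-connectivity outlier samples
#'
#' Each sample's connectivity is its summed correlation with all other
#' samples; samples whose standardized connectivity falls below
#' \code{-zCut} are flagged for removal before network construction.
#'
#' @param expr genes x samples matrix or \code{SummarizedExperiment}.
#' @param zCut flag threshold (z-score units).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flagSampleOutliers <- function(expr, zCut = 3) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "logexpr") else as.matrix(expr)
  cc <- suppressWarnings(cor(m))
  cc[!is.finite(cc)] <- 0
  conn <- rowSums(cc) - 1
  if (sd(conn) == 0) return(character())
  z <- (conn - mean(conn)) / sd(conn)
  colnames(m)[z < -zCut]
}
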