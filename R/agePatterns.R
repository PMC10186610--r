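#' Age-association test over decade bins
#'
#' Per gene, a nested-model F-test comparing an OLS fit with the decade-bin
#' factor plus covariates against the covariates-only reduced model,
#' Benjamini-Hochberg adjusted across genes. This is the screening step for
#' common aging-associated genes (significant at adjusted p < 0.05).
#'
#' @param expr \code{SummarizedExperiment} with assay \code{logexpr} and an
#'   \code{age} colData column.
#' @param covariates colData columns entering both models (e.g. sex).
#' @return \code{DataFrame} with gene, F, p, padj.
#' @export
ageAssociationTest <- function(expr, covariates = character()) {
  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  bins <- ageBins(cd$age)
  if (anyNA(bins)) stop("ages outside 20-79 are not binnable")
  if (any(table(bins) < 2)) stop("every decade bin needs >= 2 samples")
  Y <- t(SummarizedExperiment::assay(expr, "logexpr"))
  df <- data.frame(.bin = bins)
  for (v in covariates)
    if (length(unique(cd[[v]])) > 1) df[[v]] <- cd[[v]]
  X1 <- stats::model.matrix(stats::reformulate(colnames(df)), data = df)
  X0 <- if (ncol(df) > 1)
    stats::model.matrix(stats::reformulate(colnames(df)[-1]),
                        data = df[, -1, drop = FALSE])
  else matrix(1, nrow(Y), 1)
  full <- fitGeneOLS(X1, Y)
  red <- fitGeneOLS(X0, Y)
  df1 <- ncol(X1) - ncol(X0)
  Fstat <- ((red$rss - full$rss) / df1) / (full$rss / full$df)
  p <- pf(Fstat, df1, full$df, lower.tail = FALSE)
  bad <- !is.finite(Fstat)
  Fstat[bad] <- 0
  p[bad] <- 1
  S4Vectors::DataFrame(gene = colnames(Y), F = Fstat, p = p,
                       padj = p.adjust(p, "BH"), row.names = colnames(Y))
}

#' Decade-bin z-profiles
#'
#' Per gene: z-score across all samples, then the mean z per decade bin.
#' Constant genes (zero variance) get an all-zero profile. Profiles are
#' invariant to affine transforms of a gene's values.
#'
#' @param expr \code{SummarizedExperiment} with assay \code{logexpr}, or a
#'   genes x samples matrix.
#' @param ages per-sample ages (taken from colData when omitted).
#' @return genes x 6 matrix of bin means (columns 20-29 ... 70-79).
#' @export
binProfiles <- function(expr, ages = NULL) {
  if (is(expr, "SummarizedExperiment")) {
    if (is.null(ages)) ages <- SummarizedExperiment::colData(expr)$age
    m <- SummarizedExperiment::assay(expr, "logexpr")
  } else m <- as.matrix(expr)
  bins <- ageBins(ages)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  prof <- vapply(ageBinLabels, function(b)
    rowMeans(z[, bins == b, drop = FALSE]), numeric(nrow(m)))
  colnames(prof) <- ageBinLabels
  prof
}

#' Cluster decade-bin profiles into pattern groups
#'
#' Average-linkage hierarchical clustering on \code{1 - Pearson} distance
#' between bin profiles, cut at height \code{1 - minCorr}. Genes are
#' processed in lexicographic id order so the grouping is deterministic.
#' Groups smaller than \code{minSize} are flagged unselectable: a trend
#' group supported by only two genes is never carried forward.
#'
#' @param profiles genes x 6 matrix from \code{\link{binProfiles}}.
#' @param minCorr minimum within-group profile correlation.
#' @param minSize minimum group size for selectability.
#' @return A \linkS4class{PatternGroupSet} (nothing selected yet; see
#'   \code{\link{selectAgeGroups}}).
#' @export
clusterPatterns <- function(profiles, minCorr = 0.7, minSize = 3) {
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  n <- nrow(profiles)
  if (n < 2) {
    membership <- setNames(rep(1L, n), rownames(profiles))
    cent <- matrix(colMeans(profiles), 1, 6,
                   dimnames = list(NULL, ageBinLabels))
    return(new("PatternGroupSet", membership = membership,
               centroids = cent, slopeValues = slopeValue(cent[1, ]),
               selected = FALSE, direction = "none",
               selectable = n >= minSize))
  }
  s <- apply(profiles, 1, sd)
  z <- profiles
  z[s == 0, ] <- 0
  cc <- suppressWarnings(cor(t(z)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  membership <- cutree(hc, h = 1 - minCorr)
  names(membership) <- rownames(profiles)
  k <- max(membership)
  cent <- t(vapply(seq_len(k), function(g)
    colMeans(profiles[membership == g, , drop = FALSE]), numeric(6)))
  colnames(cent) <- ageBinLabels
  sizes <- tabulate(membership, k)
  new("PatternGroupSet",
      membership = as.integer(membership) |> setNames(names(membership)),
      centroids = cent,
      slopeValues = apply(cent, 1, slopeValue),
      selected = rep(FALSE, k),
      direction = rep("none", k),
      selectable = sizes >= minSize)
}

#' Slope value of an age-trajectory centroid
#'
#' The product of the two consecutive bin-mean differences beyond age 50:
#' \code{(m[60-69] - m[50-59]) * (m[70-79] - m[60-69])}. A positive value
#' means the trajectory keeps moving in one direction after 50 (consistent
#' aging trend); a negative value flags a reversal. The metric is invariant
#' to adding a constant to all bins and scales by c^2 under multiplication
#' by c > 0.
#'
#' @param centroid numeric vector of 6 decade-bin means (20-29 ... 70-79),
#'   or a matrix with 6 columns (one row per group).
#' @return numeric slope value(s).
#' @examples
#' slopeValue(c(0, 0, 0, 1, 2, 3))   #  1
#' slopeValue(c(0, 0, 0, 1, 2, 1))   # -1
#' @export
slopeValue <- function(centroid) {
  if (is.matrix(centroid)) return(apply(centroid, 1, slopeValue))
  if (length(centroid) != 6) stop("a centroid has exactly 6 decade bins")
  (centroid[5] - centroid[4]) * (centroid[6] - centroid[5])
}

#' Select aging-associated pattern groups
#'
#' A group is selected as a common aging trend when its slope value is
#' strictly positive, the move from 60-69 to 70-79 is at least
#' \code{flatEpsilon} z-units (groups whose last two bins sit in a similar
#' range are rejected as flat), and the group is selectable (size >=
#' minSize). Additionally, late-induction groups whose 70-79 mean exceeds
#' the maximum of all earlier bins by at least \code{spikeDelta} are
#' selected even though their slope is ~0. Direction is the sign of
#' \code{m[70-79] - m[50-59]}.
#'
#' @param groups a \linkS4class{PatternGroupSet}.
#' @param flatEpsilon minimum |m[70-79] - m[60-69]| (z-units).
#' @param spikeDelta minimum late-spike elevation over all earlier bins.
#' @return list with \code{agingUp}, \code{agingDown}
#'   (\linkS4class{GeneSet}s), and \code{groups} (the input with selection
#'   flags and directions filled in; late-spike selections are reported in
#'   the \code{spike} attribute of the returned groups object).
#' @export
selectAgeGroups <- function(groups, flatEpsilon = 0.05, spikeDelta = 0.5) {
  cent <- groups@centroids
  slopes <- groups@slopeValues
  gap <- cent[, 6] - cent[, 5]
  trend <- slopes > 0 & abs(gap) >= flatEpsilon
  spike <- (cent[, 6] - apply(cent[, 1:5, drop = FALSE], 1, max)) >=
    spikeDelta
  sel <- (trend | spike) & groups@selectable
  dirn <- ifelse(cent[, 6] - cent[, 4] > 0, "up",
                 ifelse(cent[, 6] - cent[, 4] < 0, "down", "none"))
  dirn[spike & !trend] <- "up"
  out <- groups
  out@selected <- as.logical(sel)
  out@direction <- ifelse(sel, dirn, "none")
  attr(out, "spike") <- as.logical(spike & groups@selectable)
  mem <- groups@membership
  upGenes <- names(mem)[mem %in% which(sel & dirn == "up")]
  downGenes <- names(mem)[mem %in% which(sel & dirn == "down")]
  list(agingUp = geneSet(upGenes, "aging_up", "up"),
       agingDown = geneSet(downGenes, "aging_down", "down"),
       groups = out)
}

#' Derive the LHA gene sets by aging-gene subtraction
#'
#' Longevity-and-healthy-aging (LHA) genes are the consensus DEGs that
#' remain after removing every gene found in any common aging-associated
#' set (trajectory-derived or external, e.g. a published meta-analysis
#' list). Every removal is logged with its source set.
#'
#' @param cdegUp,cdegDown consensus DEG \linkS4class{GeneSet}s.
#' @param agingSets list of aging \linkS4class{GeneSet}s.
#' @param externalAging optional additional \linkS4class{GeneSet}.
#' @return An \linkS4class{LHAResult}.
#' @export
deriveLHA <- function(cdegUp, cdegDown, agingSets = list(),
                      externalAging = NULL) {
  if (!is.null(externalAging)) agingSets <- c(agingSets, list(externalAging))
  prov <- data.frame(gene = character(), direction = character(),
                     source = character())
  removeFrom <- function(set, dirn) {
    keep <- set@members
    for (ag in agingSets) {
      hit <- intersect(keep, ag@members)
      if (length(hit))
        prov <<- rbind(prov, data.frame(gene = hit, direction = dirn,
                                        source = ag@name))
      keep <- setdiff(keep, ag@members)
    }
    keep
  }
  upKeep <- removeFrom(cdegUp, "up")
  downKeep <- removeFrom(cdegDown, "down")
  new("LHAResult",
      up = geneSet(upKeep, "LHA_up", "up"),
      down = geneSet(downKeep, "LHA_down", "down"),
      removedAging = geneSet(unique(prov$gene), "removed_aging", "none"),
      provenance = prov)
}
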