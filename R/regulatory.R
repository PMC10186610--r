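#' Classify genes by correlation with a stimulus reference
#'
#' Pearson correlation of each query gene's expression profile with a
#' reference gene (e.g. the insulin receptor) across stimulus conditions;
#' class \code{positive}/\code{negative} when |r| reaches \code{rCut},
#' else \code{none}. Constant profiles have undefined correlation and are
#' classed \code{none} with a degenerate flag.
#'
#' @param series genes x conditions matrix (>= 3 conditions).
#' @param referenceGene row name of the reference.
#' @param queryGenes rows to classify (default: all but the reference).
#' @param rCut absolute-correlation threshold.
#' @return data.frame (gene, r, class, degenerate).
#' @export
stimulusCorrelation <- function(series, referenceGene, queryGenes = NULL,
                                rCut = 0.3) {
  series <- as.matrix(series)
  if (ncol(series) < 3) stop("need >= 3 conditions for correlation")
  if (!referenceGene %in% rownames(series))
    stop("reference gene not found in the series")
  if (is.null(queryGenes))
    queryGenes <- setdiff(rownames(series), referenceGene)
  ref <- series[referenceGene, ]
  if (sd(ref) == 0) stop("reference profile is constant")
  r <- vapply(queryGenes, function(g) {
    x <- series[g, ]
    if (sd(x) == 0) NA_real_ else cor(x, ref)
  }, numeric(1))
  cls <- ifelse(is.na(r), "none",
                ifelse(r >= rCut, "positive",
                       ifelse(r <= -rCut, "negative", "none")))
  data.frame(gene = queryGenes, r = unname(r), class = unname(cls),
             degenerate = is.na(r))
}

#' Promoter windows around transcription start sites
#'
#' Promoter = [TSS - upstream, TSS + downstream) in 0-based half-open
#' terms, strand-mirrored for minus-strand genes and clipped at the
#' chromosome origin. Implemented on \code{GRanges} (1-based closed), so a
#' plus-strand gene starting at position 10001 with the defaults spans
#' 8001-10500.
#'
#' @param genes \code{GRanges} of gene bodies with strand (\code{*}
#'   treated as \code{+}).
#' @param upstream,downstream window size in bp around the TSS.
#' @return \code{GRanges} of promoter windows (same names/metadata).
#' @export
promotersFromGenes <- function(genes, upstream = 2000, downstream = 500) {
  g <- genes
  BiocGenerics::strand(g)[BiocGenerics::strand(g) == "*"] <- "+"
  p <- GenomicRanges::promoters(g, upstream = upstream,
                                downstream = downstream)
  BiocGenerics::start(p) <- pmax(BiocGenerics::start(p), 1L)
  p
}

#' Overlapping interval pairs
#'
#' All pairs of intervals from two sets that overlap (half-open test:
#' a.start < b.end and b.start < a.end in 0-based terms, the standard
#' \code{GRanges} any-overlap). Equivalent to the quadratic all-pairs
#' check.
#'
#' @param a,b \code{GRanges}.
#' @return data.frame (queryIndex, subjectIndex, queryName, subjectName).
#' @export
intervalOverlap <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  nm <- function(x, i) {
    n <- names(x)
    if (is.null(n)) {
      mc <- S4Vectors::mcols(x)
      n <- if ("name" %in% colnames(mc)) as.character(mc$name)
           else as.character(seq_along(x))
    }
    n[i]
  }
  data.frame(queryIndex = qi, subjectIndex = si,
             queryName = nm(a, qi), subjectName = nm(b, si))
}

#' Promoter-binding ratio per LHA cluster
#'
#' Fraction of each cluster's genes whose promoter carries a binding site
#' (membership in \code{boundGenes}), with an upper-tail hypergeometric
#' enrichment p against the universe. Duplicate peaks do not matter: a
#' gene is counted once.
#'
#' @param lhaClusters named list of cluster \linkS4class{GeneSet}s.
#' @param boundGenes \linkS4class{GeneSet} of promoter-bound genes.
#' @param universe character vector of background genes.
#' @return data.frame (cluster, size, bound, ratio, p, padj).
#' @export
bindingRatioPerCluster <- function(lhaClusters, boundGenes, universe) {
  bound <- intersect(unique(boundGenes@members), universe)
  rows <- lapply(names(lhaClusters), function(cl) {
    g <- intersect(lhaClusters[[cl]]@members, universe)
    ov <- length(intersect(g, bound))
    data.frame(cluster = cl, size = length(g), bound = ov,
               ratio = if (length(g)) ov / length(g) else NA_real_,
               p = hypergeometricOverlapP(length(universe), length(g),
                                          length(bound), ov))
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out
}

#' Phagocyte-specific transcription factor filter
#'
#' Retains a TF when its minimum cell-type score over the professional
#' phagocyte types strictly exceeds \code{foldCut} times its maximum score
#' over all other types, after shifting all scores so the global minimum
#' is zero (scores from \code{\link{geneCellScores}} are signed). Equality
#' at the boundary is rejected.
#'
#' @param tfScores TFs x cell types score matrix.
#' @param phagocyteTypes column names of the phagocyte types (e.g.
#'   monocytes, dendritic cells).
#' @param foldCut specificity fold requirement.
#' @return character vector of retained TF names.
#' @export
tfSpecificityFilter <- function(tfScores, phagocyteTypes, foldCut = 2) {
  if (!all(phagocyteTypes %in% colnames(tfScores)))
    stop("unknown phagocyte type column")
  shifted <- tfScores - min(tfScores)
  other <- setdiff(colnames(tfScores), phagocyteTypes)
  minPh <- apply(shifted[, phagocyteTypes, drop = FALSE], 1, min)
  maxOther <- if (length(other))
    apply(shifted[, other, drop = FALSE], 1, max) else 0
  rownames(tfScores)[minPh > foldCut * maxOther]
}

#' TF-target enrichment in a query set
#'
#' Per TF, an upper-tail hypergeometric test of its target genes against
#' the query set over the universe, Benjamini-Hochberg adjusted across
#' TFs.
#'
#' @param tfTable named list: TF -> character vector of target genes.
#' @param query non-empty \linkS4class{GeneSet}.
#' @param universe character vector of background genes.
#' @return data.frame (tf, targets, overlap, p, padj) sorted by p.
#' @export
tfTargetEnrichment <- function(tfTable, query, universe) {
  q <- intersect(query@members, universe)
  if (!length(q)) stop("query set is empty over the universe")
  rows <- lapply(names(tfTable), function(tf) {
    tg <- intersect(unique(tfTable[[tf]]), universe)
    ov <- length(intersect(tg, q))
    data.frame(tf = tf, targets = length(tg), overlap = ov,
               p = hypergeometricOverlapP(length(universe), length(tg),
                                          length(q), ov))
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out[order(out$p), ]
}
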