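#' @import methods
#' @import stats
#' @import utils
#' @importFrom tools md5sum
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Directional gene set
#'
#' A named set of gene identifiers with an optional direction of regulation.
#' Used for differentially expressed gene (DEG) calls, consensus DEG (cDEG)
#' sets, aging gene sets and longevity-and-healthy-aging (LHA) sets alike.
#'
#' @slot name single character label.
#' @slot direction one of \code{"up"}, \code{"down"}, \code{"none"}.
#' @slot members character vector of unique gene identifiers.
#'
#' @exportClass GeneSet
setClass("GeneSet",
  representation(name = "character", direction = "character",
                 members = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (length(object@direction) != 1L ||
      !object@direction %in% c("up", "down", "none"))
    msg <- c(msg, "'direction' must be one of 'up', 'down', 'none'")
  if (anyDuplicated(object@members))
    msg <- c(msg, "duplicate members in gene set")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param members character vector of gene ids (duplicates removed).
#' @param name set label.
#' @param direction \code{"up"}, \code{"down"} or \code{"none"}.
#' @return A \linkS4class{GeneSet}.
#' @examples
#' geneSet(c("G1", "G2"), name = "demo", direction = "up")
#' @export
geneSet <- function(members, name = "set", direction = "none") {
  new("GeneSet", name = name, direction = direction,
      members = unique(as.character(members)))
}

#' @describeIn geneSet Number of member genes.
#' @param x,object a \code{GeneSet}.
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet '", object@name, "' (", object@direction, "): ",
      length(object@members), " genes\n", sep = "")
  if (length(object@members))
    cat("  ", paste(head(object@members, 6), collapse = ", "),
        if (length(object@members) > 6) ", ..." else "", "\n", sep = "")
})

#' Accessors for GeneSet
#'
#' @param x a \linkS4class{GeneSet}.
#' @return \code{members} returns the character vector of gene ids;
#'   \code{direction} the direction label; \code{setName} the set name.
#' @export
members <- function(x) x@members

#' @rdname members
#' @export
direction <- function(x) x@direction

#' @rdname members
#' @export
setName <- function(x) x@name

#' Permutation overlap null summary
#'
#' Result of drawing random gene sets of the observed sizes from a universe
#' and recording the k-way intersection size, used to judge whether the
#' observed consensus DEG overlap exceeds chance.
#'
#' @slot observed observed k-way overlap count.
#' @slot nullMean,nullSd moments of the permutation null.
#' @slot empiricalP add-one empirical upper-tail p-value.
#' @slot nPerm number of permutations.
#' @slot analyticExpectation N * prod(n_i / N), the independence expectation.
#' @slot nullDistribution the permuted overlap counts.
#'
#' @exportClass OverlapNull
setClass("OverlapNull",
  representation(observed = "integer", nullMean = "numeric",
                 nullSd = "numeric", empiricalP = "numeric",
                 nPerm = "integer", analyticExpectation = "numeric",
                 nullDistribution = "integer"))

setValidity("OverlapNull", function(object) {
  msg <- character()
  if (!is.na(object@empiricalP) &&
      (object@empiricalP <= 0 || object@empiricalP > 1))
    msg <- c(msg, "empiricalP must lie in (0, 1]")
  if (object@nullMean < 0) msg <- c(msg, "nullMean must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapNull", function(object) {
  cat("OverlapNull: observed =", object@observed,
      "| null mean =", signif(object@nullMean, 4),
      "sd =", signif(object@nullSd, 4), "\n")
  cat("  analytic expectation =", signif(object@analyticExpectation, 4),
      "| empirical p =", signif(object@empiricalP, 4),
      "(", object@nPerm, "permutations )\n")
})

#' Age-trajectory pattern groups
#'
#' Clusters of genes sharing a decade-binned z-profile, each summarised by a
#' centroid over the six decade bins (20-29 ... 70-79), a slope value over the
#' last three bins, and selection flags for the common-aging gene derivation.
#'
#' @slot membership named integer vector, gene id -> group id.
#' @slot centroids groups x 6 matrix of mean bin profiles.
#' @slot slopeValues per-group slope metric.
#' @slot selected per-group logical, TRUE if the group passes the aging
#'   trend selection rules.
#' @slot direction per-group "up"/"down"/"none".
#' @slot selectable per-group logical, FALSE for groups below the minimum
#'   size (never selected regardless of slope).
#'
#' @exportClass PatternGroupSet
setClass("PatternGroupSet",
  representation(membership = "integer", centroids = "matrix",
                 slopeValues = "numeric", selected = "logical",
                 direction = "character", selectable = "logical"))

setValidity("PatternGroupSet", function(object) {
  msg <- character()
  if (ncol(object@centroids) != 6L)
    msg <- c(msg, "centroids must have exactly 6 decade-bin columns")
  k <- nrow(object@centroids)
  if (length(object@slopeValues) != k || length(object@selected) != k ||
      length(object@direction) != k || length(object@selectable) != k)
    msg <- c(msg, "per-group slots must match the number of groups")
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by gene id")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatternGroupSet", function(object) {
  cat("PatternGroupSet:", nrow(object@centroids), "groups over",
      length(object@membership), "genes;",
      sum(object@selected), "selected as aging-associated\n")
})

#' Pattern-group accessors
#'
#' @param x a \linkS4class{PatternGroupSet}.
#' @return \code{groupMembership}: named gene -> group vector;
#'   \code{groupCentroids}: groups x 6 bin-mean matrix;
#'   \code{slopeValues}: per-group slope metric.
#' @name patternGroups
NULL

#' @rdname patternGroups
#' @export
groupMembership <- function(x) x@membership

#' @rdname patternGroups
#' @export
groupCentroids <- function(x) x@centroids

#' @rdname patternGroups
#' @export
slopeValues <- function(x) x@slopeValues

#' Gene set enrichment result
#'
#' Weighted Kolmogorov-Smirnov enrichment of a gene set against a ranked
#' list, with a gene-label permutation null.
#'
#' @slot setName gene set label.
#' @slot ES enrichment score in [-1, 1].
#' @slot NES ES normalised by the mean |null ES| of the same sign.
#' @slot p add-one empirical same-sign tail p (NA if too few same-sign
#'   null scores).
#' @slot nPerm number of permutations.
#' @slot leadingEdge genes contributing up to the running-sum extremum.
#' @slot nullES the permuted enrichment scores.
#'
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(setName = "character", ES = "numeric", NES = "numeric",
                 p = "numeric", nPerm = "integer",
                 leadingEdge = "character", nullES = "numeric"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (abs(object@ES) > 1 + 1e-12) msg <- c(msg, "ES must lie in [-1, 1]")
  if (!is.na(object@NES) && sign(object@NES) != sign(object@ES) &&
      object@ES != 0)
    msg <- c(msg, "NES must share the sign of ES")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult '", object@setName, "': ES = ",
      signif(object@ES, 4), ", NES = ", signif(object@NES, 4),
      ", p = ", signif(object@p, 4), " (", object@nPerm, " perms)\n",
      sep = "")
})

#' Cell-type proportion estimates
#'
#' Per-sample immune cell-type proportions from non-negative least squares
#' deconvolution against a signature matrix.
#'
#' @slot proportions samples x cell types matrix, rows sum to 1.
#' @slot residualNorm per-sample residual L2 norm of the NNLS fit.
#' @slot degenerate per-sample flag, TRUE where the solver returned the zero
#'   vector and a uniform composition was substituted.
#' @slot method short description of the solver.
#'
#' @exportClass ProportionEstimate
setClass("ProportionEstimate",
  representation(proportions = "matrix", residualNorm = "numeric",
                 degenerate = "logical", method = "character"))

setValidity("ProportionEstimate", function(object) {
  msg <- character()
  p <- object@proportions
  if (any(p < -1e-9)) msg <- c(msg, "proportions must be non-negative")
  if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "each sample's proportions must sum to 1")
  if (length(object@residualNorm) != nrow(p))
    msg <- c(msg, "residualNorm length must match the number of samples")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProportionEstimate", function(object) {
  cat("ProportionEstimate:", nrow(object@proportions), "samples x",
      ncol(object@proportions), "cell types (", object@method, ")\n")
})

#' @rdname nnlsProportions
#' @param x a \code{ProportionEstimate}.
#' @export
proportions <- function(x) x@proportions

#' @rdname nnlsProportions
#' @export
residualNorms <- function(x) x@residualNorm

#' Longevity-and-healthy-aging gene sets
#'
#' cDEG sets after subtraction of common aging-associated genes, with a
#' provenance log of every removal.
#'
#' @slot up,down the LHA \linkS4class{GeneSet}s.
#' @slot removedAging all genes removed, as a \linkS4class{GeneSet}.
#' @slot provenance data.frame (gene, direction, source) logging removals.
#'
#' @exportClass LHAResult
setClass("LHAResult",
  representation(up = "GeneSet", down = "GeneSet",
                 removedAging = "GeneSet", provenance = "data.frame"))

setValidity("LHAResult", function(object) {
  msg <- character()
  if (length(intersect(object@up@members, object@removedAging@members)))
    msg <- c(msg, "LHA up set must be disjoint from removed aging genes")
  if (length(intersect(object@down@members, object@removedAging@members)))
    msg <- c(msg, "LHA down set must be disjoint from removed aging genes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LHAResult", function(object) {
  cat("LHAResult:", length(object@up@members), "up,",
      length(object@down@members), "down LHA genes;",
      length(object@removedAging@members), "aging genes removed\n")
})

#' @rdname deriveLHA
#' @param x an \code{LHAResult}.
#' @export
lhaUp <- function(x) x@up

#' @rdname deriveLHA
#' @export
lhaDown <- function(x) x@down

#' @rdname deriveLHA
#' @export
removedAging <- function(x) x@removedAging

#' Co-expression module assignment
#'
#' @slot membership named integer vector gene -> module id (0 = unassigned).
#' @slot power soft-threshold power used for the adjacency.
#' @slot minSize minimum module size enforced.
#'
#' @exportClass ModuleAssignment
setClass("ModuleAssignment",
  representation(membership = "integer", power = "numeric",
                 minSize = "integer"))

setValidity("ModuleAssignment", function(object) {
  sizes <- table(object@membership[object@membership > 0L])
  if (length(sizes) && any(sizes < object@minSize))
    "non-zero modules must respect the minimum size" else TRUE
})

setMethod("show", "ModuleAssignment", function(object) {
  k <- object@membership
  cat("ModuleAssignment:", length(unique(k[k > 0])), "modules over",
      length(k), "genes (", sum(k == 0), "unassigned ); power =",
      object@power, "\n")
})

#' @rdname detectModules
#' @param x a \code{ModuleAssignment}.
#' @export
moduleMembership <- function(x) x@membership
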