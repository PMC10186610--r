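#' Intersect directional gene sets across cohorts
#'
#' The consensus DEGs (cDEGs) are the genes called in the same direction in
#' every cohort: the exact intersection of the member lists.
#'
#' @param sets list of at least two \linkS4class{GeneSet}s.
#' @param direction optional; when given, all sets must carry it.
#' @param name label for the result.
#' @return A \linkS4class{GeneSet} (direction inherited from the inputs).
#' @export
intersectSets <- function(sets, direction = NULL, name = "consensus") {
  if (length(sets) < 2) stop("need at least two sets to intersect")
  dirs <- vapply(sets, function(s) s@direction, character(1))
  if (!is.null(direction) && !all(dirs == direction))
    stop("all sets must share direction '", direction, "'")
  common <- Reduce(intersect, lapply(sets, members))
  geneSet(common, name = name,
          direction = if (length(unique(dirs)) == 1) dirs[1] else "none")
}

#' Permutation null for a k-way gene-set overlap
#'
#' Draws, in each permutation, one uniform random subset of the gene
#' universe per cohort, matching the observed per-cohort set sizes, and
#' records the size of their k-way intersection. The analytic independence
#' expectation is \code{N * prod(n_i / N)}. The empirical p-value uses the
#' add-one convention \code{(1 + #(null >= observed)) / (nPerm + 1)} and is
#' only computed when \code{observed} is supplied.
#'
#' @param universeSize number of genes drawn from.
#' @param setSizes integer sizes of the cohort DEG sets (each <= universe).
#' @param observed the observed overlap count (optional).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return An \linkS4class{OverlapNull}.
#' @examples
#' permutationOverlapNull(1000, c(100, 100), nPerm = 200, seed = 1)
#' @export
permutationOverlapNull <- function(universeSize, setSizes, observed = NA,
                                   nPerm = 10000, seed = 1L) {
  setSizes <- as.integer(setSizes)
  if (any(setSizes > universeSize))
    stop("a set size exceeds the universe size")
  if (nPerm < 100) stop("need at least 100 permutations")
  set.seed(seed)
  k <- length(setSizes)
  nulls <- integer(nPerm)
  hits <- integer(universeSize)
  for (i in seq_len(nPerm)) {
    hits[] <- 0L
    for (s in setSizes) {
      idx <- sample.int(universeSize, s)
      hits[idx] <- hits[idx] + 1L
    }
    nulls[i] <- sum(hits == k)
  }
  emp <- if (is.na(observed)) NA_real_ else
    (1 + sum(nulls >= observed)) / (nPerm + 1)
  new("OverlapNull",
      observed = as.integer(observed), nullMean = mean(nulls),
      nullSd = sd(nulls), empiricalP = emp, nPerm = as.integer(nPerm),
      analyticExpectation = universeSize * prod(setSizes / universeSize),
      nullDistribution = nulls)
}

#' Fraction of a query set found in a reference set
#'
#' \code{100 * |query cap reference| / |query|}; the statistic used to
#' compare Hainan cDEGs with the Leiden nonagenarian DEG lists.
#'
#' @param query,reference \linkS4class{GeneSet}s.
#' @return overlap percentage (0-100).
#' @export
overlapFraction <- function(query, reference) {
  if (!length(query@members)) stop("empty query set")
  100 * length(intersect(query@members, reference@members)) /
    length(query@members)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' \code{P(X >= observed)} for the overlap of two sets of sizes
#' \code{sizeA} and \code{sizeB} drawn from a universe of
#' \code{universeSize} genes.
#'
#' @param universeSize,sizeA,sizeB,observed integers.
#' @return p-value in (0, 1].
#' @export
hypergeometricOverlapP <- function(universeSize, sizeA, sizeB, observed) {
  stopifnot(sizeA <= universeSize, sizeB <= universeSize,
            observed <= min(sizeA, sizeB))
  phyper(observed - 1, sizeA, universeSize - sizeA, sizeB,
         lower.tail = FALSE)
}
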