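# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (enumeration, direct loops)
# rather than calling the package's vectorised implementations.

# Upper-tail hypergeometric P(X >= obs) by exhaustive enumeration of all
# C(N, b) draws against the fixed set 1..a.
bruteHypergeom <- function(N, a, b, obs) {
  draws <- combn(N, b)
  overlaps <- colSums(draws <= a)
  mean(overlaps >= obs)
}

# Benjamini-Hochberg step-up by definition.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Unweighted/weighted KS running sum by direct position-by-position loop.
# Ties between the positive and negative extremum resolve to the positive
# one, matching the package's documented convention.
bruteES <- function(scores, hitIdx, weightP = 0) {
  N <- length(scores)
  isHit <- seq_len(N) %in% hitIdx
  w <- abs(scores)^weightP
  denom <- sum(w[isHit])
  run <- 0
  mx <- -Inf
  mn <- Inf
  for (i in seq_len(N)) {
    run <- run + if (isHit[i]) {
      if (denom == 0) 1 / sum(isHit) else w[i] / denom
    } else -1 / (N - sum(isHit))
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  unname(if (mx >= -mn - 1e-9) mx else mn)
}

# All-pairs interval overlap on 1-based closed intervals.
bruteOverlapPairs <- function(s1, e1, s2, e2) {
  pairs <- NULL
  for (i in seq_along(s1))
    for (j in seq_along(s2))
      if (s1[i] <= e2[j] && s2[j] <= e1[i])
        pairs <- rbind(pairs, c(i, j))
  pairs
}

# Adjusted Rand index via mclust (independent of the package).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Expression SummarizedExperiment built directly from a matrix + metadata.
makeExprSE <- function(m, md = NULL) {
  if (is.null(md)) md <- data.frame(row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = m),
    colData = S4Vectors::DataFrame(md, row.names = colnames(m)))
}

# Block-structured expression for co-expression recovery tests: each block
# follows a latent factor; background genes are independent noise.
makeBlockData <- function(nBlocks = 3, blockSize = 50, nNoise = 30,
                          nSamples = 40, load = 0.9, seed = 1) {
  set.seed(seed)
  nG <- nBlocks * blockSize + nNoise
  truth <- c(rep(seq_len(nBlocks), each = blockSize), rep(0L, nNoise))
  m <- matrix(rnorm(nG * nSamples), nG, nSamples)
  for (b in seq_len(nBlocks)) {
    f <- rnorm(nSamples)
    idx <- which(truth == b)
    m[idx, ] <- load * matrix(f, length(idx), nSamples, byrow = TRUE) +
      sqrt(1 - load^2) * m[idx, , drop = FALSE]
  }
  dimnames(m) <- list(sprintf("G%06d", seq_len(nG)),
                      sprintf("s%03d", seq_len(nSamples)))
  list(m = m, truth = truth)
}
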