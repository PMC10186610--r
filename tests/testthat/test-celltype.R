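cellsSE <- function(m, labels) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = m),
    colData = S4Vectors::DataFrame(cellType = labels,
                                   row.names = colnames(m)))
}

test_that("cell-type ranking puts exclusive markers on top", {
  m <- matrix(1, 5, 6, dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  lab <- rep(c("Mono", "T"), each = 3)
  m["g3", lab == "Mono"] <- 5          # exclusive marker
  r <- rankGenesForCelltype(cellsSE(m, lab), "Mono")
  expect_identical(names(r)[1], "g3")
  expect_equal(unname(r["g1"]), 0)     # uniform gene scores 0
  # two-type symmetry: swapping the target negates scores
  r2 <- rankGenesForCelltype(cellsSE(m, lab), "T")
  expect_equal(unname(r2[names(r)]), -unname(r), tolerance = 1e-12)
})

test_that("enrichment scores equal the brute-force KS running sum", {
  set.seed(8)
  for (i in 1:30) {
    N <- sample(8:20, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:N)
    k <- sample(2:(N - 2), 1)
    hit <- sort(sample(N, k))
    for (wp in c(0, 1)) {
      es <- gsea(scores, names(scores)[hit], weightP = wp, nPerm = 100,
                 seed = 1)@ES
      expect_equal(es, bruteES(scores, hit, wp), tolerance = 1e-12)
    }
  }
  # top-k set reaches the maximal deviation computed by the oracle
  scores <- sort(rnorm(15), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:15)
  es <- gsea(scores, names(scores)[1:4], weightP = 0, nPerm = 100,
             seed = 1)@ES
  expect_equal(es, bruteES(scores, 1:4, 0), tolerance = 1e-12)
  expect_equal(es, 1, tolerance = 1e-12)
})

test_that("unweighted |ES| is invariant to reversing the ranked list", {
  set.seed(9)
  scores <- sort(rnorm(30), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:30)
  hit <- names(scores)[c(2, 5, 9, 20)]
  esF <- gsea(scores, hit, weightP = 0, nPerm = 100, seed = 1)@ES
  rev_ <- rev(scores)
  esR <- gsea(rev_, hit, weightP = 0, nPerm = 100, seed = 1)@ES
  expect_equal(abs(esF), abs(esR), tolerance = 1e-12)
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(10)
  for (i in 1:10) {
    N <- 50
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:N)
    hit <- sample(names(scores), 8)
    ours <- gsea(scores, hit, weightP = 1, nPerm = 100, seed = 1)@ES
    ref <- fgsea::calcGseaStat(scores, which(names(scores) %in% hit),
                               gseaParam = 1, returnAllExtremes = FALSE)
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("gsea guards degenerate sets and reports sane NES", {
  scores <- sort(rnorm(20), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:20)
  expect_error(gsea(scores, c("zz1", "zz2")), "disjoint")
  expect_error(gsea(scores, names(scores)), "whole ranked list")
  res <- gsea(scores, names(scores)[1:5], nPerm = 500, seed = 2)
  expect_true(abs(res@ES) <= 1)
  expect_equal(sign(res@NES), sign(res@ES))
  expect_gt(res@p, 0)
  expect_lte(res@p, 1)
})

test_that("gene-cell scores are conserved z-scores", {
  set.seed(11)
  m <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("c%02d", 1:40)))
  lab <- rep(c("Mono", "NK", "T", "B"), each = 10)
  m["g01", ] <- 7                       # equal everywhere
  m["g02", lab == "Mono"] <- m["g02", lab == "Mono"] + 10
  sc <- geneCellScores(cellsSE(m, lab))
  expect_equal(unname(sc["g01", ]), rep(0, 4))
  expect_identical(names(which.max(sc["g02", ])), "Mono")
  # type-size-weighted row means vanish (z-score conservation)
  sizes <- table(lab)[colnames(sc)]
  expect_equal(unname(sc %*% as.numeric(sizes))[, 1] / sum(sizes),
               rep(0, 30), tolerance = 1e-12)
  # invariant to cell order
  perm <- sample(40)
  sc2 <- geneCellScores(cellsSE(m[, perm], lab[perm]))
  expect_equal(sc2, sc, tolerance = 1e-12)
})

test_that("score clustering recovers planted programs", {
  set.seed(12)
  centers <- rbind(c(3, 0, 0, 0), c(0, 3, 0, 0))
  sc0 <- centers[rep(1:2, each = 15), ]
  rownames(sc0) <- sprintf("g%02d", 1:30)
  colnames(sc0) <- c("Mono", "NK", "T", "B")
  cl <- clusterGeneScores(sc0, k = 2, seed = 1)
  expect_equal(ari(cl, rep(1:2, each = 15)), 1)
  expect_true(all(clusterGeneScores(sc0, k = 1) == 1))

  aris <- vapply(1:10, function(s) {
    sim <- simulateCelltypeProfiles(nGenes = 120,
      cellTypes = c(Monocyte = 25, DC = 25, NK = 25, CD8T = 25,
                    T = 25, B = 25),
      markersPerType = 0,
      programs = list(
        p1 = list(genes = 1:30, types = c("Monocyte", "DC"), effect = 2),
        p2 = list(genes = 31:60, types = c("NK", "CD8T"), effect = 2),
        p3 = list(genes = 61:90, types = "T", effect = 2),
        p4 = list(genes = 91:120, types = "B", effect = 2)),
      noiseSd = 0.3, seed = 500 + s)
    sc <- geneCellScores(sim$se)
    cl <- clusterGeneScores(sc, k = 4, seed = 1)
    ari(cl, rep(1:4, each = 30))
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("signature scores are mean member z-scores", {
  set.seed(13)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  m[1:2, ] <- 4                           # constant genes
  expect_equal(unname(signatureScore(m, paste0("g", 1:2))), rep(0, 12))
  # equals the mean of per-gene z-scores, computed independently
  sub <- m[3:6, ]
  zOracle <- t(apply(sub, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(signatureScore(m, paste0("g", 3:6)), colMeans(zOracle),
               tolerance = 1e-12)
  # genes split between sample halves score a difference of 1/sd, i.e.
  # the shift expressed in z-units
  half <- matrix(rep(c(1, 0), c(10, 10)), 4, 20, byrow = TRUE,
                 dimnames = list(paste0("h", 1:4), paste0("s", 1:20)))
  sHalf <- signatureScore(half, paste0("h", 1:4))
  expect_equal(mean(sHalf[1:10]) - mean(sHalf[11:20]),
               1 / sd(half[1, ]), tolerance = 1e-12)
  # linearity over a disjoint union of equal-size sets
  sA <- signatureScore(m, paste0("g", 3:5))
  sB <- signatureScore(m, paste0("g", 6:8))
  sAB <- signatureScore(m, paste0("g", 3:8))
  expect_equal(sAB, (sA + sB) / 2, tolerance = 1e-12)
})

test_that("over-representation analysis matches the enumeration oracle", {
  uni <- sprintf("u%02d", 1:12)
  pws <- list(geneSet(uni[1:6], "pw1"), geneSet(uni[7:8], "pw2"))
  names(pws) <- c("pw1", "pw2")
  q <- geneSet(uni[c(1:4, 7)], "q")
  tab <- oraHypergeometric(q, pws, uni)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$p[i],
                 bruteHypergeom(12, 5, tab$size[i], tab$overlap[i]),
                 tolerance = 1e-12)
  }
  dis <- oraHypergeometric(geneSet(uni[9:10], "q2"),
                           list(pw = geneSet(uni[1:3], "pw")), uni)
  expect_equal(dis$p, 1)
})

test_that("one-way ANOVA reduces to the squared t with two groups", {
  set.seed(14)
  x <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  res <- anovaAcrossGroups(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(unname(res["F"]), unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(unname(res["p"]), tt$p.value, tolerance = 1e-10)
  # all groups identical in mean with no between variance
  y <- rep(c(1, 2), 6)
  expect_equal(unname(anovaAcrossGroups(y, rep(c("a", "b", "c"), 4))["F"]),
               0, tolerance = 1e-12)
  # calibration under the null
  ps <- vapply(1:500, function(i)
    unname(anovaAcrossGroups(rnorm(30), rep(c("a", "b", "c"), 10))["p"]),
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
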