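test_that("delta beta is an antisymmetric group-mean difference", {
  sim <- simulateMethylome(nProbes = 100, seed = 1)
  expect_equal(unname(deltaBeta(sim$betaA, sim$betaA)), rep(0, 100))
  expect_equal(deltaBeta(sim$betaA, sim$betaB),
               -deltaBeta(sim$betaB, sim$betaA), tolerance = 1e-12)
  shifted <- pmin(sim$betaA + 0.1, 1)
  inRange <- rowSums(sim$betaA > 0.85) == 0
  db <- deltaBeta(sim$betaA, shifted)
  expect_equal(unname(db[inRange]), rep(0.1, sum(inRange)),
               tolerance = 1e-12)
  expect_error(deltaBeta(sim$betaA[1:50, ], sim$betaB), "identical")
})

test_that("skewness g1 follows the moment definition", {
  expect_equal(skewnessG1(c(-2, -1, 0, 1, 2)), 0)
  x <- c(0, 0, 0, -1)
  # by hand: m2 = 0.1875, m3 = -0.09375, g1 = -2/sqrt(3)
  expect_equal(skewnessG1(x), -2 / sqrt(3), tolerance = 1e-12)
  expect_equal(skewnessG1(rep(4, 10)), 0)
})

test_that("skewness matches the independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(2)
  for (i in 1:20) {
    x <- rexp(200) - runif(1)
    expect_equal(skewnessG1(x), e1071::skewness(x, type = 1),
                 tolerance = 1e-10)
  }
})

test_that("a planted global hypomethylation shift yields negative skewness", {
  gs <- vapply(1:20, function(s) {
    sim <- simulateMethylome(nProbes = 3000, globalShiftFrac = 0.15,
                             seed = 800 + s)
    skewnessG1(deltaBeta(sim$betaA, sim$betaB))
  }, numeric(1))
  expect_gte(mean(gs < 0), 0.95)
})

test_that("DMP calling is specific on null data and sensitive on planted", {
  null <- simulateMethylome(nProbes = 10000, seed = 7)
  dm0 <- callDMPs(null$betaA, null$betaB)
  expect_lte(sum(dm0$call != "ns"), 5)

  sens <- fdr <- numeric(10)
  for (s in 1:10) {
    sim <- simulateMethylome(nProbes = 4000, hyperProbes = 1:100,
                             hypoProbes = 101:200, deltaBeta = 0.2,
                             seed = 900 + s)
    dm <- callDMPs(sim$betaA, sim$betaB, dCut = 0.1, pCut = 0.01)
    calls <- dm$probe[dm$call != "ns"]
    truth <- sim$truth$probe[sim$truth$role != "null"]
    correctDir <- sum(dm$call[1:100] == "hyper") +
      sum(dm$call[101:200] == "hypo")
    sens[s] <- correctDir / 200
    fdr[s] <- if (length(calls)) mean(!calls %in% truth) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.05)
})

test_that("DMP calls respect thresholds and group-swap symmetry", {
  sim <- simulateMethylome(nProbes = 500, hyperProbes = 1:20,
                           hypoProbes = 21:40, seed = 3)
  dm <- callDMPs(sim$betaA, sim$betaB)
  swap <- callDMPs(sim$betaB, sim$betaA)
  expect_equal(dm$delta_beta, -swap$delta_beta, tolerance = 1e-12)
  expect_identical(dm$call == "hyper", swap$call == "hypo")
  # a large delta with a hopeless p stays ns
  a <- matrix(c(0.2, 0.5, 0.4, 0.6), 1, 4)
  b <- matrix(c(0.5, 0.3, 0.8, 0.4), 1, 4)
  rownames(a) <- rownames(b) <- "cg1"
  one <- callDMPs(a, b, dCut = 0.1, pCut = 0.01)
  expect_identical(one$call, "ns")
  expect_error(callDMPs(a[, 1, drop = FALSE], b), ">= 2 samples")
})

test_that("probe-to-gene mapping dedups and counts unannotated probes", {
  dmps <- data.frame(probe = paste0("cg", 1:5),
                     call = c("hypo", "hypo", "hyper", "ns", "hypo"))
  ann <- data.frame(probe = paste0("cg", 1:4),
                    gene = c("GA", "GA", "GB", "GC"))
  mp <- mapProbesToGenes(dmps, ann)
  expect_identical(members(mp$hypo), "GA")    # two probes, one gene
  expect_identical(members(mp$hyper), "GB")
  expect_equal(mp$nUnannotated, 1)            # cg5 called but unannotated
  none <- mapProbesToGenes(data.frame(probe = "cg9", call = "ns"), ann)
  expect_length(members(none$hyper), 0)
  expect_length(members(none$hypo), 0)
})

test_that("LHA-cluster methylation classification uses the shared oracle", {
  uni <- sprintf("u%02d", 1:12)
  clusters <- list(C1 = geneSet(uni[1:4], "C1"), C2 = geneSet(uni[5:8], "C2"))
  hyper <- geneSet(uni[9:10], "hyper")
  hypo <- geneSet(uni[1:4], "hypo")           # C1 entirely hypo
  tab <- classifyLhaMethylation(hyper, hypo, clusters, uni)
  c1hypo <- tab[tab$cluster == "C1" & tab$direction == "hypo", ]
  expect_equal(c1hypo$overlap, 4)
  expect_equal(c1hypo$p, bruteHypergeom(12, 4, 4, 4), tolerance = 1e-12)
  c2hyper <- tab[tab$cluster == "C2" & tab$direction == "hyper", ]
  expect_equal(c2hyper$overlap, 0)
  expect_equal(c2hyper$p, 1)
  # bookkeeping: overlaps never exceed cluster or set sizes
  expect_true(all(tab$overlap <= pmin(tab$clusterSize, tab$methylated)))
})

test_that("planted cluster hypomethylation is detected end to end", {
  sim <- simulateMethylome(nProbes = 2000, hypoProbes = 1:60,
                           deltaBeta = 0.25, seed = 13)
  dm <- callDMPs(sim$betaA, sim$betaB)
  mp <- mapProbesToGenes(dm, sim$annotation)
  cluster1 <- geneSet(unique(sim$annotation$gene[1:60]), "C1")
  tab <- classifyLhaMethylation(mp$hyper, mp$hypo,
                                list(C1 = cluster1),
                                unique(sim$annotation$gene))
  expect_lt(tab$p[tab$direction == "hypo"], 0.05)
})
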