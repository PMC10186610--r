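cohorts2 <- function(n = 5) list(cohortSpec("A", n, n), cohortSpec("B", n, n))

test_that("multicohort simulation is reproducible and respects null configs", {
  s1 <- simulateMulticohortCounts(nGenes = 100, cohorts = cohorts2(),
                                  seed = 42)
  s2 <- simulateMulticohortCounts(nGenes = 100, cohorts = cohorts2(),
                                  seed = 42)
  expect_identical(SummarizedExperiment::assay(s1$cohorts$A),
                   SummarizedExperiment::assay(s2$cohorts$A))
  expect_identical(s1$truth, s2$truth)

  # no planted effects, no sex/batch variation: case and control marginal
  # means agree per gene up to sampling noise
  big <- simulateMulticohortCounts(nGenes = 500,
    cohorts = list(cohortSpec("A", 100, 100)),
    sexEffectSd = 0, batchEffectSd = 0, seed = 1)
  se <- big$cohorts$A
  grp <- SummarizedExperiment::colData(se)$group
  m <- SummarizedExperiment::assay(se)
  lr <- log2(rowMeans(m[, grp == "case"]) + 1) -
    log2(rowMeans(m[, grp == "control"]) + 1)
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("planted shared effects produce the generative case/control ratio", {
  sim <- simulateMulticohortCounts(nGenes = 1000,
    cohorts = list(cohortSpec("A", 30, 30), cohortSpec("B", 30, 30),
                   cohortSpec("C", 30, 30)),
    sharedUp = 1:100, effect = 1.0, sexEffectSd = 0, batchEffectSd = 0,
    seed = 3)
  ratios <- vapply(sim$cohorts, function(se) {
    grp <- SummarizedExperiment::colData(se)$group
    m <- SummarizedExperiment::assay(se)[1:100, ]
    lib <- colSums(SummarizedExperiment::assay(se))
    mean(rowMeans(sweep(m, 2, lib / mean(lib), "/")[, grp == "case"]) /
         rowMeans(sweep(m, 2, lib / mean(lib), "/")[, grp == "control"]))
  }, numeric(1))
  expect_true(all(abs(ratios - 2) / 2 < 0.1))
})

test_that("planted effect sizes converge to generative parameters at n = 200", {
  sim <- simulateMulticohortCounts(nGenes = 400,
    cohorts = list(cohortSpec("A", 200, 200)), sharedUp = 1:100,
    effect = 1.0, sexEffectSd = 0, batchEffectSd = 0,
    libSizeRange = c(1, 1), seed = 9)
  se <- sim$cohorts$A
  grp <- SummarizedExperiment::colData(se)$group
  m <- SummarizedExperiment::assay(se)
  ratio <- mean(rowMeans(m[1:100, grp == "case"]) /
                rowMeans(m[1:100, grp == "control"]))
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("age-series archetypes reproduce their noise-free bin profiles", {
  noisefree <- function(arch) simulateAgeSeries(nGenes = 10,
    archetypeGenes = setNames(5L, arch), nPerBin = 3, amplitude = 1,
    noiseSd = 0, dispersion = 0, seed = 2)
  binMeans <- function(sim, gene = 1) {
    m <- log2(SummarizedExperiment::assay(sim$se))
    tapply(m[gene, ], ageBins(SummarizedExperiment::colData(sim$se)$age),
           mean)
  }
  flat <- binMeans(noisefree("flat"))
  expect_equal(as.numeric(diff(flat)), rep(0, 5), tolerance = 1e-12)
  up <- binMeans(noisefree("monotone_up"))
  expect_true(all(diff(up) > 0))
  spikeSim <- simulateAgeSeries(nGenes = 10,
    archetypeGenes = c(late_spike = 5L),
    archetypes = ageArchetypes(spikeDelta = 0.8), nPerBin = 3,
    amplitude = 1, noiseSd = 0, dispersion = 0, seed = 2)
  spike <- binMeans(spikeSim)
  expect_equal(as.numeric(diff(spike[1:5])), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(spike[6] - spike[5]), 0.8, tolerance = 1e-12)
  expect_error(simulateAgeSeries(nPerBin = 1), "at least 2")
})

test_that("cell-type marker programs are elevated and recoverable", {
  pr <- list(mono = list(genes = 901:920, types = c("Monocyte", "DC"),
                         effect = 1.5))
  sim0 <- simulateCelltypeProfiles(nGenes = 1000, programs = pr,
                                   noiseSd = 0, seed = 1)
  m <- SummarizedExperiment::assay(sim0$se)
  lab <- SummarizedExperiment::colData(sim0$se)$cellType
  inProg <- lab %in% c("Monocyte", "DC")
  progMeans <- rowMeans(m[901:920, inProg, drop = FALSE])
  otherMeans <- rowMeans(m[901:920, !inProg, drop = FALSE])
  expect_true(all(progMeans > otherMeans))

  # fold-rank recovery under noise, 20 seeds
  hits <- vapply(1:20, function(s) {
    sim <- simulateCelltypeProfiles(nGenes = 200,
      cellTypes = c(Monocyte = 30, NK = 30, B = 30),
      markersPerType = 10,
      programs = list(p = list(genes = 101:120, types = "Monocyte",
                               effect = 1.5)),
      noiseSd = 0.5, seed = s)
    mm <- SummarizedExperiment::assay(sim$se)
    ll <- SummarizedExperiment::colData(sim$se)$cellType
    fold <- rowMeans(mm[, ll == "Monocyte"]) -
      rowMeans(mm[, ll != "Monocyte"])
    top <- names(sort(fold, decreasing = TRUE))[1:30]
    mean(sprintf("G%06d", 101:120) %in% top)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("methylome simulator hits its planted shifts and stays in (0,1)", {
  null <- simulateMethylome(nProbes = 10000, seed = 5)
  db <- deltaBeta(null$betaA, null$betaB)
  expect_lt(abs(mean(db)), 0.01)
  expect_lt(abs(skewnessG1(db)), 0.1)
  expect_true(all(null$betaA > 0 & null$betaA < 1))
  expect_true(all(null$betaB > 0 & null$betaB < 1))

  planted <- simulateMethylome(nProbes = 2000, hypoProbes = 1:100,
                               deltaBeta = 0.2, seed = 6)
  dbP <- deltaBeta(planted$betaA, planted$betaB)
  expect_lt(abs(mean(dbP[1:100]) - (-0.2)), 0.03)
})

test_that("mixture simulator honours its composition contracts", {
  sig <- simulateSignature(nGenes = 60, cellTypes = c("A", "B", "C"),
                           seed = 1)
  oneHot <- diag(3)
  mix <- simulateMixtures(sig, oneHot, noiseSd = 0, seed = 1)
  expect_equal(unname(mix$bulk[, 1]), unname(sig[, 1]), tolerance = 1e-12)
  eq <- matrix(1 / 3, 1, 3)
  mixEq <- simulateMixtures(sig, eq, noiseSd = 0, seed = 1)
  expect_equal(unname(mixEq$bulk[, 1]), unname(rowMeans(sig)),
               tolerance = 1e-12)
  noisy <- simulateMixtures(sig, randomProportions(20, 3, seed = 2),
                            noiseSd = 0.1, seed = 3)
  expect_equal(unname(rowSums(noisy$proportions)), rep(1, 20),
               tolerance = 1e-12)
})

test_that("planted index sets are validated", {
  expect_error(simulateMulticohortCounts(nGenes = 50,
    cohorts = cohorts2(), sharedUp = c(1, 60)), "1..n_genes")
  expect_error(simulateMulticohortCounts(nGenes = 50,
    cohorts = cohorts2(), sharedUp = 1:5, sharedDown = 3:8), "disjoint")
})
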