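test_that("the slope metric is the product of the last two bin steps", {
  expect_equal(slopeValue(c(0, 0, 0, 1, 2, 3)), 1)
  expect_equal(slopeValue(c(0, 0, 0, 1, 2, 1)), -1)
  # the flat-trajectory example: slope positive yet the last step tiny
  flatish <- c(0, 0, 0, 0, -0.16494, -0.20438)
  expect_equal(slopeValue(flatish), (-0.16494) * (-0.20438 + 0.16494),
               tolerance = 1e-12)
  expect_gt(slopeValue(flatish), 0)
  expect_lt(abs(-0.20438 - (-0.16494)), 0.05)   # rejected by the flat rule
  expect_error(slopeValue(1:5), "6 decade bins")
})

test_that("the slope metric has the required invariances", {
  set.seed(1)
  for (i in 1:50) {
    v <- rnorm(6)
    expect_equal(slopeValue(v + runif(1, -5, 5)), slopeValue(v),
                 tolerance = 1e-9)
    c0 <- runif(1, 0.1, 3)
    expect_equal(slopeValue(c0 * v), c0^2 * slopeValue(v),
                 tolerance = 1e-9)
    mono <- c(rnorm(3), sort(rnorm(3)) * sample(c(-1, 1), 1))
    if (!any(duplicated(mono[4:6]))) expect_gt(slopeValue(mono), 0)
  }
})

test_that("bin profiles are z-scaled decade means with affine invariance", {
  ages <- rep(c(25, 35, 45, 55, 65, 75), each = 3)
  m <- rbind(const = rep(5, 18), linear = ages + rnorm(18, 0, 1e-9))
  colnames(m) <- sprintf("s%02d", 1:18)
  prof <- binProfiles(m, ages)
  expect_equal(unname(prof["const", ]), rep(0, 6))
  expect_true(all(diff(prof["linear", ]) > 0))
  m2 <- m * 3.7 + 11
  expect_equal(binProfiles(m2, ages)["linear", ], prof["linear", ],
               tolerance = 1e-6)
})

test_that("age-association F-test is calibrated and powered", {
  # calibration: flat genes give uniform p
  simNull <- simulateAgeSeries(nGenes = 1000, archetypeGenes = integer(0),
                               nPerBin = 10, noiseSd = 0.3, seed = 31)
  aa <- ageAssociationTest(logNormalize(simNull$se))
  ks <- suppressWarnings(ks.test(aa$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # power: planted monotone genes detected at padj < 0.05
  det <- vapply(1:25, function(s) {
    sim <- simulateAgeSeries(nGenes = 150,
      archetypeGenes = c(monotone_up = 10), nPerBin = 20,
      amplitude = 1, noiseSd = 0.5, seed = 300 + s)
    aa <- ageAssociationTest(logNormalize(sim$se))
    mean(aa$padj[1:10] < 0.05)
  }, numeric(1))
  expect_gte(mean(det), 0.95)
})

test_that("covariate-only variation is not called age-associated", {
  set.seed(41)
  ages <- rep(c(25, 35, 45, 55, 65, 75), each = 4)
  sex <- rep(c("M", "F"), 12)
  m <- matrix(rnorm(20 * 24, sd = 0.1), 20, 24) +
    2 * matrix(as.numeric(sex == "M"), 20, 24, byrow = TRUE)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:24))
  se <- makeExprSE(m, data.frame(age = ages, sex = sex))
  aa <- ageAssociationTest(se, covariates = "sex")
  expect_gt(min(aa$p), 0.05 / 20)   # nothing significant after Bonferroni
})

test_that("pattern clustering separates archetypes and flags tiny groups", {
  arch <- ageArchetypes()
  prof <- rbind(
    matrix(rep(arch$monotone_up, 10), 10, 6, byrow = TRUE),
    matrix(rep(arch$rise_fall, 10), 10, 6, byrow = TRUE))
  rownames(prof) <- sprintf("G%06d", 1:20)
  pg <- clusterPatterns(prof)
  expect_equal(nrow(groupCentroids(pg)), 2)
  expect_true(all(table(groupMembership(pg)) == 10))

  # a 2-member group is never selectable
  prof2 <- rbind(prof,
                 matrix(rep(arch$monotone_down, 2) + 0, 2, 6, byrow = TRUE))
  rownames(prof2) <- sprintf("G%06d", 1:22)
  pg2 <- clusterPatterns(prof2, minSize = 3)
  small <- which(tabulate(groupMembership(pg2)) == 2)
  expect_false(any(pg2@selectable[small]))
  sel <- selectAgeGroups(pg2)
  smallGenes <- names(groupMembership(pg2))[groupMembership(pg2) %in% small]
  expect_false(any(smallGenes %in% members(sel$agingDown)))
})

test_that("noisy archetype suites are recovered by clustering", {
  aris <- vapply(1:10, function(s) {
    sim <- simulateAgeSeries(nGenes = 120,
      archetypeGenes = c(monotone_up = 30, monotone_down = 30,
                         rise_fall = 30, late_spike = 30),
      nPerBin = 15, amplitude = 1.5, noiseSd = 0.3, seed = 400 + s)
    prof <- binProfiles(logNormalize(sim$se))
    pg <- clusterPatterns(prof, minCorr = 0.7)
    ari(groupMembership(pg)[sim$truth$gene],
        sim$truth$archetype)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
  # determinism given input order
  sim <- simulateAgeSeries(nGenes = 60,
    archetypeGenes = c(monotone_up = 20, rise_fall = 20),
    nPerBin = 10, seed = 5)
  prof <- binProfiles(logNormalize(sim$se))
  expect_identical(groupMembership(clusterPatterns(prof)),
                   groupMembership(clusterPatterns(prof)))
})

test_that("group selection follows the slope, flat and spike rules", {
  arch <- ageArchetypes(spikeDelta = 1)
  cent <- rbind(up = arch$monotone_up, down = arch$monotone_down,
                rf = arch$rise_fall, spike = arch$late_spike,
                flat32 = c(0, 0, 0, 0, -0.16494, -0.20438))
  prof <- cent[rep(1:5, each = 5), ]
  rownames(prof) <- sprintf("G%06d", 1:25)
  pg <- clusterPatterns(prof, minCorr = 0.9, minSize = 3)
  sel <- selectAgeGroups(pg, flatEpsilon = 0.05, spikeDelta = 0.5)
  g <- sel$groups
  byGene <- function(i) groupMembership(g)[[sprintf("G%06d", i)]]
  expect_true(g@selected[byGene(1)])                      # monotone up
  expect_identical(g@direction[byGene(1)], "up")
  expect_true(g@selected[byGene(6)])                      # monotone down
  expect_identical(g@direction[byGene(6)], "down")
  expect_false(g@selected[byGene(11)])                    # rise-then-fall
  expect_lt(slopeValues(g)[byGene(11)], 0)
  expect_true(g@selected[byGene(16)])                     # late spike
  expect_true(attr(g, "spike")[byGene(16)])
  expect_false(g@selected[byGene(21)])                    # flat example
  expect_gt(slopeValues(g)[byGene(21)], 0)
})

test_that("LHA derivation subtracts aging genes with provenance", {
  cUp <- geneSet(c("A", "B", "C"), "cDEG_up", "up")
  cDown <- geneSet(c("D", "E"), "cDEG_down", "down")
  lha0 <- deriveLHA(cUp, cDown)
  expect_setequal(members(lhaUp(lha0)), c("A", "B", "C"))
  expect_setequal(members(lhaDown(lha0)), c("D", "E"))

  aging <- geneSet(c("A", "B", "C", "D"), "aging", "none")
  lha1 <- deriveLHA(cUp, cDown, list(aging))
  expect_length(members(lhaUp(lha1)), 0)
  expect_setequal(members(lhaDown(lha1)), "E")
  expect_setequal(lha1@provenance$gene, c("A", "B", "C", "D"))
  expect_true(all(lha1@provenance$source == "aging"))
  ext <- geneSet("E", "external", "none")
  lha2 <- deriveLHA(cUp, cDown, list(aging), externalAging = ext)
  expect_length(members(lhaDown(lha2)), 0)
})
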