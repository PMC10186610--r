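#' End-to-end LHA recovery experiment on planted truth
#'
#' Runs the whole signature-derivation chain on synthetic data in which
#' both longevity genes (differentially expressed in every cohort, flat
#' with age) and common aging genes (differentially expressed in every
#' cohort *and* carrying a monotone age trajectory) are planted: simulate
#' cohorts, per-cohort differential expression, consensus intersection,
#' age-trajectory screening/clustering/slope selection, and LHA
#' derivation by subtraction. Returns how many planted longevity genes
#' survive into the LHA sets (sensitivity) and how many planted aging
#' genes leak through (contamination).
#'
#' @param nGenes gene universe size.
#' @param nPerGroup samples per group per cohort.
#' @param nCohorts number of cohorts.
#' @param nLongevity planted longevity genes (half up, half down).
#' @param nAging planted aging genes (half rising, half falling with age),
#'   also planted as shared DE so they would contaminate the consensus
#'   sets if not subtracted.
#' @param effect planted log2 fold change in the cohorts.
#' @param agePerBin age-series samples per decade bin.
#' @param ageAmplitude,ageNoiseSd age-series trajectory amplitude and
#'   noise (log2 scale).
#' @param pThreshold,fcThreshold DEG calling thresholds.
#' @param seed integer seed.
#' @return list with \code{sensitivity}, \code{contamination},
#'   \code{lha} (the \linkS4class{LHAResult}), and the intermediate set
#'   sizes.
#' @export
lhaRecoveryExperiment <- function(nGenes = 2000, nPerGroup = 30,
    nCohorts = 3, nLongevity = 100, nAging = 100, effect = 1.0,
    agePerBin = 20, ageAmplitude = 1.5, ageNoiseSd = 0.3,
    pThreshold = 0.05, fcThreshold = 1.2, seed = 1L) {
  seed <- as.integer(seed)
  half <- nLongevity %/% 2
  halfA <- nAging %/% 2
  longUp <- seq_len(half)
  longDown <- half + seq_len(nLongevity - half)
  agingUp <- nLongevity + seq_len(halfA)
  agingDown <- nLongevity + halfA + seq_len(nAging - halfA)
  ids <- geneIds(nGenes)

  sim <- simulateMulticohortCounts(
    nGenes = nGenes,
    cohorts = lapply(seq_len(nCohorts), function(i)
      cohortSpec(paste0("C", i), nPerGroup, nPerGroup)),
    sharedUp = c(longUp, agingUp), sharedDown = c(longDown, agingDown),
    effect = effect, seed = seed)
  degUp <- list(); degDown <- list()
  for (nm in names(sim$cohorts)) {
    expr <- removeCovariateEffects(logNormalize(sim$cohorts[[nm]]),
                                   c("sex", "batch"))
    sets <- callDegs(deTwoGroup(expr), pThreshold, fcThreshold, name = nm)
    degUp[[nm]] <- sets$up
    degDown[[nm]] <- sets$down
  }
  cdegUp <- intersectSets(degUp, "up", "cDEG_up")
  cdegDown <- intersectSets(degDown, "down", "cDEG_down")

  aging <- simulateAgeSeries(
    nGenes = nGenes,
    archetypeGenes = list(monotone_up = agingUp,
                          monotone_down = agingDown),
    nPerBin = agePerBin, amplitude = ageAmplitude, noiseSd = ageNoiseSd,
    seed = seed + 1L)
  ageExpr <- logNormalize(aging$se)
  aa <- ageAssociationTest(ageExpr, covariates = "sex")
  sigGenes <- aa$gene[aa$padj < 0.05]
  lha <- if (length(sigGenes) >= 2) {
    prof <- binProfiles(ageExpr)[sigGenes, , drop = FALSE]
    sel <- selectAgeGroups(clusterPatterns(prof))
    deriveLHA(cdegUp, cdegDown, list(sel$agingUp, sel$agingDown))
  } else deriveLHA(cdegUp, cdegDown)

  lhaAll <- union(lhaUp(lha)@members, lhaDown(lha)@members)
  longevityIds <- ids[c(longUp, longDown)]
  agingIds <- ids[c(agingUp, agingDown)]
  list(sensitivity = mean(longevityIds %in% lhaAll),
       contamination = mean(agingIds %in% lhaAll),
       lha = lha,
       nCdegUp = length(cdegUp@members),
       nCdegDown = length(cdegDown@members),
       nAgingDetected = sum(agingIds %in% lha@removedAging@members))
}
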