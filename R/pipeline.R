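#' Demo run configuration
#'
#' A small, fully synthetic configuration exercising every pipeline stage
#' in well under a minute. All sizes and planted effects are overridable;
#' defaults mirror the package's simulation defaults at reduced scale.
#'
#' @param nGenes gene universe for the cohort simulation.
#' @param nPerGroup samples per group per cohort.
#' @param nPlanted planted shared up (and down) genes.
#' @param effect planted log2 fold change.
#' @return list of class \code{RunConfig}.
#' @export
demoRunConfig <- function(nGenes = 500, nPerGroup = 10, nPlanted = 30,
                          effect = 1.5) {
  structure(list(
    nGenes = nGenes, nPerGroup = nPerGroup, nPlanted = nPlanted,
    effect = effect,
    cohortNames = c("ChM", "LG", "LS"),
    de = list(pThreshold = 0.05, fcThreshold = 1.2),
    perm = list(nPerm = 1000),
    age = list(nGenes = 400, nPerArchetype = 20, nPerBin = 4,
               amplitude = 1.5, noiseSd = 0.3,
               flatEpsilon = 0.05, spikeDelta = 0.5,
               minCorr = 0.7, minSize = 3),
    cells = list(nGenes = 300, markersPerType = 20, noiseSd = 0.5,
                 types = c(Monocyte = 20, DC = 15, NK = 20, CD8T = 20)),
    deconv = list(nSigGenes = 100, nSamples = 10, noiseSd = 0.1,
                  zeroFraction = 0.5),
    coexpr = list(nTop = 120, minSize = 10, mergeHeight = 0.1,
                  powers = 1:10),
    methylome = list(nProbes = 1500, nPerGroup = 10, nPlanted = 30,
                     deltaBeta = 0.2, globalShiftFrac = 0.1,
                     dCut = 0.1, pCut = 0.01)),
    class = "RunConfig")
}

writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

readExprTSV <- function(dir, name, mdName = "metadata.tsv") {
  m <- readMatrixTSV(file.path(dir, name))
  md <- readMetadataTSV(file.path(dir, mdName))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = m),
    colData = S4Vectors::DataFrame(md, row.names = colnames(m)))
}

#' Run the full LHA pipeline on synthetic data
#'
#' Executes simulate, preprocess, per-cohort differential expression,
#' consensus + permutation null, age-pattern selection, LHA derivation,
#' cell-type scoring/clustering/enrichment, deconvolution, co-expression
#' modules, methylome delta-beta analysis and regulatory overlap, each
#' stage reading its inputs from and writing its artifacts to
#' \code{outDir/<stage>/} as plain-text files, plus a JSON run manifest
#' with parameters, seeds and output checksums. Rerunning with the same
#' seed reproduces every output byte for byte.
#'
#' @param config a \code{\link{demoRunConfig}}-style list.
#' @param outDir output directory (created).
#' @param seed global integer seed; per-stage seeds derive from it.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = demoRunConfig(), outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  stages <- character()
  sdir <- function(s) {
    d <- file.path(outDir, s)
    dir.create(d, showWarnings = FALSE)
    stages <<- c(stages, s)
    d
  }

  ## -- simulate ----------------------------------------------------------
  d <- sdir("simulate")
  np <- config$nPlanted
  sim <- simulateMulticohortCounts(
    nGenes = config$nGenes,
    cohorts = lapply(config$cohortNames, function(nm)
      cohortSpec(nm, config$nPerGroup, config$nPerGroup)),
    sharedUp = seq_len(np), sharedDown = np + seq_len(np),
    effect = config$effect, seed = seed)
  for (nm in names(sim$cohorts)) {
    se <- sim$cohorts[[nm]]
    writeMatrixTSV(SummarizedExperiment::assay(se),
                   file.path(d, paste0("counts_", nm, ".tsv")))
    writeMetadataTSV(as.data.frame(SummarizedExperiment::colData(se)),
                     file.path(d, paste0("metadata_", nm, ".tsv")))
  }
  write.table(sim$truth, file.path(d, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  aging <- simulateAgeSeries(
    nGenes = config$age$nGenes,
    archetypeGenes = setNames(rep(config$age$nPerArchetype, 4),
                              c("monotone_up", "monotone_down",
                                "rise_fall", "late_spike")),
    nPerBin = config$age$nPerBin, amplitude = config$age$amplitude,
    noiseSd = config$age$noiseSd, seed = seed + 11L)
  writeMatrixTSV(SummarizedExperiment::assay(aging$se),
                 file.path(d, "counts_ages.tsv"))
  writeMetadataTSV(as.data.frame(SummarizedExperiment::colData(aging$se)),
                   file.path(d, "metadata_ages.tsv"))
  cells <- simulateCelltypeProfiles(
    nGenes = config$cells$nGenes, cellTypes = config$cells$types,
    markersPerType = config$cells$markersPerType,
    noiseSd = config$cells$noiseSd, seed = seed + 13L)
  writeMatrixTSV(SummarizedExperiment::assay(cells$se),
                 file.path(d, "cells_logexpr.tsv"))
  writeMetadataTSV(data.frame(
    sample = colnames(cells$se),
    cellType = SummarizedExperiment::colData(cells$se)$cellType),
    file.path(d, "cells_metadata.tsv"))
  mp <- config$methylome
  meth <- simulateMethylome(
    nProbes = mp$nProbes, nA = mp$nPerGroup, nB = mp$nPerGroup,
    hyperProbes = seq_len(mp$nPlanted),
    hypoProbes = mp$nPlanted + seq_len(mp$nPlanted),
    deltaBeta = mp$deltaBeta, globalShiftFrac = mp$globalShiftFrac,
    seed = seed + 17L)
  writeMatrixTSV(meth$betaA, file.path(d, "beta_A.tsv"))
  writeMatrixTSV(meth$betaB, file.path(d, "beta_B.tsv"))
  write.csv(meth$annotation, file.path(d, "probe_annotation.csv"),
            row.names = FALSE, quote = FALSE)
  sig <- simulateSignature(nGenes = config$deconv$nSigGenes,
                           seed = seed + 19L)
  writeMatrixTSV(sig, file.path(d, "signature.tsv"))
  mix <- simulateMixtures(
    sig, randomProportions(config$deconv$nSamples, ncol(sig),
                           seed = seed + 23L),
    noiseSd = config$deconv$noiseSd, seed = seed + 29L)
  writeMatrixTSV(mix$bulk, file.path(d, "bulk_mixtures.tsv"))
  writeMatrixTSV(mix$proportions, file.path(d, "true_proportions.tsv"))

  ## -- preprocess --------------------------------------------------------
  pdir <- sdir("preprocess")
  for (nm in config$cohortNames) {
    m <- readMatrixTSV(file.path(d, paste0("counts_", nm, ".tsv")))
    md <- readMetadataTSV(file.path(d, paste0("metadata_", nm, ".tsv")))
    expr <- logNormalize(makeCountsSE(m, md))
    expr <- removeCovariateEffects(expr, c("sex", "batch"))
    writeMatrixTSV(SummarizedExperiment::assay(expr, "logexpr"),
                   file.path(pdir, paste0("logexpr_", nm, ".tsv")))
    writeMetadataTSV(md, file.path(pdir, paste0("metadata_", nm, ".tsv")))
    writeJSON(S4Vectors::metadata(expr)$provenance,
              file.path(pdir, paste0("provenance_", nm, ".json")))
  }

  ## -- diffexpr ----------------------------------------------------------
  ddir <- sdir("diffexpr")
  degUp <- list(); degDown <- list()
  for (nm in config$cohortNames) {
    expr <- readExprTSV(pdir, paste0("logexpr_", nm, ".tsv"),
                        paste0("metadata_", nm, ".tsv"))
    de <- deTwoGroup(expr, covariates = character())
    writeDETable(de, file.path(ddir, paste0("de_", nm, ".tsv")))
    sets <- callDegs(de, config$de$pThreshold, config$de$fcThreshold,
                     name = nm)
    degUp[[nm]] <- sets$up
    degDown[[nm]] <- sets$down
    writeGMT(sets, file.path(ddir, paste0("degs_", nm, ".gmt")))
  }

  ## -- consensus ---------------------------------------------------------
  cdir <- sdir("consensus")
  degUp <- lapply(config$cohortNames, function(nm)
    readGMT(file.path(ddir, paste0("degs_", nm, ".gmt")))[[paste0(nm, "_up")]])
  degDown <- lapply(config$cohortNames, function(nm)
    readGMT(file.path(ddir, paste0("degs_", nm, ".gmt")))[[paste0(nm, "_down")]])
  cdegUp <- intersectSets(degUp, "up", "cDEG_up")
  cdegDown <- intersectSets(degDown, "down", "cDEG_down")
  writeGMT(list(cdegUp, cdegDown), file.path(cdir, "cdegs.gmt"))
  nullUp <- permutationOverlapNull(
    config$nGenes, vapply(degUp, length, integer(1)),
    observed = length(cdegUp), nPerm = config$perm$nPerm,
    seed = seed + 31L)
  nullDown <- permutationOverlapNull(
    config$nGenes, vapply(degDown, length, integer(1)),
    observed = length(cdegDown), nPerm = config$perm$nPerm,
    seed = seed + 37L)
  writeJSON(list(
    up = list(observed = nullUp@observed, null_mean = nullUp@nullMean,
              analytic = nullUp@analyticExpectation,
              p = nullUp@empiricalP),
    down = list(observed = nullDown@observed,
                null_mean = nullDown@nullMean,
                analytic = nullDown@analyticExpectation,
                p = nullDown@empiricalP)),
    file.path(cdir, "overlap_null.json"))

  ## -- age patterns ------------------------------------------------------
  adir <- sdir("age_patterns")
  ageCounts <- readMatrixTSV(file.path(d, "counts_ages.tsv"))
  ageMd <- readMetadataTSV(file.path(d, "metadata_ages.tsv"))
  ageExpr <- logNormalize(makeCountsSE(ageCounts, ageMd))
  aa <- ageAssociationTest(ageExpr, covariates = "sex")
  write.table(as.data.frame(aa), file.path(adir, "age_association.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sigGenes <- aa$gene[aa$padj < 0.05]
  prof <- binProfiles(ageExpr)[sigGenes, , drop = FALSE]
  writeMatrixTSV(prof, file.path(adir, "bin_profiles.tsv"))
  groups <- clusterPatterns(prof, minCorr = config$age$minCorr,
                            minSize = config$age$minSize)
  selection <- selectAgeGroups(groups, config$age$flatEpsilon,
                               config$age$spikeDelta)
  writeGMT(list(selection$agingUp, selection$agingDown),
           file.path(adir, "aging_sets.gmt"))
  g <- selection$groups
  writeJSON(lapply(seq_len(nrow(g@centroids)), function(i) list(
    group = i, size = sum(g@membership == i),
    slope = g@slopeValues[[i]], selected = g@selected[i],
    selectable = g@selectable[i], direction = g@direction[i],
    late_spike = attr(g, "spike")[i])),
    file.path(adir, "selection_report.json"))

  ## -- LHA ---------------------------------------------------------------
  ldir <- sdir("lha")
  agingSets <- unname(readGMT(file.path(adir, "aging_sets.gmt")))
  cdegs <- readGMT(file.path(cdir, "cdegs.gmt"))
  lha <- deriveLHA(cdegs$cDEG_up, cdegs$cDEG_down, agingSets)
  writeGMT(list(lhaUp(lha), lhaDown(lha)), file.path(ldir, "lha.gmt"))
  write.table(lha@provenance, file.path(ldir, "removals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- celltype ----------------------------------------------------------
  tdir <- sdir("celltype")
  cellExpr <- readExprTSV(d, "cells_logexpr.tsv", "cells_metadata.tsv")
  scores <- geneCellScores(cellExpr)
  writeMatrixTSV(scores, file.path(tdir, "gene_cell_scores.tsv"))
  lhaSets <- readGMT(file.path(ldir, "lha.gmt"))
  lhaAll <- union(lhaSets$LHA_up@members, lhaSets$LHA_down@members)
  lhaInCells <- intersect(lhaAll, rownames(scores))
  clusters <- list()
  if (length(lhaInCells) >= 8) {
    k <- min(4, length(lhaInCells) %/% 2)
    cl <- clusterGeneScores(scores[lhaInCells, , drop = FALSE], k = k,
                            seed = seed + 41L)
    write.table(data.frame(gene = names(cl), cluster = cl),
                file.path(tdir, "lha_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    clusters <- lapply(sort(unique(cl)), function(i)
      geneSet(names(cl)[cl == i], paste0("C", i)))
    names(clusters) <- vapply(clusters, setName, character(1))
    writeGMT(clusters, file.path(tdir, "lha_clusters.gmt"))
  }
  firstType <- names(config$cells$types)[1]
  ranked <- rankGenesForCelltype(cellExpr, firstType)
  enr <- tryCatch(
    gsea(ranked, geneSet(lhaInCells, "LHA_in_cells"), nPerm = 500,
         seed = seed + 43L),
    error = function(e) NULL)
  if (!is.null(enr))
    writeJSON(list(set = enr@setName, cellType = firstType,
                   ES = enr@ES, NES = enr@NES, p = enr@p),
              file.path(tdir, "gsea_lha.json"))

  ## -- deconvolution -----------------------------------------------------
  vdir <- sdir("deconvolution")
  sig <- readMatrixTSV(file.path(d, "signature.tsv"))
  bulk <- readMatrixTSV(file.path(d, "bulk_mixtures.tsv"))
  est <- nnlsProportions(bulk, sig)
  est <- filterCelltypes(est, config$deconv$zeroFraction)
  writeMatrixTSV(proportions(est), file.path(vdir, "proportions.tsv"))

  ## -- coexpr ------------------------------------------------------------
  xdir <- sdir("coexpr")
  expr1 <- readExprTSV(pdir, paste0("logexpr_", config$cohortNames[1],
                                    ".tsv"),
                       paste0("metadata_", config$cohortNames[1], ".tsv"))
  m1 <- SummarizedExperiment::assay(expr1, "logexpr")
  vars <- apply(m1, 1, var)
  top <- m1[order(-vars)[seq_len(min(config$coexpr$nTop, nrow(m1)))], ]
  keepS <- setdiff(colnames(top), flagSampleOutliers(top))
  top <- top[, keepS, drop = FALSE]
  st <- pickSoftThreshold(top, powers = config$coexpr$powers)
  adj <- adjacencyMatrix(top, power = st$power)
  tom <- tomSimilarity(adj)
  mods <- detectModules(1 - tom, top, minSize = config$coexpr$minSize,
                        mergeHeight = config$coexpr$mergeHeight)
  mm <- moduleMembership(mods)
  write.table(data.frame(gene = names(mm), module = mm),
              file.path(xdir, "modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ids <- setdiff(sort(unique(mm)), 0L)
  if (length(ids)) {
    eg <- vapply(ids, function(i)
      moduleEigengene(top[names(mm)[mm == i], , drop = FALSE])$scores,
      numeric(ncol(top)))
    colnames(eg) <- paste0("M", ids)
    ages1 <- SummarizedExperiment::colData(expr1)$age[
      match(keepS, colnames(m1))]
    tr <- correlateWithTrait(eg, ages1)
    write.table(tr, file.path(xdir, "module_age_correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- methylome ---------------------------------------------------------
  mdir <- sdir("methylome")
  betaA <- readMatrixTSV(file.path(d, "beta_A.tsv"))
  betaB <- readMatrixTSV(file.path(d, "beta_B.tsv"))
  annot <- read.csv(file.path(d, "probe_annotation.csv"))
  db <- deltaBeta(betaA, betaB)
  dmps <- callDMPs(betaA, betaB, dCut = mp$dCut, pCut = mp$pCut)
  write.table(dmps, file.path(mdir, "dmps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mapped <- mapProbesToGenes(dmps, annot)
  writeGMT(list(mapped$hyper, mapped$hypo),
           file.path(mdir, "methylated_genes.gmt"))
  methSummary <- list(skewness = skewnessG1(db),
                      mean_delta_beta = mean(db),
                      n_hyper = sum(dmps$call == "hyper"),
                      n_hypo = sum(dmps$call == "hypo"))
  if (length(clusters)) {
    cls <- classifyLhaMethylation(mapped$hyper, mapped$hypo, clusters,
                                  universe = unique(annot$gene))
    write.table(cls, file.path(mdir, "lha_cluster_methylation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeJSON(methSummary, file.path(mdir, "summary.json"))

  ## -- regulatory --------------------------------------------------------
  rdir <- sdir("regulatory")
  set.seed(seed + 47L)
  universe <- rownames(readMatrixTSV(
    file.path(pdir, paste0("logexpr_", config$cohortNames[1], ".tsv"))))
  coords <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = seq(10000, by = 20000,
                                 length.out = length(universe)),
                     width = 5000),
    strand = rep(c("+", "-"), length.out = length(universe)))
  names(coords) <- universe
  proms <- promotersFromGenes(coords)
  boundIdx <- sort(sample(length(universe), round(0.3 * length(universe))))
  peaks <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = BiocGenerics::start(proms)[boundIdx] +
                       sample(0:400, length(boundIdx), replace = TRUE),
                     width = 200))
  ov <- intervalOverlap(proms, peaks)
  boundGenes <- geneSet(unique(ov$queryName), "promoter_bound")
  write.table(ov, file.path(rdir, "promoter_peak_overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(clusters)) {
    br <- bindingRatioPerCluster(clusters, boundGenes, universe)
    write.table(br, file.path(rdir, "binding_ratio.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  # small insulin-stimulus series around a reference profile
  nq <- 20
  refProfile <- c(0, 1, 2, 3, 2.5)
  series <- rbind(INSR = refProfile,
                  matrix(rep(refProfile, nq), nq, byrow = TRUE) *
                    rep(c(1, -1), length.out = nq) +
                    matrix(rnorm(nq * 5, 0, 0.2), nq))
  rownames(series) <- c("INSR", head(universe, nq))
  sc <- stimulusCorrelation(series, "INSR")
  write.table(sc, file.path(rdir, "stimulus_correlation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tfTable <- split(sample(universe, 200, replace = TRUE),
                   rep(paste0("TF", 1:10), each = 20))
  tfe <- tfTargetEnrichment(tfTable,
                            geneSet(head(universe, 50), "query"),
                            universe)
  write.table(tfe, file.path(rdir, "tf_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## -- manifest ----------------------------------------------------------
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "lhasig",
    version = as.character(utils::packageVersion("lhasig")),
    seed = seed, stages = stages,
    parameters = unclass(config),
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 sub(paste0(outDir, "/"), "", files,
                                     fixed = TRUE))))
  writeJSON(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}
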