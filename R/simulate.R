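#' Cohort specification for the multi-cohort count simulator
#'
#' @param name cohort label.
#' @param nCase,nControl sample counts (each >= 2). Cases play the role of
#'   the long-lived individuals (LLI), controls the younger F1SP group.
#' @param sexRatio fraction of male samples.
#' @param batches character vector of batch labels cycled over samples.
#' @param libraryType library-type label recorded in the metadata.
#' @return A validated list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(name, nCase, nControl, sexRatio = 0.5,
                       batches = c("b1", "b2"), libraryType = "polyA") {
  stopifnot(nCase >= 2, nControl >= 2, sexRatio >= 0, sexRatio <= 1,
            length(batches) >= 1)
  structure(list(name = name, nCase = as.integer(nCase),
                 nControl = as.integer(nControl), sexRatio = sexRatio,
                 batches = batches, libraryType = libraryType),
            class = "CohortSpec")
}

geneIds <- function(n) sprintf("G%06d", seq_len(n))
probeIds <- function(n) sprintf("cg%06d", seq_len(n))

# Internal: validate planted index sets against the gene universe.
checkPlanted <- function(nGenes, ...) {
  sets <- list(...)
  idx <- unlist(sets, use.names = FALSE)
  if (length(idx) && (any(idx < 1) || any(idx > nGenes)))
    stop("planted gene indices must lie in 1..n_genes")
  if (anyDuplicated(idx))
    stop("planted gene sets must be mutually disjoint")
  invisible(TRUE)
}

#' Simulate multi-cohort negative binomial count matrices
#'
#' Emulates several case/control blood RNA-seq cohorts sharing one gene
#' universe. Counts are negative binomial with log-normal gene base means,
#' per-sample library-size factors, multiplicative case effects of
#' \code{2^effect} on planted genes shared across all cohorts (the planted
#' "longevity" signal) or private to one cohort, and multiplicative
#' log-normal sex and batch effects.
#'
#' @param nGenes size of the gene universe.
#' @param cohorts list of \code{\link{cohortSpec}} objects.
#' @param sharedUp,sharedDown integer indices of genes up/down-regulated in
#'   cases of every cohort.
#' @param cohortSpecific named list (by cohort name) of integer index
#'   vectors, up-regulated only in that cohort.
#' @param effect absolute log2 fold change planted on affected genes.
#' @param dispersion shared NB dispersion (1/size); must be > 0.
#' @param baseMeanLog mean and sd of the natural-log gene base means.
#' @param sexEffectSd,batchEffectSd sd of per-gene log2 sex/batch effects.
#' @param libSizeRange range of the uniform per-sample library size factor.
#' @param seed integer seed; the full output is reproducible from it.
#' @return list with \code{cohorts} (named list of counts
#'   \code{SummarizedExperiment}s, colData columns sample, group, age, sex,
#'   batch, library) and \code{truth} (data.frame gene, role, effect).
#' @examples
#' sim <- simulateMulticohortCounts(nGenes = 200,
#'   cohorts = list(cohortSpec("A", 5, 5), cohortSpec("B", 5, 5)),
#'   sharedUp = 1:10, sharedDown = 11:20, seed = 1)
#' sim$cohorts$A
#' @export
simulateMulticohortCounts <- function(nGenes = 2000, cohorts,
    sharedUp = integer(), sharedDown = integer(),
    cohortSpecific = list(), effect = 1.0, dispersion = 0.1,
    baseMeanLog = c(4, 1.2), sexEffectSd = 0.3, batchEffectSd = 0.3,
    libSizeRange = c(0.7, 1.4), seed = 1L) {
  stopifnot(length(cohorts) >= 1, dispersion > 0)
  do.call(checkPlanted,
          c(list(nGenes, sharedUp, sharedDown), unname(cohortSpecific)))
  set.seed(seed)
  ids <- geneIds(nGenes)
  baseMean <- exp(rnorm(nGenes, baseMeanLog[1], baseMeanLog[2]))
  sexCoef <- rnorm(nGenes, 0, sexEffectSd)            # log2, applied to males
  lfc <- numeric(nGenes)
  lfc[sharedUp] <- effect
  lfc[sharedDown] <- -effect
  role <- rep("null", nGenes)
  role[sharedUp] <- "shared_up"
  role[sharedDown] <- "shared_down"

  out <- list()
  for (cs in cohorts) {
    n <- cs$nCase + cs$nControl
    group <- rep(c("case", "control"), c(cs$nCase, cs$nControl))
    sex <- ifelse(runif(n) < cs$sexRatio, "M", "F")
    batch <- rep_len(cs$batches, n)
    lib <- runif(n, libSizeRange[1], libSizeRange[2])
    batchCoef <- matrix(rnorm(nGenes * length(cs$batches), 0, batchEffectSd),
                        nGenes, length(cs$batches),
                        dimnames = list(NULL, cs$batches))
    lfcCohort <- lfc
    spec <- cohortSpecific[[cs$name]]
    if (!is.null(spec)) {
      lfcCohort[spec] <- effect
      role[spec] <- "cohort_specific"
    }
    logmu <- log2(baseMean) +
      outer(lfcCohort, as.numeric(group == "case")) +
      outer(sexCoef, as.numeric(sex == "M")) +
      batchCoef[, batch, drop = FALSE]
    mu <- 2^logmu * rep(lib, each = nGenes)
    counts <- matrix(rnbinom(nGenes * n, mu = mu, size = 1 / dispersion),
                     nGenes, n)
    dimnames(counts) <- list(ids, paste0(cs$name, "_s", seq_len(n)))
    md <- data.frame(sample = colnames(counts), group = group,
                     age = ifelse(group == "case",
                                  round(runif(n, 95, 105)),
                                  round(runif(n, 55, 70))),
                     sex = sex, batch = batch, library = cs$libraryType)
    out[[cs$name]] <- makeCountsSE(counts, md)
  }
  truth <- data.frame(gene = ids, role = role,
                      effect = abs(lfc) + (role == "cohort_specific") * effect)
  truth$effect[truth$role == "null"] <- 0
  list(cohorts = out, truth = truth)
}

#' Built-in age-trajectory archetypes
#'
#' Decade-bin z-profiles (20-29 ... 70-79) used by
#' \code{\link{simulateAgeSeries}}: strictly monotone up/down, a
#' rise-then-fall non-monotone shape, a flat profile with a late spike only
#' at 70-79, and flat.
#'
#' @param spikeDelta height of the late-spike archetype's last bin.
#' @return named list of 6-vectors.
#' @export
ageArchetypes <- function(spikeDelta = 1.0) {
  list(monotone_up   = c(-1.0, -0.6, -0.2, 0.2, 0.6, 1.0),
       monotone_down = c(1.0, 0.6, 0.2, -0.2, -0.6, -1.0),
       rise_fall     = c(-1.2, -0.4, 0.4, 0.8, 1.2, -1.2),
       late_spike    = c(0, 0, 0, 0, 0, spikeDelta),
       flat          = c(0, 0, 0, 0, 0, 0))
}

ageBinBreaks <- c(20, 30, 40, 50, 60, 70, 80)
ageBinLabels <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")

#' Assign ages to decade bins
#' @param ages numeric ages in years (20-79).
#' @return factor with the six decade-bin levels.
#' @export
ageBins <- function(ages) {
  cut(ages, breaks = ageBinBreaks, right = FALSE, labels = ageBinLabels)
}

#' Simulate an age-binned expression series
#'
#' Emulates a whole-blood cross-sectional cohort spanning ages 20-79 with
#' genes planted on trajectory archetypes (see \code{\link{ageArchetypes}}).
#' The noise-free decade-bin mean of a planted gene's log2 expression follows
#' \code{amplitude * archetype}; samples are allocated uniformly over the six
#' decade bins.
#'
#' @param nGenes gene universe size.
#' @param archetypeGenes either a named integer vector (genes per
#'   archetype, planted on consecutive leading indices) or a named list of
#'   integer gene-index vectors for explicit placement; names must exist
#'   in \code{archetypes}. The rest of the universe is flat/null.
#' @param archetypes archetype catalogue, default \code{ageArchetypes()}.
#' @param nPerBin samples per decade bin (>= 2).
#' @param amplitude log2-scale amplitude applied to the z-profiles.
#' @param noiseSd per-observation log2 Gaussian noise sd.
#' @param dispersion NB dispersion; \code{0} returns the expected
#'   (continuous) counts so zero-noise contracts hold exactly.
#' @param baseMeanLog mean/sd of natural-log base means.
#' @param seed integer seed.
#' @return list with \code{se} (counts \code{SummarizedExperiment}, colData
#'   sample, age, sex, group="all") and \code{truth} (gene, role, archetype).
#' @export
simulateAgeSeries <- function(nGenes = 1000,
    archetypeGenes = c(monotone_up = 50, monotone_down = 50,
                       rise_fall = 50, late_spike = 50),
    archetypes = ageArchetypes(), nPerBin = 20, amplitude = 1.5,
    noiseSd = 0.3, dispersion = 0.1, baseMeanLog = c(4, 1), seed = 1L) {
  if (nPerBin < 2) stop("need at least 2 samples per decade bin")
  if (!all(names(archetypeGenes) %in% names(archetypes)))
    stop("unknown archetype name")
  if (!is.list(archetypeGenes)) {
    if (sum(archetypeGenes) > nGenes)
      stop("planted gene counts exceed the gene universe")
    i <- 0
    archetypeGenes <- lapply(archetypeGenes, function(k) {
      idx <- i + seq_len(k)
      i <<- i + k
      idx
    })
  }
  do.call(checkPlanted, c(list(nGenes), unname(archetypeGenes)))
  set.seed(seed)
  ids <- geneIds(nGenes)
  role <- rep("null", nGenes)
  profile <- matrix(0, nGenes, 6)
  for (a in names(archetypeGenes)) {
    idx <- archetypeGenes[[a]]
    profile[idx, ] <- matrix(archetypes[[a]], length(idx), 6, byrow = TRUE)
    role[idx] <- a
  }
  ages <- rep(ageBinBreaks[1:6], each = nPerBin) +
    sample(0:9, 6 * nPerBin, replace = TRUE)
  bins <- as.integer(ageBins(ages))
  n <- length(ages)
  baseMean <- exp(rnorm(nGenes, baseMeanLog[1], baseMeanLog[2]))
  logmu <- log2(baseMean) + amplitude * profile[, bins, drop = FALSE] +
    matrix(rnorm(nGenes * n, 0, noiseSd), nGenes, n)
  mu <- 2^logmu
  counts <- if (dispersion > 0)
    matrix(rnbinom(nGenes * n, mu = mu, size = 1 / dispersion), nGenes, n)
  else mu
  dimnames(counts) <- list(ids, sprintf("age_s%03d", seq_len(n)))
  md <- data.frame(sample = colnames(counts), group = "all", age = ages,
                   sex = sample(c("M", "F"), n, replace = TRUE),
                   batch = "b1", library = "polyA")
  truth <- data.frame(gene = ids, role = role)
  truth$role[truth$role == "monotone_up"] <- "aging_up"
  truth$role[truth$role == "monotone_down"] <- "aging_down"
  truth$archetype <- role
  list(se = makeCountsSE(counts, md), truth = truth)
}

#' Simulate cell-labelled expression profiles
#'
#' Each cell type carries a disjoint marker program with elevated mean
#' expression; additional planted gene programs are elevated in designated
#' groups of cell types (e.g. a phagocyte program shared by monocytes and
#' dendritic cells). Values are log2-scale Gaussian around the programmed
#' means.
#'
#' @param nGenes gene universe size.
#' @param cellTypes named integer vector: cells per type.
#' @param markersPerType marker genes per cell type.
#' @param markerEffect log2 elevation of a marker in its own type.
#' @param programs named list; each element is
#'   \code{list(genes = indices, types = type names, effect = log2 shift)}.
#' @param noiseSd per-observation Gaussian sd (log2 scale).
#' @param baseMeanLog mean/sd of log2 base expression.
#' @param seed integer seed.
#' @return list with \code{se} (genes x cells \code{SummarizedExperiment},
#'   assay "logexpr", colData cellType) and \code{truth}
#'   (gene, role: marker:<type> / program:<name> / null).
#' @export
simulateCelltypeProfiles <- function(nGenes = 1000,
    cellTypes = c(Monocyte = 60, DC = 30, NK = 40, CD8T = 60, CD4T = 60,
                  B = 40),
    markersPerType = 30, markerEffect = 2, programs = list(),
    noiseSd = 0.5, baseMeanLog = c(3, 1), seed = 1L) {
  set.seed(seed)
  nTypes <- length(cellTypes)
  if (markersPerType * nTypes > nGenes)
    stop("marker programs exceed the gene universe")
  ids <- geneIds(nGenes)
  labels <- rep(names(cellTypes), cellTypes)
  n <- length(labels)
  base <- rnorm(nGenes, baseMeanLog[1], baseMeanLog[2])
  shift <- matrix(0, nGenes, nTypes, dimnames = list(NULL, names(cellTypes)))
  role <- rep("null", nGenes)
  for (k in seq_len(nTypes)) {
    idx <- (k - 1) * markersPerType + seq_len(markersPerType)
    shift[idx, k] <- markerEffect
    role[idx] <- paste0("marker:", names(cellTypes)[k])
  }
  for (p in names(programs)) {
    pr <- programs[[p]]
    checkPlanted(nGenes, pr$genes)
    eff <- if (is.null(pr$effect)) 1.5 else pr$effect
    shift[pr$genes, pr$types] <- shift[pr$genes, pr$types] + eff
    role[pr$genes] <- paste0("program:", p)
  }
  expr <- base + shift[, match(labels, colnames(shift)), drop = FALSE] +
    matrix(rnorm(nGenes * n, 0, noiseSd), nGenes, n)
  dimnames(expr) <- list(ids, sprintf("cell%04d", seq_len(n)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = expr),
    colData = S4Vectors::DataFrame(cellType = labels,
                                   row.names = colnames(expr)))
  list(se = se, truth = data.frame(gene = ids, role = role))
}

invLogit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Simulate a two-group methylome
#'
#' Beta values arise as the inverse logit of Gaussian M-values around a
#' per-probe baseline. Planted hyper/hypo probes shift group B's baseline
#' beta by +/- \code{deltaBeta}; an optional global hypomethylation component
#' gives a random fraction of probes a negative M-shift of exponentially
#' distributed magnitude, producing the net negative delta-beta skew seen in
#' long-lived methylomes.
#'
#' @param nProbes probe universe size.
#' @param nA,nB samples per group (A plays the middle-aged controls, B the
#'   long-lived group).
#' @param hyperProbes,hypoProbes integer probe indices planted hyper/hypo
#'   methylated in group B.
#' @param deltaBeta planted absolute beta shift.
#' @param mNoiseSd Gaussian sd of M-values (logit scale).
#' @param globalShiftFrac fraction of unplanted probes receiving the global
#'   hypomethylation shift in group B.
#' @param globalShiftRate rate of the exponential M-shift magnitude.
#' @param probesPerGene probes annotated per gene (round robin).
#' @param seed integer seed.
#' @return list with \code{betaA}, \code{betaB} (probes x samples matrices),
#'   \code{annotation} (data.frame probe, gene, chrom, pos) and \code{truth}
#'   (probe, role, delta).
#' @export
simulateMethylome <- function(nProbes = 10000, nA = 20, nB = 20,
    hyperProbes = integer(), hypoProbes = integer(), deltaBeta = 0.2,
    mNoiseSd = 0.25, globalShiftFrac = 0, globalShiftRate = 2,
    probesPerGene = 2, seed = 1L) {
  stopifnot(nA >= 2, nB >= 2)
  checkPlanted(nProbes, hyperProbes, hypoProbes)
  set.seed(seed)
  probes <- probeIds(nProbes)
  beta0 <- runif(nProbes, 0.1, 0.9)
  planted <- c(hyperProbes, hypoProbes)
  beta0[planted] <- runif(length(planted), 0.35, 0.65)
  delta <- numeric(nProbes)
  delta[hyperProbes] <- deltaBeta
  delta[hypoProbes] <- -deltaBeta
  role <- rep("null", nProbes)
  role[hyperProbes] <- "hyper"
  role[hypoProbes] <- "hypo"

  m0A <- logit(beta0)
  m0B <- logit(pmin(pmax(beta0 + delta, 0.02), 0.98))
  if (globalShiftFrac > 0) {
    free <- setdiff(seq_len(nProbes), planted)
    hit <- sample(free, round(globalShiftFrac * length(free)))
    m0B[hit] <- m0B[hit] - rexp(length(hit), rate = globalShiftRate)
    role[hit] <- "global_shift"
  }
  betaA <- invLogit(m0A + matrix(rnorm(nProbes * nA, 0, mNoiseSd),
                                 nProbes, nA))
  betaB <- invLogit(m0B + matrix(rnorm(nProbes * nB, 0, mNoiseSd),
                                 nProbes, nB))
  dimnames(betaA) <- list(probes, sprintf("A%02d", seq_len(nA)))
  dimnames(betaB) <- list(probes, sprintf("B%02d", seq_len(nB)))
  genes <- geneIds(ceiling(nProbes / probesPerGene))
  annotation <- data.frame(probe = probes,
                           gene = rep(genes, each = probesPerGene,
                                      length.out = nProbes),
                           chrom = "chr1",
                           pos = seq(1000, by = 500, length.out = nProbes))
  list(betaA = betaA, betaB = betaB, annotation = annotation,
       truth = data.frame(probe = probes, role = role, delta = delta))
}

#' Simulate a cell-type signature matrix
#'
#' LM22-style non-negative signature: each cell type has a block of marker
#' genes with strongly elevated expression over a shared log-normal
#' background, giving a full-column-rank matrix.
#'
#' @param nGenes signature genes.
#' @param cellTypes character vector of type names.
#' @param markerFold linear fold elevation of a marker in its type.
#' @param seed integer seed.
#' @return genes x cell types numeric matrix.
#' @export
simulateSignature <- function(nGenes = 200,
    cellTypes = c("Monocyte", "DC", "NK", "CD8T", "B"),
    markerFold = 8, seed = 1L) {
  set.seed(seed)
  k <- length(cellTypes)
  base <- exp(rnorm(nGenes, 2, 0.5))
  sig <- matrix(rep(base, k), nGenes, k,
                dimnames = list(geneIds(nGenes), cellTypes))
  per <- nGenes %/% k
  for (j in seq_len(k)) {
    idx <- (j - 1) * per + seq_len(per)
    sig[idx, j] <- sig[idx, j] * markerFold
  }
  sig
}

#' Simulate signature-weighted bulk mixtures
#'
#' Bulk profile per sample = signature matrix times the sample's cell-type
#' proportion vector, under multiplicative log-normal noise. Proportions are
#' normalised to sum to 1 and stored as the planted truth.
#'
#' @param signature genes x cell types matrix
#'   (\code{\link{simulateSignature}}).
#' @param proportions samples x cell types non-negative matrix; rows are
#'   renormalised to 1.
#' @param noiseSd sd of the log-normal multiplicative noise (natural log);
#'   0 gives exact mixtures.
#' @param seed integer seed.
#' @return list with \code{bulk} (genes x samples matrix) and
#'   \code{proportions} (the normalised truth).
#' @export
simulateMixtures <- function(signature, proportions, noiseSd = 0.1,
                             seed = 1L) {
  proportions <- as.matrix(proportions)
  stopifnot(ncol(proportions) == ncol(signature), all(proportions >= 0))
  proportions <- proportions / rowSums(proportions)
  set.seed(seed)
  bulk <- signature %*% t(proportions)
  if (noiseSd > 0)
    bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noiseSd), nrow(bulk)))
  colnames(bulk) <- sprintf("mix%03d", seq_len(nrow(proportions)))
  rownames(proportions) <- colnames(bulk)
  list(bulk = bulk, proportions = proportions)
}

#' Random cell-type proportion vectors
#'
#' Symmetric Dirichlet draws (unit-rate exponentials, row-normalised).
#'
#' @param n samples, @param k cell types, @param seed integer seed.
#' @param k number of cell types.
#' @param seed integer seed.
#' @return n x k matrix with rows summing to 1.
#' @export
randomProportions <- function(n, k, seed = 1L) {
  set.seed(seed)
  p <- matrix(rexp(n * k), n, k)
  p / rowSums(p)
}
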