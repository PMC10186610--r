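---
title: "Deriving a longevity-and-healthy-aging immune gene signature: models and methods"
author: "lhasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a longevity-and-healthy-aging immune gene signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhasig)
```

## The problem

Blood transcriptomes of exceptionally long-lived individuals (LLIs) differ
from those of younger controls for two entangled reasons: changes that track
ordinary aging, and changes specific to extreme longevity and the healthy
immune aging that accompanies it. `lhasig` implements a multi-stage
derivation that separates the two:

1. **Consensus differential expression.** Each cohort is tested separately
   (different sites, batches and library types would otherwise confound a
   pooled analysis) and the per-direction DEG sets are intersected across
   cohorts. The resulting consensus DEGs (cDEGs) are compared against a
   permutation null that redraws sets of the observed sizes uniformly from
   the gene universe.
2. **Common-aging gene identification.** An age-binned reference cohort
   (decades 20--29 through 70--79) is screened with a nested-model F-test,
   significant genes are z-scaled, averaged per decade bin, clustered on the
   Pearson similarity of their six-bin profiles, and each cluster is scored
   with a *slope value* over the post-50 bins.
3. **LHA derivation.** The longevity-and-healthy-aging (LHA) sets are the
   cDEGs minus every common-aging gene (trajectory-derived plus any external
   aging list supplied as GMT).
4. **Characterisation.** Cell-type enrichment (weighted KS GSEA and
   hypergeometric ORA), gene-by-cell-type score clustering, NNLS
   deconvolution of immune composition, weighted co-expression modules
   correlated with age, two-group methylome delta-beta analysis, and
   promoter-binding / TF-target overlap.

Every stage consumes plain-text formats (TSV, GMT, CSV, BED, JSON) and is
exercised end-to-end by a synthetic-data module with planted ground truth.

## The slope metric

For a cluster centroid of six decade-bin means $m_1,\dots,m_6$ the slope
value is

$$ s = (m_5 - m_4)\,(m_6 - m_5), $$

the product of the two consecutive bin-mean differences beyond age 50. $s >
0$ means the trajectory keeps moving in the same direction through the last
three decades — a *consistent* aging trend — while a reversal
(rise-then-fall) makes the factors differ in sign and $s < 0$. The metric is
translation-invariant and scales by $c^2$ under multiplication by $c > 0$,
so it can be applied to z-scaled profiles without further normalisation.

Two guard rules accompany the sign test, both motivated by trajectories
that a bare $s > 0$ mishandles:

* **Flat guard.** A trajectory can have $s > 0$ while barely moving: with
  bin means $-0.16494$ at 60--69 and $-0.20438$ at 70--79 after a flat
  start, $s \approx 0.0065 > 0$ yet the last step is only $0.039$ z-units.
  Groups with $|m_6 - m_5| < 0.05$ (the `flatEpsilon` default, in z-units)
  are rejected as flat. The default is calibrated so that this borderline
  trajectory is rejected while the built-in monotone archetypes (last step
  $\ge 0.4$ z-units) pass with a wide margin.
* **Late-spike rule.** Genes induced only in the 70--79 decade have $s
  \approx 0$ but are genuinely aging-associated. A group whose last bin
  exceeds the maximum of all earlier bins by at least `spikeDelta = 0.5`
  z-units is selected regardless of its slope. The threshold is half the
  total dynamic range of a unit-amplitude archetype; it is exposed in the
  API and in the pipeline configuration because no external reference pins
  it.

Groups smaller than `minSize = 3` are never selected: a trend supported by
two genes is not evidence of a shared aging program. Selection direction is
the sign of $m_6 - m_4$.

## Statistical choices, and where they deviate from common practice

**OLS on log-normalised counts instead of a negative binomial Wald test.**
Per-cohort differential expression fits, per gene, ordinary least squares of
`log2(count/sizefactor + 1)` on a case/control indicator plus additive
covariates, with a t-test on the group coefficient and Benjamini–Hochberg
adjustment. This is a deliberate methodological substitution for NB-based
testing: the statistic is fully specified, dependency-free, and its type-I
calibration is directly testable — on a 2,000-gene null simulation at $n =
30+30$ the fraction of nominal $p < 0.05$ lands in $[0.04, 0.06]$ (see the
test suite). The cost is some power at very low counts, where the Gaussian
approximation is weakest. Constant genes are reported with $p = 1$ and
log2FC 0 rather than dropped, keeping the gene universe aligned across
cohorts for the consensus intersection.

**Size factors.** Median-of-ratios over genes positive in every sample;
when no such gene exists, genes positive in at least 90% of samples are
used with per-sample available ratios. Factors are rescaled to geometric
mean 1. The pseudocount of 1 is added after size-factor scaling so zero
counts stay at exactly zero.

**Covariate removal.** Sex, batch and library type are removed per gene by
OLS residualisation with the gene grand mean restored, so downstream fold
changes remain interpretable on the log2 scale; `group` and `age` are
refused in the removal design. Main effects are additive — the data sources
this emulates do not specify interactions, and a balanced-confound
simulation shows planted group differences preserved within 5%.

**DEG thresholds.** Strict inequalities: nominal $p < 0.05$ *and* linear
fold change $> 1.2$ for the discovery cohorts; a p-only mode ($p < 0.01$,
no FC filter) mirrors the rule used for microarray validation cohorts. Both
nominal-p and adjusted-p calling are exposed because published analyses mix
the two conventions.

**Permutation overlap null.** Sets are redrawn uniformly without
replacement — detectability-matched sampling would need per-gene expression
strata that the method's inputs do not carry. The universe defaults to the
genes tested in all cohorts. The empirical p uses the add-one convention,
and up- and down-regulated sets are permuted separately. The analytic
independence expectation $N\prod_i (n_i/N)$ is reported alongside and the
permutation mean is tested against it (within four standard errors at
10,000 permutations).

**GSEA.** The weighted Kolmogorov–Smirnov running sum with weight $p = 1$;
$p = 0$ (classic KS) is retained and verified against an exhaustive
brute-force oracle over *all* set placements on short lists. The null
permutes gene labels — with a pre-ranked list, sample permutation is not
available. NES divides ES by the mean |null ES| of the same sign; with
fewer than 3 same-sign null scores NES and p are NA with a warning. Ties
between equal-magnitude positive and negative running-sum extrema resolve
to the positive one; the rule is arbitrary but deterministic and shared
with the test oracle.

**Deconvolution.** Non-negative least squares (active-set, exact zeros at
the constraints) with sum-to-one renormalisation replaces the ν-SVR of the
web tool commonly used for this step: it is deterministic, dependency-light
and recovers noise-free mixtures to machine precision when the signature
has full column rank. The zero-proportion filter then drops cell types
estimated at exactly zero in more than 50% of samples and renormalises.
The substitution is recorded in the estimate's `method` metadata.

**Co-expression modules.** Unsigned adjacency $|r|^\beta$, topological
overlap, average-linkage clustering with a *static* tree cut at height
0.99 (the dynamic variant is unspecified in the sources this emulates and a
static cut is deterministic), minimum module size 30, and iterative merging
of modules whose eigengenes correlate above $1 - 0.1$ — the quoted
"dissimilarity threshold 0.1" is read as the merge height, the more common
convention. Eigengenes are unit-norm first right singular vectors of the
gene-standardised module matrix, sign-fixed to correlate non-negatively
with the module mean profile so results are reproducible across
linear-algebra backends. Sample outliers are flagged by standardized
correlation connectivity below $-3$; the criterion stands in for an
unspecified "unsupervised clustering" rule.

**Methylome.** Delta beta is long-lived minus control (so negative skew
means net demethylation in the long-lived; the orientation is
configurable). Probe-level Welch t-tests on beta values are the default —
an M-value mode is provided since beta variance is heteroscedastic near the
bounds — with calls at $|\Delta\beta| > 0.1$ and adjusted $p < 0.01$,
strict. Calling is probe-level with gene mapping; no spatial merging of
adjacent probes is attempted because no region definition is specified.
Skewness is the Fisher–Pearson $g_1 = m_3/m_2^{3/2}$.

**Regulatory overlap.** Promoters default to $[\mathrm{TSS}-2000,
\mathrm{TSS}+500)$ — a conventional core-promoter window, configurable
since no coordinates are pinned externally. Intervals are BED-convention
0-based half-open on disk and `GRanges` in memory; overlap is verified
against a quadratic all-pairs oracle. The insulin-response classification
threshold $|r| \ge 0.3$ is likewise an exposed default. The TF specificity
filter shifts cell-type scores to a non-negative scale and requires the
minimum phagocyte score to *strictly* exceed `foldCut` times the maximum
non-phagocyte score (equality rejected; the boundary behaviour is pinned by
a test).

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* of the study designs:

* multi-cohort NB counts (shared dispersion 0.1, log-normal base means,
  library factors in $[0.7, 1.4]$) with multiplicative sex/batch effects of
  log2-sd 0.3 — large enough that covariate adjustment is required for
  calibration — and planted case effects of $2^{1}$ on shared longevity
  genes;
* an age series of 6 decade bins with trajectory archetypes defined on the
  z-scale (monotone up/down, rise-then-fall, late-spike, flat) at amplitude
  1.5 log2 units and observation noise 0.3;
* cell-labelled profiles with disjoint marker programs and planted
  cross-type gene programs;
* two-group methylomes as inverse-logit Gaussians (M-value sd 0.25), with
  planted $\pm\Delta\beta$ probes and an optional global hypomethylation
  component (a random probe fraction shifted by exponential magnitudes)
  that produces the negative delta-beta skew;
* signature-weighted bulk mixtures with multiplicative log-normal noise.

Gene and probe identifiers are synthetic (`G000001`, `cg000001`) to avoid
implying real annotations. What the generators do **not** model: read-level
noise, GC/length biases, correlated gene-gene backgrounds outside planted
blocks, cell-composition confounding of methylomes, per-gene dispersion
(a single shared dispersion is the default; simplicity keeps planted
effects exactly recoverable), or any attempt to mimic specific real genes.
Passing tests therefore demonstrate *internal correctness and calibration*
of the pipeline under its stated model — not performance on any particular
real cohort.

With dispersion set to 0 the age-series generator returns expected
(continuous) counts so that zero-noise archetype contracts — exact bin-mean
equality and strict monotonicity — hold exactly; all stochastic output is
integer counts.

## Numerical conventions

* Z-scores of constant vectors are defined as 0 throughout.
* Pattern clustering processes genes in lexicographic id order and uses
  average linkage on $1 -$ Pearson, cut at $1 - 0.7$; groups are therefore
  deterministic given the input.
* k-means for gene-score clustering uses 10 restarts under a fixed seed and
  relabels clusters by the cell type of the peak centroid score.
* NNLS zeros are detected at the solver's exact zeros (tolerance 1e-10);
  degenerate all-zero solutions are reported as uniform with a flag.
* BH adjustment is `p.adjust(method = "BH")`, verified against the
  step-up definition by brute force in the tests.
* All generators and every permutation routine take explicit integer seeds;
  the pipeline derives per-stage seeds from the global one by fixed
  offsets, and a rerun with the same seed reproduces every artifact byte
  for byte (checksums in the run manifest).

## Problem sizes used in the validation runs

The shipped tests and the acceptance script run: 3 cohorts of 30+30
samples over 2,000 genes with 100 planted longevity and 100 planted aging
genes (10 seeds) for end-to-end LHA recovery; 10,000 permutations for the
overlap null; exhaustive GSEA oracle comparison for all $2^N - 2$ set
placements with $N \le 12$ plus 200 random placements for $N$ up to 20;
20-sample mixtures over 5 cell types; 100-seed skewness and sign-recovery
experiments at 2,000 probes / 15-gene modules; and 3 planted 50-gene
blocks plus 30 noise genes for module recovery. These sizes were chosen so
each experiment's Monte-Carlo error is comfortably below the margin it is
tested against.

## A short tour

```{r tour, eval = FALSE}
## synthetic cohorts with planted truth
sim <- simulateMulticohortCounts(
  nGenes = 2000,
  cohorts = list(cohortSpec("ChM", 30, 30), cohortSpec("LG", 30, 30),
                 cohortSpec("LS", 30, 30)),
  sharedUp = 1:100, sharedDown = 101:200, effect = 1, seed = 1)

## per-cohort DE and consensus
sets <- lapply(sim$cohorts, function(se) {
  expr <- removeCovariateEffects(logNormalize(se), c("sex", "batch"))
  callDegs(deTwoGroup(expr), pThreshold = 0.05, fcThreshold = 1.2)
})
cdegUp <- intersectSets(lapply(sets, `[[`, "up"), "up")
permutationOverlapNull(2000, sapply(sets, function(s) length(s$up)),
                       observed = length(cdegUp), seed = 1)

## aging trajectories and LHA
aging <- simulateAgeSeries(nGenes = 2000,
  archetypeGenes = list(monotone_up = 201:250), seed = 2)
expr <- logNormalize(aging$se)
aa <- ageAssociationTest(expr, covariates = "sex")
prof <- binProfiles(expr)[aa$gene[aa$padj < 0.05], ]
sel <- selectAgeGroups(clusterPatterns(prof))
lha <- deriveLHA(cdegUp, intersectSets(lapply(sets, `[[`, "down"), "down"),
                 list(sel$agingUp, sel$agingDown))
lha
```

The full pipeline, with file-based stage handoff and a checksummed
manifest, is `runPipeline(demoRunConfig(), "out/", seed = 1)`.

## Known limitations

* The OLS substitution trades power at low counts for testable calibration;
  genes expressed near zero may be under-called relative to NB methods.
* The permutation null assumes uniform gene detectability; if DEG calling
  is strongly biased toward highly expressed genes the null overlap is
  underestimated.
* Static tree cut plus eigengene merging approximates, but does not equal,
  dynamic tree cut; very close modules may merge differently.
* The late-spike `spikeDelta` and flat `flatEpsilon` thresholds are
  package defaults with stated rationale, not externally validated
  constants; both are exposed everywhere they act.
* Probe-level DMP calling without region merging can fragment one
  differentially methylated region into several probe calls; counts of
  "regions" are therefore not comparable across conventions.
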