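#' @useDynLib prstail, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject slot slotNames is show
#' @importFrom stats qnorm pnorm dnorm rnorm runif median var sd cor qchisq
#'   uniroot t.test aggregate
#' @importFrom utils write.table read.table packageVersion
NULL

#' Simulation configuration
#'
#' Holds every architecture, cohort-size, threshold, overlap and replication
#' parameter of the liability-threshold PRS experiment. Defaults reproduce the
#' full-scale study design: 170,000 independent biallelic SNPs (minimum MAF
#' 0.1\%), 1,200 causal SNPs, SNP-heritability 0.10 on the liability scale,
#' population (and sample) prevalence 0.05, a discovery cohort of 366,771
#' individuals, target cohorts of 300,000 with 0/50/100\% individual overlap,
#' top/bottom 5\% extreme-tail selection, and 100 replicates. Use
#' [deskConfig()] for a reduced design of the same causal density that runs on
#' a single CPU.
#'
#' @slot nSnps number of independent biallelic SNPs.
#' @slot nCausal number of causal SNPs.
#' @slot h2Liab SNP-heritability of liability in [0, 1].
#' @slot prevalence population case fraction K in (0, 1).
#' @slot samplePrevalence expected case fraction in sampled cohorts (equal to
#'   \code{prevalence} under the population-sampling design used here).
#' @slot mafMin minimum minor allele frequency.
#' @slot nDiscovery discovery cohort size.
#' @slot nTarget target cohort size.
#' @slot extremeFraction tail fraction per side used to derive the
#'   extreme-tail phenotype.
#' @slot prsThresholds p-value cutoffs for SNP inclusion in the PRS; the first
#'   element is the primary threshold.
#' @slot alphas significance thresholds at which false positive rates are
#'   recorded.
#' @slot overlaps fractions of target individuals shared with the discovery
#'   cohort.
#' @slot nReps number of simulation replicates.
#' @slot masterSeed master seed; all randomness is derived from it per
#'   (replicate, purpose) pair.
#' @slot blockSize SNP block size used by streaming kernels.
#' @export
setClass("SimConfig", representation(
  nSnps = "numeric", nCausal = "numeric", h2Liab = "numeric",
  prevalence = "numeric", samplePrevalence = "numeric", mafMin = "numeric",
  nDiscovery = "numeric", nTarget = "numeric", extremeFraction = "numeric",
  prsThresholds = "numeric", alphas = "numeric", overlaps = "numeric",
  nReps = "numeric", masterSeed = "numeric", blockSize = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  scalar1 <- function(x) length(x) == 1L && is.finite(x)
  if (!scalar1(object@nSnps) || object@nSnps < 1) msg <- c(msg, "nSnps must be a positive count")
  if (!scalar1(object@nCausal) || object@nCausal < 0) msg <- c(msg, "nCausal must be a non-negative count")
  if (object@nCausal > object@nSnps) msg <- c(msg, "nCausal must not exceed nSnps")
  if (!scalar1(object@h2Liab) || object@h2Liab < 0 || object@h2Liab > 1) msg <- c(msg, "h2Liab must lie in [0, 1]")
  if (!scalar1(object@prevalence) || object@prevalence <= 0 || object@prevalence >= 1) msg <- c(msg, "prevalence must lie in (0, 1)")
  if (!scalar1(object@samplePrevalence) || object@samplePrevalence <= 0 || object@samplePrevalence >= 1) msg <- c(msg, "samplePrevalence must lie in (0, 1)")
  if (!scalar1(object@mafMin) || object@mafMin <= 0 || object@mafMin >= 0.5) msg <- c(msg, "mafMin must lie in (0, 0.5)")
  if (!scalar1(object@extremeFraction) || object@extremeFraction <= 0 || object@extremeFraction > 0.5) msg <- c(msg, "extremeFraction must lie in (0, 0.5]")
  if (any(object@prsThresholds <= 0 | object@prsThresholds > 1)) msg <- c(msg, "prsThresholds must lie in (0, 1]")
  if (any(object@alphas <= 0 | object@alphas >= 1)) msg <- c(msg, "alphas must lie in (0, 1)")
  if (any(object@overlaps < 0 | object@overlaps > 1)) msg <- c(msg, "overlaps must lie in [0, 1]")
  if (any(round(object@overlaps * object@nTarget) > object@nDiscovery))
    msg <- c(msg, "nTarget * overlap must not exceed nDiscovery")
  if (!scalar1(object@nReps) || object@nReps < 1) msg <- c(msg, "nReps must be a positive count")
  if (!scalar1(object@masterSeed) || abs(object@masterSeed) >= 2^31) msg <- c(msg, "masterSeed must be a 32-bit integer")
  if (!scalar1(object@blockSize) || object@blockSize < 1) msg <- c(msg, "blockSize must be a positive count")
  if (length(msg)) msg else TRUE
})

#' Per-SNP genetic architecture
#'
#' Allele frequencies, causal flags and true liability-scale effects (on the
#' standardized-genotype scale; zero for non-causal SNPs). Created by
#' [drawPanel()]; the causal effects are rescaled so that their squared sum
#' equals the configured SNP-heritability exactly.
#'
#' @slot maf per-SNP allele frequency.
#' @slot isCausal per-SNP causal flag.
#' @slot betaTrue per-SNP true effect on liability per standardized dosage.
#' @export
setClass("SnpPanel", representation(
  maf = "numeric", isCausal = "logical", betaTrue = "numeric"))

setValidity("SnpPanel", function(object) {
  msg <- character()
  M <- length(object@maf)
  if (length(object@isCausal) != M || length(object@betaTrue) != M)
    msg <- c(msg, "maf, isCausal and betaTrue must have equal length")
  if (any(object@maf <= 0 | object@maf > 0.5)) msg <- c(msg, "maf must lie in (0, 0.5]")
  if (any(object@betaTrue[!object@isCausal] != 0))
    msg <- c(msg, "betaTrue must be zero for non-causal SNPs")
  if (length(msg)) msg else TRUE
})

#' A simulated cohort
#'
#' Individuals with stable integer identifiers, raw allele-count dosages (one
#' byte per genotype, individuals x SNPs), standard-normal liabilities and
#' case/control status. Status is \code{liability > T} where \code{T} is the
#' liability threshold for the population prevalence. Identifiers shared
#' across cohorts denote the same individual with bit-identical dosages and
#' liability; this is how discovery/target sample overlap is represented.
#'
#' Consumers stream the dosage matrix in SNP blocks via [dosageBlock()];
#' kernels never materialise a numeric copy of the whole matrix.
#'
#' @slot ids unique integer individual identifiers.
#' @slot dosages raw matrix (individuals x SNPs) of allele counts in {0,1,2}.
#' @slot liability per-individual liability.
#' @slot status per-individual case flag.
#' @export
setClass("Cohort", representation(
  ids = "integer", dosages = "matrix", liability = "numeric",
  status = "logical"))

setValidity("Cohort", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (!is.raw(object@dosages)) msg <- c(msg, "dosages must be a raw matrix")
  if (nrow(object@dosages) != n) msg <- c(msg, "dosages must have one row per individual")
  if (length(object@liability) != n || length(object@status) != n)
    msg <- c(msg, "liability and status must have one entry per individual")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique within a cohort")
  if (length(msg)) msg else TRUE
})

#' Per-SNP association results
#'
#' One row per SNP from the allele-dosage trend test ([gwas()]): effect
#' estimate on the 0/1 phenotype per dosage unit, standard error, Z score and
#' two-sided normal p-value. Monomorphic SNPs carry \code{beta = se = z = 0},
#' \code{p = 1} and \code{polymorphic = FALSE} so downstream masks stay total.
#'
#' @slot beta per-SNP effect estimate.
#' @slot se per-SNP standard error.
#' @slot z per-SNP Z statistic.
#' @slot p per-SNP two-sided p-value.
#' @slot polymorphic per-SNP flag: variable in the tested sample.
#' @slot n number of individuals tested.
#' @export
setClass("GwasResult", representation(
  beta = "numeric", se = "numeric", z = "numeric", p = "numeric",
  polymorphic = "logical", n = "numeric"))

#' A thresholded PRS model
#'
#' Discovery-GWAS effect estimates for SNPs passing the inclusion p-value
#' cutoff (closed interval, \code{p <= threshold}) and zero elsewhere. With
#' SNPs simulated in linkage equilibrium, pruning is a no-op and
#' pruning-and-thresholding reduces to thresholding.
#'
#' @slot included per-SNP inclusion flag.
#' @slot weights per-SNP scoring weight (discovery beta where included).
#' @slot threshold the p-value cutoff used.
#' @export
setClass("PrsModel", representation(
  included = "logical", weights = "numeric", threshold = "numeric"))

#' An extreme-tail phenotype derived from PRS
#'
#' The individuals retained after keeping the top and bottom score tails:
#' cases are the top tail, controls the bottom tail, and the middle of the
#' score distribution is discarded. Perfectly balanced by construction.
#'
#' @slot selectedIds identifiers of retained individuals (controls first).
#' @slot status case flag of retained individuals.
#' @slot scores PRS values of retained individuals.
#' @export
setClass("DerivedPhenotype", representation(
  selectedIds = "integer", status = "logical", scores = "numeric"))

#' Parameters of the analytic PRS accuracy model
#'
#' Inputs of the Dudbridge-style expected-R2 model used by [expectedPrsR2()]
#' and [requiredDiscoveryN()]: total and causal SNP counts, liability variance
#' explained by all causal SNPs, prevalences, the PRS inclusion p-value
#' cutoff, whether the trait is binary, and the liability-scale R2 the score
#' should reach.
#'
#' @slot nSnps,nCausal SNP counts.
#' @slot vg liability variance explained by all causal SNPs.
#' @slot prevalence,samplePrevalence population and sample case fractions.
#' @slot pThreshold PRS inclusion p-value cutoff.
#' @slot binaryTrait if FALSE, the continuous-trait limit is used.
#' @slot targetR2Liab liability-scale R2 target for sample-size solving.
#' @export
setClass("PowerParams", representation(
  nSnps = "numeric", nCausal = "numeric", vg = "numeric",
  prevalence = "numeric", samplePrevalence = "numeric",
  pThreshold = "numeric", binaryTrait = "logical", targetR2Liab = "numeric"))

setValidity("PowerParams", function(object) {
  msg <- character()
  if (object@nCausal < 0 || object@nCausal > object@nSnps) msg <- c(msg, "nCausal must lie in [0, nSnps]")
  if (object@vg < 0 || object@vg > 1) msg <- c(msg, "vg must lie in [0, 1]")
  if (object@prevalence <= 0 || object@prevalence >= 1) msg <- c(msg, "prevalence must lie in (0, 1)")
  if (object@samplePrevalence <= 0 || object@samplePrevalence >= 1) msg <- c(msg, "samplePrevalence must lie in (0, 1)")
  if (object@pThreshold <= 0 || object@pThreshold > 1) msg <- c(msg, "pThreshold must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
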