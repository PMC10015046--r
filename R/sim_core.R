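#' Build a simulation configuration
#'
#' All arguments default to the full-scale study design (see
#' \linkS4class{SimConfig}). Counts may be given as doubles; they are
#' validated, not coerced.
#'
#' @param nSnps,nCausal,h2Liab,prevalence,samplePrevalence,mafMin,nDiscovery,nTarget,extremeFraction,prsThresholds,alphas,overlaps,nReps,masterSeed,blockSize
#'   see \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSnps = 2000, nCausal = 20, nDiscovery = 5000,
#'                  nTarget = 4000, nReps = 2, masterSeed = 1)
#' cfg
#' @export
simConfig <- function(nSnps = 170000, nCausal = 1200, h2Liab = 0.10,
                      prevalence = 0.05, samplePrevalence = 0.05,
                      mafMin = 0.001, nDiscovery = 366771, nTarget = 300000,
                      extremeFraction = 0.05,
                      prsThresholds = c(0.05, 1, 5e-8),
                      alphas = c(5e-8, 0.05, 1e-15),
                      overlaps = c(0, 0.5, 1),
                      nReps = 100, masterSeed = 1, blockSize = 8192) {
  new("SimConfig", nSnps = nSnps, nCausal = nCausal, h2Liab = h2Liab,
      prevalence = prevalence, samplePrevalence = samplePrevalence,
      mafMin = mafMin, nDiscovery = nDiscovery, nTarget = nTarget,
      extremeFraction = extremeFraction, prsThresholds = prsThresholds,
      alphas = alphas, overlaps = overlaps, nReps = nReps,
      masterSeed = masterSeed, blockSize = blockSize)
}

#' Read or replace configuration parameters
#'
#' @param config a \linkS4class{SimConfig}.
#' @param name a slot name, e.g. \code{"nSnps"}.
#' @return \code{getParam} returns the value; \code{setParams} returns a new
#'   validated configuration with the named slots replaced.
#' @export
getParam <- function(config, name) {
  stopifnot(is(config, "SimConfig"))
  if (!name %in% slotNames(config)) stop("unknown parameter: ", name)
  slot(config, name)
}

#' @rdname getParam
#' @param ... named parameters to replace.
#' @export
setParams <- function(config, ...) {
  stopifnot(is(config, "SimConfig"))
  repl <- list(...)
  bad <- setdiff(names(repl), slotNames(config))
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))
  for (nm in names(repl)) slot(config, nm) <- repl[[nm]]
  validObject(config)
  config
}

#' Liability threshold for a given prevalence
#'
#' The value T with P(N(0,1) > T) = K: individuals whose liability exceeds T
#' are cases, the rest controls.
#'
#' @param prevalence population case fraction K in (0, 1).
#' @return the upper-tail standard-normal quantile at K.
#' @examples
#' liabilityThreshold(0.5)   # 0
#' liabilityThreshold(0.05)  # 1.6449
#' @export
liabilityThreshold <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be a single number in (0, 1)")
  qnorm(prevalence, lower.tail = FALSE)
}

#' Draw a genetic architecture panel
#'
#' Allele frequencies are drawn uniformly on [mafMin, 0.5] (the simplest
#' distribution consistent with a stated minimum MAF), causal SNPs are a
#' uniform random subset, and causal effects are i.i.d. normal on the
#' standardized-genotype scale rescaled so that sum(betaTrue^2) equals
#' \code{h2Liab} exactly. Uses the current RNG state.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SnpPanel}.
#' @export
drawPanel <- function(config) {
  stopifnot(is(config, "SimConfig"))
  M <- as.integer(config@nSnps)
  mc <- as.integer(config@nCausal)
  maf <- runif(M, config@mafMin, 0.5)
  causal <- logical(M)
  beta <- numeric(M)
  if (mc > 0) {
    idx <- sample.int(M, mc)
    causal[idx] <- TRUE
    b <- rnorm(mc)
    beta[idx] <- b * sqrt(config@h2Liab / sum(b^2))
  }
  new("SnpPanel", maf = maf, isCausal = causal, betaTrue = beta)
}

#' Simulate a cohort under the liability threshold model
#'
#' Dosages are independent Binomial(2, maf_j) draws per SNP (Hardy-Weinberg,
#' linkage equilibrium). Liability is the sum of causal effects on the
#' theoretically standardized dosages, (d - 2p)/sqrt(2p(1-p)), plus an
#' environmental term N(0, 1 - sum(betaTrue^2)), so liability has unit
#' variance by construction. Case status is liability above the threshold for
#' the population prevalence: sampling is plain population sampling, so the
#' realized case fraction is a Binomial(n, K) draw, not an exact quota.
#'
#' @param panel a \linkS4class{SnpPanel}.
#' @param n number of individuals (>= 1).
#' @param config a \linkS4class{SimConfig}; only \code{prevalence} is used.
#' @param ids optional integer identifiers (default \code{seq_len(n)}).
#' @return a \linkS4class{Cohort}.
#' @export
simulateCohort <- function(panel, n, config, ids = NULL) {
  stopifnot(is(panel, "SnpPanel"), is(config, "SimConfig"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  h2 <- sum(panel@betaTrue^2)
  if (h2 > 1) stop("sum of squared effects exceeds 1")
  # genotype stream seeded from R's RNG, so set.seed() governs all draws
  gseed <- sample.int(2147483647L, 2)
  sim <- cpp_simulate_genotypes(panel@maf, panel@betaTrue, n, gseed)
  liab <- sim$g + rnorm(n, 0, sqrt(1 - h2))
  thr <- liabilityThreshold(config@prevalence)
  new("Cohort", ids = ids, dosages = sim$dosages, liability = liab,
      status = liab > thr)
}

#' Build a target cohort with controlled discovery overlap
#'
#' Exactly \code{round(overlap * nTarget)} individuals are copied from a
#' uniform random subset of the discovery cohort (same ids, dosages, liability
#' and status); the remainder are freshly simulated from the same panel.
#' Within one replicate the overlap variants reuse one discovery cohort, so
#' shared individuals are bit-identical across cohorts.
#'
#' @param discovery the discovery \linkS4class{Cohort}.
#' @param overlap fraction of target individuals shared with discovery.
#' @param nTarget target cohort size.
#' @param panel the \linkS4class{SnpPanel} the discovery was simulated from.
#' @param config a \linkS4class{SimConfig}.
#' @param idStart first identifier for freshly simulated individuals; defaults
#'   to \code{max(ids(discovery)) + 1}. Pass distinct ranges when building
#'   several target variants so that fresh individuals never share ids.
#' @return a \linkS4class{Cohort} with copied individuals first.
#' @export
makeTargetWithOverlap <- function(discovery, overlap, nTarget, panel, config,
                                  idStart = NULL) {
  stopifnot(is(discovery, "Cohort"), is(panel, "SnpPanel"),
            is(config, "SimConfig"))
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  nTarget <- as.integer(nTarget)
  k <- as.integer(round(overlap * nTarget))
  nd <- nIndividuals(discovery)
  if (k > nd) stop("overlap * nTarget exceeds the discovery cohort size")
  if (is.null(idStart)) idStart <- max(discovery@ids) + 1L
  pick <- if (k > 0) sort(sample.int(nd, k)) else integer(0)
  nFresh <- nTarget - k
  if (nFresh > 0) {
    fresh <- simulateCohort(panel, nFresh, config,
                            ids = seq.int(idStart, length.out = nFresh))
  }
  if (k == 0) return(fresh)
  copiedDos <- cpp_subset_rows(discovery@dosages, pick)
  if (nFresh == 0) {
    return(new("Cohort", ids = discovery@ids[pick], dosages = copiedDos,
               liability = discovery@liability[pick],
               status = discovery@status[pick]))
  }
  new("Cohort",
      ids = c(discovery@ids[pick], fresh@ids),
      dosages = cpp_rbind_raw(copiedDos, fresh@dosages),
      liability = c(discovery@liability[pick], fresh@liability),
      status = c(discovery@status[pick], fresh@status))
}

#' Debug writers for cohorts and panels
#'
#' Plain tab-separated outputs: one row per individual (id, liability,
#' status) or per SNP (snp_index, maf, is_causal, beta_true).
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCohortTsv <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  df <- data.frame(id = cohort@ids, liability = cohort@liability,
                   status = as.integer(cohort@status))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTsv
#' @param panel a \linkS4class{SnpPanel}.
#' @export
writePanelTsv <- function(panel, path) {
  stopifnot(is(panel, "SnpPanel"))
  df <- data.frame(snp_index = seq_len(nSnps(panel)), maf = panel@maf,
                   is_causal = as.integer(panel@isCausal),
                   beta_true = panel@betaTrue)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic child seed for a (replicate, purpose) pair. Keeps every seed
# in [1, 2^31 - 2] and spreads purposes apart so streams never collide.
childSeed <- function(masterSeed, rep, purpose) {
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 131 + ch) %% 1048573
  val <- (abs(masterSeed) %% 2147483647) * 1000003 + rep * 7919 + h * 104729
  as.integer(val %% 2147483562 + 1)
}
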