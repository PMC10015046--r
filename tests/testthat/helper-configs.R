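# Small architectures used across tests. Sizes are chosen so each file runs
# in seconds; statistical assertions use tolerances matched to the binomial /
# Monte-Carlo error at these sizes.

tinyConfig <- function(...) {
  args <- modifyList(list(nSnps = 500, nCausal = 10, nDiscovery = 3000,
                          nTarget = 2000, nReps = 2, masterSeed = 11),
                     list(...))
  do.call(simConfig, args)
}

smallConfig <- function(...) {
  args <- modifyList(list(nSnps = 2000, nCausal = 20, nDiscovery = 8000,
                          nTarget = 6000, nReps = 3, masterSeed = 7),
                     list(...))
  do.call(simConfig, args)
}

# raw dosage matrix from an integer matrix (individuals x SNPs)
rawDosages <- function(m) {
  matrix(as.raw(m), nrow = nrow(m))
}

# standardized genetic value of a cohort, computed independently from blocks
geneticValue <- function(cohort, panel, chunk = 500L) {
  M <- nSnps(panel)
  g <- numeric(nIndividuals(cohort))
  for (j0 in seq.int(1L, M, by = chunk)) {
    j1 <- min(j0 + chunk - 1L, M)
    idx <- j0:j1
    b <- betaTrue(panel)[idx]
    if (all(b == 0)) next
    d <- dosageBlock(cohort, j0, j1)
    p <- maf(panel)[idx]
    std <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    g <- g + drop(std %*% b)
  }
  g
}
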