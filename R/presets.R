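#' Study presets
#'
#' \code{fullConfig()} is the full-scale design: 170,000 SNPs, 1,200 causal,
#' discovery N = 366,771 (the avengeme-convention solution for a PRS
#' explaining 5\% at inclusion p <= 0.05), target N = 300,000 and 100
#' replicates. One replicate streams on the order of 6e10 genotype draws;
#' this preset is for cluster-scale runs.
#'
#' \code{deskConfig()} keeps the causal density (141 of 20,000 SNPs), solves
#' the discovery size with [requiredDiscoveryN()] at the same target R2
#' (43,141 under the planning convention), and uses a 40,000-individual
#' target with 20 replicates. It reproduces the qualitative mechanism on one
#' CPU in minutes.
#'
#' @param masterSeed master seed for the run.
#' @param nReps number of replicates.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' deskConfig()
#' @export
deskConfig <- function(masterSeed = 1, nReps = 20) {
  pp <- powerParams(nSnps = 20000, nCausal = 141)
  nd <- requiredDiscoveryN(pp)
  simConfig(nSnps = 20000, nCausal = 141, nDiscovery = nd, nTarget = 40000,
            nReps = nReps, masterSeed = masterSeed)
}

#' @rdname deskConfig
#' @export
fullConfig <- function(masterSeed = 1, nReps = 100) {
  simConfig(nReps = nReps, masterSeed = masterSeed)
}
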