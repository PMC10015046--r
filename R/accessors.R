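#' @rdname SnpPanel-class
#' @export
setMethod("nSnps", "SnpPanel", function(x) length(x@maf))

#' @rdname Cohort-class
#' @export
setMethod("nSnps", "Cohort", function(x) ncol(x@dosages))

#' @rdname SnpPanel-class
#' @export
setMethod("maf", "SnpPanel", function(x) x@maf)

#' @rdname SnpPanel-class
#' @export
setMethod("isCausal", "SnpPanel", function(x) x@isCausal)

#' @rdname SnpPanel-class
#' @export
setMethod("betaTrue", "SnpPanel", function(x) x@betaTrue)

#' @rdname Cohort-class
#' @export
setMethod("ids", "Cohort", function(x) x@ids)

#' @rdname Cohort-class
#' @export
setMethod("liability", "Cohort", function(x) x@liability)

#' @rdname Cohort-class
#' @export
setMethod("status", "Cohort", function(x) x@status)

#' @rdname Cohort-class
#' @export
setMethod("nIndividuals", "Cohort", function(x) length(x@ids))

#' @rdname dosageBlock
#' @export
setMethod("dosageBlock", "Cohort", function(x, j0, j1) {
  cpp_block_int(x@dosages, as.integer(j0), as.integer(j1))
})

#' @rdname Cohort-class
#' @export
setMethod("alleleFreq", "Cohort", function(x) {
  cpp_allele_freq(x@dosages, integer(0))
})

#' @rdname DerivedPhenotype-class
#' @export
setMethod("ids", "DerivedPhenotype", function(x) x@selectedIds)

#' @rdname DerivedPhenotype-class
#' @export
setMethod("status", "DerivedPhenotype", function(x) x@status)

#' @rdname PrsModel-class
#' @export
setMethod("included", "PrsModel", function(x) x@included)

#' @rdname PrsModel-class
#' @export
setMethod("prsWeights", "PrsModel", function(x) x@weights)

#' Convert association results to a data frame
#'
#' @param x a \linkS4class{GwasResult}.
#' @param row.names,optional,... passed through for generic compatibility.
#' @return a data.frame with columns snp_index, beta, se, z, p, polymorphic.
#' @export
as.data.frame.GwasResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(snp_index = seq_along(x@beta), beta = x@beta, se = x@se,
             z = x@z, p = x@p, polymorphic = x@polymorphic)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  SNPs: %s (%s causal), h2_liab = %g, MAF >= %g\n",
              format(object@nSnps, big.mark = ","),
              format(object@nCausal, big.mark = ","),
              object@h2Liab, object@mafMin))
  cat(sprintf("  prevalence K = %g, sample prevalence P = %g\n",
              object@prevalence, object@samplePrevalence))
  cat(sprintf("  discovery N = %s, target N = %s, tail fraction = %g\n",
              format(object@nDiscovery, big.mark = ","),
              format(object@nTarget, big.mark = ","), object@extremeFraction))
  cat(sprintf("  PRS thresholds: %s; alphas: %s; overlaps: %s\n",
              paste(format(object@prsThresholds), collapse = ", "),
              paste(format(object@alphas), collapse = ", "),
              paste(format(object@overlaps), collapse = ", ")))
  cat(sprintf("  replicates: %d, master seed: %d\n",
              as.integer(object@nReps), as.integer(object@masterSeed)))
})

setMethod("show", "SnpPanel", function(object) {
  cat(sprintf("SnpPanel: %s SNPs, %s causal, sum(beta^2) = %.6g\n",
              format(length(object@maf), big.mark = ","),
              format(sum(object@isCausal), big.mark = ","),
              sum(object@betaTrue^2)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %s individuals x %s SNPs, %s cases (%.3f)\n",
              format(length(object@ids), big.mark = ","),
              format(ncol(object@dosages), big.mark = ","),
              format(sum(object@status), big.mark = ","),
              mean(object@status)))
})

setMethod("show", "GwasResult", function(object) {
  cat(sprintf("GwasResult: %s SNPs tested in %s individuals (%s monomorphic)\n",
              format(length(object@z), big.mark = ","),
              format(object@n, big.mark = ","),
              format(sum(!object@polymorphic), big.mark = ",")))
})

setMethod("show", "PrsModel", function(object) {
  cat(sprintf("PrsModel: p <= %g, %s of %s SNPs included\n",
              object@threshold,
              format(sum(object@included), big.mark = ","),
              format(length(object@included), big.mark = ",")))
})

setMethod("show", "DerivedPhenotype", function(object) {
  cat(sprintf("DerivedPhenotype: %s retained (%s cases / %s controls)\n",
              format(length(object@selectedIds), big.mark = ","),
              format(sum(object@status), big.mark = ","),
              format(sum(!object@status), big.mark = ",")))
})

setMethod("show", "PowerParams", function(object) {
  cat(sprintf("PowerParams: %s SNPs (%s causal), vg = %g, K = %g, P = %g,\n",
              format(object@nSnps, big.mark = ","),
              format(object@nCausal, big.mark = ","),
              object@vg, object@prevalence, object@samplePrevalence))
  cat(sprintf("  inclusion p <= %g, binary = %s, target liability R2 = %g\n",
              object@pThreshold, object@binaryTrait, object@targetR2Liab))
})
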