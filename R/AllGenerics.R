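#' @rdname SnpPanel-class
#' @param x a \linkS4class{SnpPanel} or \linkS4class{Cohort}.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname SnpPanel-class
#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' @rdname SnpPanel-class
#' @export
setGeneric("isCausal", function(x) standardGeneric("isCausal"))

#' @rdname SnpPanel-class
#' @export
setGeneric("betaTrue", function(x) standardGeneric("betaTrue"))

#' @rdname Cohort-class
#' @param x a \linkS4class{Cohort} (or \linkS4class{DerivedPhenotype} for
#'   \code{ids} and \code{status}).
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname Cohort-class
#' @export
setGeneric("liability", function(x) standardGeneric("liability"))

#' @rdname Cohort-class
#' @export
setGeneric("status", function(x) standardGeneric("status"))

#' @rdname Cohort-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Stream a SNP block of the dosage matrix
#'
#' Returns columns \code{j0:j1} of the cohort's dosage matrix as an integer
#' matrix. This is the block-access contract: operations iterate SNP blocks
#' and never require the full genotype matrix in numeric form.
#'
#' @param x a \linkS4class{Cohort}.
#' @param j0,j1 first and last SNP column (1-based, inclusive).
#' @return an integer matrix (individuals x block SNPs) with entries in
#'   {0,1,2}.
#' @export
setGeneric("dosageBlock", function(x, j0, j1) standardGeneric("dosageBlock"))

#' @rdname Cohort-class
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname PrsModel-class
#' @param x a \linkS4class{PrsModel}.
#' @export
setGeneric("included", function(x) standardGeneric("included"))

#' @rdname PrsModel-class
#' @export
setGeneric("prsWeights", function(x) standardGeneric("prsWeights"))
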