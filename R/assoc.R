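#' Per-SNP trend-test GWAS of a binary phenotype
#'
#' Simple linear regression of the 0/1 phenotype on allele dosage, per SNP —
#' equivalent under the null to the Cochran-Armitage trend test, with exact
#' type-I error calibration, which is the quantity this package studies.
#' Two-sided p-values come from the normal approximation (sample sizes here
#' are large); no covariates are fitted. Computation streams SNP column
#' blocks with one pass over the genotype source, so the result is invariant
#' to block size and to individual ordering.
#'
#' Monomorphic SNPs (no dosage variation in the tested sample) are flagged
#' \code{polymorphic = FALSE} and reported with \code{beta = se = z = 0},
#' \code{p = 1}, keeping downstream masks total.
#'
#' @param x a \linkS4class{Cohort} or a raw dosage matrix
#'   (individuals x SNPs).
#' @param phenotype per-individual 0/1 labels (numeric or logical), aligned
#'   with the rows being tested. Must not be constant.
#' @param rows optional 1-based row indices restricting the tested
#'   individuals; \code{phenotype} then has one entry per selected row.
#' @param blockSize number of SNP columns processed per block.
#' @return a \linkS4class{GwasResult}. At least 3 individuals are required
#'   (the OLS residual variance needs a degree of freedom).
#' @examples
#' \dontrun{
#' res <- gwas(cohort, as.numeric(status(cohort)))
#' }
#' @export
gwas <- function(x, phenotype, rows = NULL, blockSize = 8192) {
  dos <- if (is(x, "Cohort")) x@dosages else x
  if (!is.raw(dos) || !is.matrix(dos)) stop("x must be a Cohort or raw dosage matrix")
  if (is.logical(phenotype)) phenotype <- as.numeric(phenotype)
  rows <- if (is.null(rows)) integer(0) else as.integer(rows)
  n <- if (length(rows)) length(rows) else nrow(dos)
  if (length(phenotype) != n) stop("phenotype length does not match the tested individuals")
  if (n < 3) stop("at least 3 individuals are required")
  if (var(phenotype) == 0) stop("phenotype is constant")
  M <- ncol(dos)
  starts <- seq.int(1L, M, by = as.integer(blockSize))
  parts <- lapply(starts, function(j0) {
    j1 <- min(j0 + as.integer(blockSize) - 1L, M)
    cpp_gwas_range(dos, phenotype, rows, j0, j1)
  })
  res <- do.call(rbind, parts)
  z <- res[, 3]
  new("GwasResult", beta = res[, 1], se = res[, 2], z = z,
      p = 2 * pnorm(-abs(z)), polymorphic = res[, 4] > 0, n = n)
}

#' Genomic inflation of null test statistics
#'
#' The median of z^2 over null SNPs divided by the theoretical median of a
#' 1-df chi-square (0.4549), together with the variance of z over null SNPs.
#' Values near 1 indicate calibrated tests.
#'
#' @param result a \linkS4class{GwasResult}.
#' @param nullMask per-SNP flag selecting the null SNPs (at least one).
#' @return a list with elements \code{lambda} and \code{varZ}.
#' @export
genomicInflation <- function(result, nullMask) {
  stopifnot(is(result, "GwasResult"))
  nullMask <- as.logical(nullMask)
  if (length(nullMask) != length(result@z)) stop("mask length must match SNP count")
  if (!any(nullMask)) stop("the null mask selects no SNPs")
  z <- result@z[nullMask]
  list(lambda = median(z^2) / qchisq(0.5, df = 1), varZ = var(z))
}

#' Write GWAS summary statistics as TSV
#'
#' Minimal summary-statistics dialect for this simulation (no genomic
#' coordinates exist): snp_index, maf, beta, se, z, p, n.
#'
#' @param result a \linkS4class{GwasResult}.
#' @param path output file path.
#' @param maf optional per-SNP allele frequencies to include.
#' @return the path, invisibly.
#' @export
writeGwasTsv <- function(result, path, maf = NULL) {
  stopifnot(is(result, "GwasResult"))
  df <- data.frame(snp_index = seq_along(result@z),
                   maf = if (is.null(maf)) NA_real_ else maf,
                   beta = result@beta, se = result@se, z = result@z,
                   p = result@p, n = result@n)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
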