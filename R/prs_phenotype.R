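#' Select SNPs for a thresholded PRS
#'
#' Inclusion is \code{p <= threshold} (closed interval, matching common plink
#' behaviour) restricted to SNPs polymorphic in the discovery sample. SNPs
#' are simulated in linkage equilibrium, so no pruning/clumping step exists:
#' pruning-and-thresholding reduces to thresholding.
#'
#' @param discoveryGwas a \linkS4class{GwasResult} from the discovery cohort.
#' @param threshold inclusion p-value cutoff in (0, 1].
#' @return a \linkS4class{PrsModel}; weights are the discovery effect
#'   estimates where included and zero elsewhere.
#' @export
selectSnps <- function(discoveryGwas, threshold) {
  stopifnot(is(discoveryGwas, "GwasResult"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  inc <- discoveryGwas@polymorphic & discoveryGwas@p <= threshold
  w <- ifelse(inc, discoveryGwas@beta, 0)
  new("PrsModel", included = inc, weights = w, threshold = threshold)
}

#' Score a cohort with a PRS model
#'
#' Raw-dosage scoring: score_i = sum over included SNPs of weight_j *
#' dosage_ij, in one pass over SNP blocks. No standardization or allele
#' frequency centering is applied — affine changes of the score do not affect
#' tail membership.
#'
#' @param model a non-empty \linkS4class{PrsModel}.
#' @param cohort a \linkS4class{Cohort} (or raw dosage matrix).
#' @param rows optional 1-based row subset to score.
#' @return a numeric vector of scores.
#' @export
scoreCohort <- function(model, cohort, rows = NULL) {
  stopifnot(is(model, "PrsModel"))
  dos <- if (is(cohort, "Cohort")) cohort@dosages else cohort
  if (!any(model@included)) stop("empty PRS model: no SNPs included")
  if (length(model@weights) != ncol(dos))
    stop("model SNP count does not match the cohort")
  rows <- if (is.null(rows)) integer(0) else as.integer(rows)
  drop(cpp_score(dos, matrix(model@weights, ncol = 1), rows))
}

# Score several PRS models in one pass over the genotypes. Empty models give
# a column of NA. Internal: used by runReplicate so the three thresholds cost
# a single sweep.
scoreCohortMulti <- function(models, cohort) {
  dos <- cohort@dosages
  W <- vapply(models, function(m) m@weights, numeric(ncol(dos)))
  sc <- cpp_score(dos, W, integer(0))
  for (t in seq_along(models))
    if (!any(models[[t]]@included)) sc[, t] <- NA_real_
  sc
}

#' Derive an extreme-tail case-control phenotype from scores
#'
#' Exactly \code{k = round(extremeFraction * n)} highest-scoring individuals
#' become cases and the k lowest controls; the middle of the distribution is
#' discarded (with the default 5\% tails, 90\% of the sample is removed).
#' Ties are broken deterministically by individual id: among equal scores,
#' lower ids sort first, so the top tail prefers higher ids at a tied
#' boundary.
#'
#' @param scores per-individual PRS values.
#' @param ids matching individual identifiers.
#' @param extremeFraction tail fraction per side, in (0, 0.5].
#' @return a \linkS4class{DerivedPhenotype} with controls first.
#' @examples
#' d <- deriveExtremePhenotype(1:20, 1:20, 0.1)
#' ids(d)     # 1, 2 (controls), 19, 20 (cases)
#' @export
deriveExtremePhenotype <- function(scores, ids, extremeFraction) {
  n <- length(scores)
  if (length(ids) != n) stop("scores and ids lengths differ")
  if (extremeFraction <= 0 || extremeFraction > 0.5)
    stop("extremeFraction must lie in (0, 0.5]")
  k <- as.integer(round(extremeFraction * n))
  if (k < 1 || 2L * k > n)
    stop("insufficient individuals for the requested tail fraction")
  ids <- as.integer(ids)
  ord <- order(scores, ids)
  sel <- c(ord[seq_len(k)], ord[seq.int(n - k + 1L, n)])
  new("DerivedPhenotype", selectedIds = ids[sel],
      status = rep(c(FALSE, TRUE), each = k), scores = scores[sel])
}

#' Liability-scale variance explained by a score
#'
#' Squared score-status correlation on the observed 0/1 scale, converted to
#' the liability scale with the ascertainment-aware transformation of
#' Lee et al. (2012, Genet Epidemiol 36:214-224):
#' \deqn{R^2_l = \frac{C R^2_o}{1 + C \theta R^2_o}}
#' where, with i = z/K the mean liability of cases and t the threshold,
#' C = K^2(1-K)^2 / (z^2 P(1-P)) and
#' \eqn{\theta = i ((P-K)/(1-K)) (i (P-K)/(1-K) - t)}. When the sample
#' prevalence P equals the population prevalence K (population sampling, the
#' design simulated here), \eqn{\theta = 0} and the factor reduces to the
#' simple K-based conversion K(1-K)/z^2.
#'
#' @param scores per-individual scores (not constant).
#' @param status per-individual case flags (both classes present).
#' @param prevalence population prevalence K.
#' @param samplePrevalence sample case fraction P (defaults to K).
#' @return the liability-scale variance explained.
#' @export
liabilityR2 <- function(scores, status, prevalence,
                        samplePrevalence = prevalence) {
  status <- as.numeric(status)
  if (length(scores) != length(status)) stop("scores and status lengths differ")
  if (var(status) == 0) stop("status has a single class")
  if (var(scores) == 0) stop("scores are constant")
  K <- prevalence; P <- samplePrevalence
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) stop("prevalences must lie in (0, 1)")
  r2o <- cor(scores, status)^2
  t <- qnorm(1 - K)
  z <- dnorm(t)
  i <- z / K
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  theta <- i * ((P - K) / (1 - K)) * (i * (P - K) / (1 - K) - t)
  C * r2o / (1 + C * theta * r2o)
}

#' Write PRS artefacts as TSV
#'
#' @param model a \linkS4class{PrsModel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePrsModelTsv <- function(model, path) {
  stopifnot(is(model, "PrsModel"))
  df <- data.frame(snp_index = seq_along(model@weights),
                   weight = model@weights,
                   included = as.integer(model@included))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePrsModelTsv
#' @param scores,ids,derived per-individual scores and ids, and optionally the
#'   \linkS4class{DerivedPhenotype} giving retained individuals' status.
#' @export
writeScoresTsv <- function(scores, ids, path, derived = NULL) {
  st <- rep(NA_integer_, length(scores))
  if (!is.null(derived)) {
    stopifnot(is(derived, "DerivedPhenotype"))
    st[match(derived@selectedIds, ids)] <- as.integer(derived@status)
  }
  df <- data.frame(id = ids, score = scores, derived_status = st)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
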