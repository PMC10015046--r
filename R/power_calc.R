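#' Parameters for the analytic PRS accuracy model
#'
#' @param nSnps,nCausal,vg,prevalence,samplePrevalence,pThreshold,binaryTrait,targetR2Liab
#'   see \linkS4class{PowerParams}. Defaults are the full-scale architecture.
#' @return a validated \linkS4class{PowerParams}.
#' @export
powerParams <- function(nSnps = 170000, nCausal = 1200, vg = 0.10,
                        prevalence = 0.05, samplePrevalence = prevalence,
                        pThreshold = 0.05, binaryTrait = TRUE,
                        targetR2Liab = 0.05) {
  new("PowerParams", nSnps = nSnps, nCausal = nCausal, vg = vg,
      prevalence = prevalence, samplePrevalence = samplePrevalence,
      pThreshold = pThreshold, binaryTrait = binaryTrait,
      targetR2Liab = targetR2Liab)
}

# Core of the Dudbridge-style model. Works on the scale where genotypes are
# standardized and the per-SNP estimation error of the discovery GWAS has
# variance 1/neff. Causal effects are i.i.d. normal with per-SNP variance
# vg/nCausal; a SNP enters the score when its two-sided p-value is at most
# pThreshold, i.e. |betaHat| > qnorm(1 - p/2)/sqrt(neff). Returns the squared
# correlation between the weighted score and the (unit-variance) genetic
# liability:
#   R2 = C^2 / V,
#   V  = mc * E[bh^2; sel | causal] + (M - mc) * E[bh^2; sel | null]
#   C  = mc * (sigma2 / (sigma2 + 1/neff)) * E[bh^2; sel | causal]
# with E[X^2; |X| > c] = s^2 * 2 * (u phi(u) + 1 - Phi(u)), u = c/s, for
# X ~ N(0, s^2).
r2Core <- function(neff, M, mc, vg, pThreshold) {
  if (mc == 0 || vg == 0) return(0)
  v <- 1 / neff
  sigma2 <- vg / mc
  cth <- qnorm(pThreshold / 2, lower.tail = FALSE) * sqrt(v)
  if (!is.finite(cth)) return(0)
  tailE2 <- function(s2) {
    u <- cth / sqrt(s2)
    s2 * 2 * (u * dnorm(u) + pnorm(u, lower.tail = FALSE))
  }
  Tc <- tailE2(sigma2 + v)
  T0 <- tailE2(v)
  C <- mc * sigma2 / (sigma2 + v) * Tc
  V <- mc * Tc + (M - mc) * T0
  if (V <= 0) return(0)
  C^2 / V
}

#' Expected variance explained by a thresholded PRS
#'
#' Analytic (Dudbridge-style, as in the avengeme package) expectation of the
#' variance explained by a polygenic score built from discovery-GWAS effect
#' estimates passing a p-value threshold, under normal effect sizes among
#' \code{nCausal} of \code{nSnps} independent SNPs. Null SNPs contribute pure
#' estimation noise at rate \code{pThreshold}; causal SNPs contribute signal
#' plus noise with inclusion probability given by their non-centrality.
#'
#' Two conventions are provided for binary traits:
#' \describe{
#'   \item{\code{"avengeme"}}{the sample-size planning convention used with
#'     the avengeme calculator for case-control designs: quantitative-trait
#'     non-centrality (estimation error variance 1/n) with the score R2
#'     reported on the observed scale of a balanced (50/50) case-control
#'     target, i.e. multiplied by z^2/4 / (K(1-K))^2 where z is the normal
#'     density at the liability threshold.}
#'   \item{\code{"population"}}{the design this package actually simulates: a
#'     population sample at prevalence K analysed by 0/1-on-dosage regression,
#'     giving effective sample size n * z^2 P(1-P) / (K(1-K))^2 (P = sample
#'     prevalence; with P = K this is n z^2/(K(1-K))), and R2 reported on the
#'     liability scale. This is the convention validated against simulation.}
#' }
#' With \code{binaryTrait = FALSE} both conventions reduce to the identity
#' (continuous-trait limit): error variance 1/n and liability-scale R2.
#'
#' The two conventions differ materially: at 5\% prevalence the planning
#' convention is optimistic by roughly a factor four relative to what a
#' population-sampled case-control GWAS actually delivers (see the package
#' vignette).
#'
#' @param nDiscovery discovery sample size (>= 1).
#' @param params a \linkS4class{PowerParams}.
#' @param convention \code{"avengeme"} or \code{"population"}; ignored for
#'   quantitative traits.
#' @return the expected variance explained, a fraction bounded by \code{vg}.
#' @examples
#' p <- powerParams(nSnps = 2000, nCausal = 20)
#' expectedPrsR2(5000, p) < expectedPrsR2(10000, p)  # monotone in n
#' @export
expectedPrsR2 <- function(nDiscovery, params,
                          convention = c("avengeme", "population")) {
  stopifnot(is(params, "PowerParams"))
  convention <- match.arg(convention)
  if (!is.numeric(nDiscovery) || any(nDiscovery < 1))
    stop("nDiscovery must be >= 1")
  K <- params@prevalence
  P <- params@samplePrevalence
  z <- dnorm(qnorm(1 - K))
  if (!params@binaryTrait) {
    neff <- nDiscovery
    out <- 1
  } else if (convention == "avengeme") {
    neff <- nDiscovery
    out <- z^2 * 0.25 / (K * (1 - K))^2
  } else {
    neff <- nDiscovery * z^2 * P * (1 - P) / (K * (1 - K))^2
    out <- 1
  }
  vapply(neff, r2Core, numeric(1), M = params@nSnps, mc = params@nCausal,
         vg = params@vg, pThreshold = params@pThreshold) * out
}

#' Discovery sample size needed for a target PRS accuracy
#'
#' The smallest integer N for which [expectedPrsR2()] reaches
#' \code{targetR2Liab}, found by root-finding on the monotone expected-R2
#' curve (absolute tolerance of one individual).
#'
#' @inheritParams expectedPrsR2
#' @param bracket search interval for N.
#' @return the required discovery sample size (integer-valued numeric).
#' @examples
#' # full-scale architecture, planning convention
#' requiredDiscoveryN(powerParams())
#' @export
requiredDiscoveryN <- function(params,
                               convention = c("avengeme", "population"),
                               bracket = c(1e3, 1e8)) {
  stopifnot(is(params, "PowerParams"))
  convention <- match.arg(convention)
  target <- params@targetR2Liab
  ceilVg <- if (params@binaryTrait && convention == "avengeme") {
    K <- params@prevalence
    params@vg * dnorm(qnorm(1 - K))^2 * 0.25 / (K * (1 - K))^2
  } else params@vg
  if (target <= 0 || target >= ceilVg)
    stop("infeasible target: targetR2Liab must lie in (0, ",
         format(ceilVg), ") for these parameters")
  f <- function(n) expectedPrsR2(n, params, convention) - target
  lo <- bracket[1]; hi <- bracket[2]
  if (f(hi) < 0) stop("target not reachable within the bracket")
  if (f(lo) > 0) return(1)
  root <- uniroot(f, c(lo, hi), tol = 0.5)$root
  n <- floor(root)
  while (expectedPrsR2(n, params, convention) < target) n <- n + 1
  n
}

#' Expected-R2 curve over discovery sample sizes
#'
#' @inheritParams expectedPrsR2
#' @param nValues discovery sample sizes to evaluate.
#' @return a data.frame with columns n_discovery and expected_r2_liab.
#' @export
expectedR2Curve <- function(params, nValues,
                            convention = c("avengeme", "population")) {
  convention <- match.arg(convention)
  data.frame(n_discovery = nValues,
             expected_r2_liab = expectedPrsR2(nValues, params, convention))
}
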