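---
title: "Simulating GWAS of PRS-derived extreme phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GWAS of PRS-derived extreme phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prstail)
```

## The question

A tempting design for boosting GWAS power is to build a polygenic risk score
(PRS) in a target cohort from published disease GWAS weights, declare the top
tail of the score "cases" and the bottom tail "controls", and run a new GWAS
on that derived phenotype. The hope is that enriching for known risk alleles
also enriches for unknown ones. The catch is circularity: the SNPs used to
*construct* the phenotype are afterwards *tested against* it. `prstail`
simulates this design end to end under a fully specified generative model, so
the type-I error consequences can be measured exactly: every SNP is simulated
with a known causal status, so a "false positive" is unambiguous.

## Generative model

Disease liability follows the classical liability threshold model. For
individual $i$ with dosages $d_{ij} \in \{0,1,2\}$ at $M$ independent SNPs,

$$\ell_i = \sum_{j \in \text{causal}} \beta_j
  \frac{d_{ij} - 2p_j}{\sqrt{2p_j(1-p_j)}} + e_i,
  \qquad e_i \sim N(0,\, 1 - h^2),$$

and individual $i$ is a case iff $\ell_i > T$ with
$P(N(0,1) > T) = K$, the population prevalence. Defaults: $M = 170{,}000$
SNPs in linkage equilibrium, $1{,}200$ causal, $h^2 = 0.10$ on the liability
scale, $K = 0.05$, minimum MAF $0.001$.

Choices the model statement leaves open, fixed here once:

* **MAF distribution.** Uniform on $[\mathrm{mafMin}, 0.5]$ — the simplest
  law consistent with a stated minimum; it is a constructor argument of the
  panel, not a hidden constant.
* **Effect sizes.** I.i.d. normal across causal SNPs on the
  standardized-genotype scale, then rescaled so $\sum_j \beta_j^2 = h^2$
  *exactly*. This matches the normal-effects assumption of the analytic power
  model below and pins the heritability deterministically, which makes the
  variance checks in the test suite sharp.
* **Environmental variance.** The theoretical $1 - h^2$ rather than an
  empirical residual fit, so liability has unit variance by construction.
* **Sampling.** Plain population sampling: individuals are simulated until
  the cohort size is reached, so the realized case fraction is a
  Binomial$(n, K)$ draw rather than an exact quota.

Genotypes are stored as one-byte raw dosages (individuals × SNPs) and every
kernel streams SNP column blocks with per-SNP accumulators; no operation
materialises a numeric copy of the genotype matrix.

## Pipeline

One replicate of `runReplicate()`:

1. simulate a discovery cohort and run the **primary GWAS** of disease
   status;
2. build P+T PRS models at inclusion thresholds $p \le \{0.05, 1,
   5\times10^{-8}\}$ (SNPs are independent, so pruning is a no-op and only
   thresholding acts; inclusion uses the closed interval);
3. for each overlap level $\{0, 0.5, 1\}$, build a target cohort sharing
   exactly `round(overlap * nTarget)` individuals with discovery
   (bit-identical genotypes and liabilities), score it with raw-dosage
   weighted sums, keep the top and bottom 5% of the score as the **derived
   phenotype** (ties broken by individual id, so runs are deterministic), and
   run the **second GWAS**;
4. record, per (overlap, threshold, $\alpha$): null-SNP false positive rates
   overall and stratified by PRS membership, false-positive counts, Var(Z)
   over null SNPs, the realized liability-scale PRS $R^2$, and the oriented
   Z-difference for causal SNPs excluded from the PRS.

The association engine is a per-SNP OLS regression of the 0/1 phenotype on
allele dosage — equivalent under the null to the Cochran–Armitage trend
test. Its null calibration is exact, and calibration is the quantity under
study; logistic regression would change effect-size scale (the PRS only needs
a monotone weight) but not the null behaviour. Two-sided p-values use the
normal approximation; monomorphic SNPs are reported with $z = 0$, $p = 1$ so
downstream masks stay total. A deliberately broken analysis (duplicated
individuals) is used in the test suite to show the Var(Z) window
$[0.95, 1.05]$ actually rejects a miscalibrated design; note that rescaling
the *environmental* variance alone cannot inflate null-SNP statistics, since
those are calibrated for any phenotype independent of the SNP.

The Z-difference comparison orients both GWAS statistics to the allele with
positive true liability effect; orienting to *estimated* signs would bias the
difference toward zero. The primary-GWAS Z in the comparison is the
discovery-cohort statistic at full $N_1$.

Observed-scale score–status correlations are converted to the liability
scale with the ascertainment-aware transformation of Lee et al. (2012).
With sample prevalence equal to population prevalence — always the case
here — the ascertainment term vanishes and the factor reduces to
$K(1-K)/z^2$, with $z$ the normal density at the threshold.

## The analytic power model and its two conventions

`expectedPrsR2()` implements a Dudbridge-style expectation (the model behind
the avengeme calculator) for the variance a thresholded PRS explains. On the
scale where genotypes are standardized and the discovery estimate of SNP $j$
has error variance $1/n_\mathrm{eff}$, with per-causal-SNP effect variance
$\sigma^2 = v_g/m_c$ and inclusion when $|\hat\beta_j| > c$,

$$R^2 = \frac{C^2}{V}, \qquad
  V = m_c\,T(\sigma^2 + v) + (M - m_c)\,T(v), \qquad
  C = m_c\,\frac{\sigma^2}{\sigma^2 + v}\,T(\sigma^2 + v),$$

where $v = 1/n_\mathrm{eff}$ and
$T(s^2) = s^2 \cdot 2\,(u\,\phi(u) + 1 - \Phi(u))$, $u = c/s$, is the
truncated second moment of the marginal $N(0, s^2)$ distribution of
$\hat\beta$. The test suite validates the closed form against numerical
integration and, more importantly, against full simulated pipelines.

For binary traits the effective sample size is a convention, and two are
provided:

* **`"population"`** — faithful to this package's simulator: a population
  sample at prevalence $K$ analysed by 0/1-on-dosage regression has
  $n_\mathrm{eff} = n\,z^2 / (K(1-K))$ (about $0.224\,n$ at $K = 0.05$), and
  $R^2$ is reported on the liability scale. Fifty-replicate simulations at a
  2,000-SNP architecture recover this expectation within Monte-Carlo error
  (see `test-power_calc.R`), as does the desk-scale experiment.
* **`"avengeme"`** (default for `requiredDiscoveryN()`) — the sample-size
  planning convention in published applications of the avengeme calculator
  to case-control designs: quantitative-trait non-centrality
  ($n_\mathrm{eff} = n$) with the score $R^2$ reported on the observed scale
  of a balanced case-control target, i.e. multiplied by
  $z^2/4 / (K(1-K))^2 \approx 1.18$ at $K = 0.05$. Under this convention the
  full-scale architecture requires $N_1 = 366{,}723$ for a 5% score $R^2$,
  which is the kind of cohort size quoted for such designs.

The conventions differ materially, and this is a finding worth stating
plainly: at $K = 0.05$ the planning convention is optimistic by roughly a
factor of four in $R^2$. A discovery cohort sized by the planning convention
for a "5%" PRS delivers, in the population-sampled simulation it is used
for, a liability-scale $R^2$ of about 0.0125 — both by the population-mode
formula and by the realized $R^2$ the experiment measures (acceptance
criterion on parameter recovery). None of the qualitative inflation results
depend on this: they concern null SNPs, whose behaviour is driven by the
selection-and-retest circularity, not by the score's accuracy.

## Desk preset and problem sizes

`deskConfig()` keeps the full design's causal density and prevalence but
scales the architecture to one CPU: 20,000 SNPs (141 causal), discovery size
solved by the same planning convention used at full scale (43,141), target
cohorts of 40,000, tails of 5%, 20 replicates. A replicate takes roughly half
a minute; the whole experiment runs in about ten minutes and gives ~1,000
in-PRS null SNPs per replicate at the 0.05 threshold, enough to see the
stratified rates clearly. The full preset (`fullConfig()`) is constructible
and documented but is a cluster-scale computation (one replicate streams
~6×10^10 genotype draws); nothing in the test suite runs it.

At the genome-wide PRS threshold ($5\times10^{-8}$) the desk-scale PRS is
empty in most replicates (the expected count of passing causal SNPs is below
one): such replicates report NA metrics with a `degenerate` flag rather than
failing, and aggregation counts contributing replicates per cell.

## Numerical and degenerate-input choices

* Inclusion uses $p \le$ threshold (closed); `fpr()` uses strict $<$.
* Tail ties are broken by ascending individual id; with a one-SNP score the
  derived phenotype is then a deterministic function of genotype class.
* Root-finding for the required $N$ brackets $[10^3, 10^8]$ and returns the
  smallest integer whose expected $R^2$ reaches the target.
* `gwas()` needs at least 3 individuals (residual degree of freedom) and a
  non-constant phenotype; monomorphic columns degrade to $z=0$, $p=1$.
* All randomness flows from `masterSeed` through per-(replicate, purpose)
  child seeds; the genotype stream itself is a fast xoshiro256+ generator
  seeded from R's RNG, so `set.seed()` governs every draw and replicates are
  bit-for-bit reproducible.

## What the simulator does not emulate

No linkage disequilibrium (so "pruning+thresholding" is purely
thresholding — in real data, null SNPs in LD with included SNPs would also
inflate), no chromosomes or physical positions, no major-effect loci, no
genotyping error, relatedness or population stratification, and no covariate
structure. Passing tests therefore demonstrate the circularity mechanism and
the calibration of the engine on this idealised architecture; they do not
quantify how LD or confounding would modulate the inflation in real cohorts.
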