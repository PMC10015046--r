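# prstail

Forward simulation of genome-wide association studies (GWAS) run on
**polygenic-risk-score-derived extreme phenotypes**, for statistical
geneticists who want to quantify the type-I error cost of that design.

## The problem

Take published GWAS effect estimates, build a pruning-and-thresholding (P+T)
polygenic risk score (PRS) in a target cohort, call the top 5% of the score
distribution "cases" and the bottom 5% "controls", discard the middle 90%,
and run a second GWAS on this derived phenotype. The design looks like a
power boost, but it is circular: the SNPs used to construct the phenotype are
subsequently tested for association with it. `prstail` measures what that
circularity does to the false positive rate, under a generative model where
every SNP's causal status is known.

The simulator uses the liability threshold model: individual liability

    l_i = sum_j beta_j * (d_ij - 2 p_j) / sqrt(2 p_j (1 - p_j)) + e_i,
    e_i ~ N(0, 1 - h2),   case  <=>  l_i > T,   P(N(0,1) > T) = K

with M = 170,000 independent SNPs (1,200 causal), liability-scale
SNP-heritability h2 = 0.10 and prevalence K = 0.05 at full scale. Per-SNP
association testing is an allele-dosage trend test (OLS of the 0/1 phenotype
on dosage, equivalent under the null to Cochran–Armitage); PRS scoring,
extreme-tail phenotype derivation, discovery/target sample overlap, and
stratified false-positive metrics are built in. A Dudbridge-style analytic
model (`expectedPrsR2`, `requiredDiscoveryN`) solves discovery cohort sizes
for a target PRS accuracy; see `vignette("prs-derived-phenotypes")` for the
model, its two binary-trait conventions, and every design decision.

## Worked example

A reduced architecture (5,000 SNPs, 35 causal, 5 replicates) that runs in
about a minute:

```r
library(prstail)

cfg <- simConfig(nSnps = 5000, nCausal = 35, nDiscovery = 12000,
                 nTarget = 10000, nReps = 5, masterSeed = 42)
res <- runExperiment(cfg, verbose = FALSE)
agg <- res$aggregate

# overall null-SNP false positive rate at genome-wide significance (5e-8),
# PRS inclusion threshold p <= 0.05, by discovery/target overlap:
agg[agg$metric == "fpr_all_null" & agg$alpha == 5e-8 &
    agg$prs_threshold == 0.05, c("overlap", "mean", "sem", "n_reps")]
#>  overlap    mean      sem n_reps
#>      0.0 0.00375 0.000164      5
#>      0.5 0.00387 0.000599      5
#>      1.0 0.00540 0.000503      5
```

A calibrated GWAS would show 5e-8 here; the derived-phenotype GWAS shows
~4e-3 — a five-orders-of-magnitude inflation, growing with sample overlap.
Stratifying the null SNPs shows the inflation comes entirely from SNPs that
were used to construct the phenotype:

```r
agg[agg$metric %in% c("fpr_null_in_prs", "fpr_null_out_prs") &
    agg$alpha == 5e-8 & agg$prs_threshold == 0.05 & agg$overlap == 0,
    c("metric", "mean", "sem")]
#>            metric   mean     sem
#>   fpr_null_in_prs 0.0765 0.00432
#>  fpr_null_out_prs 0.0000 0.00000
```

The analytic sample-size solver for the full-scale design:

```r
requiredDiscoveryN(powerParams())
#> [1] 366723
```

`deskConfig()` is a single-CPU preset of the full design (20,000 SNPs, 20
replicates, ~10 minutes) used by the acceptance tests; `fullConfig()` is the
cluster-scale design itself. A thin command-line wrapper with `run`, `power`
and `check` subcommands lives at `inst/scripts/prstail-cli.R`.

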