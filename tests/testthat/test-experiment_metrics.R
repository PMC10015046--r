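test_that("fpr counts strictly-significant masked SNPs", {
  expect_identical(fpr(c(0.1, 0.2, 0.3), rep(TRUE, 3), 0.05), 0)
  expect_identical(fpr(c(1e-9, 0.03, 0.9, 0.04), rep(TRUE, 4), 0.05), 0.75)
  expect_error(fpr(c(0.1, 0.2), rep(FALSE, 2), 0.05), "no SNPs")
  set.seed(41)
  p <- runif(10000)
  expect_lt(abs(fpr(p, rep(TRUE, 1e4), 0.05) - 0.05),
            4 * sqrt(0.05 * 0.95 / 1e4))
})

test_that("replicate summaries give mean, s.e.m. and the 99.9% CI", {
  s <- replicateSummary(c(0.1, 0.1, 0.1))
  expect_equal(s$mean, 0.1)
  expect_equal(s$sem, 0)
  s2 <- replicateSummary(c(0, 0.2))
  expect_equal(s2$mean, 0.1)
  expect_equal(s2$sem, 0.1) # sd = 0.1414.. / sqrt(2)
  expect_equal(s2$ci[2] - s2$mean, qnorm(0.9995) * 0.1)
  expect_true(s2$ci[1] <= s2$mean && s2$mean <= s2$ci[2])
  s3 <- replicateSummary(5)
  expect_equal(s3$mean, 5)
  expect_true(is.na(s3$sem))
  expect_error(replicateSummary(NA_real_), "no replicate")
})

test_that("z-difference orients to the risk allele and matches hand arithmetic", {
  mk <- function(z) new("GwasResult", beta = z, se = rep(1, 4), z = z,
                        p = 2 * pnorm(-abs(z)), polymorphic = rep(TRUE, 4),
                        n = 10)
  panel <- new("SnpPanel", maf = rep(0.3, 4),
               isCausal = c(TRUE, TRUE, TRUE, FALSE),
               betaTrue = c(0.1, -0.2, 0.3, 0))
  model <- new("PrsModel", included = c(FALSE, FALSE, TRUE, TRUE),
               weights = c(0, 0, 1, 1), threshold = 0.05)
  g1 <- mk(c(2, -1, 5, 0))
  # identical GWASs give a zero mean difference
  zd0 <- zdiffCausalExcluded(g1, g1, panel, model)
  expect_equal(zd0$meanDiff, 0)
  expect_equal(zd0$n, 2)
  # hand-computed: excluded causal SNPs 1 and 2, signs +1 and -1
  g2 <- mk(c(1, 1, 5, 0))
  # oriented diffs: (1-2)*1 = -1 ; (1-(-1))*(-1) = -2 ; mean -1.5
  expect_equal(zdiffCausalExcluded(g2, g1, panel, model)$meanDiff, -1.5)
  noneLeft <- new("PrsModel", included = c(TRUE, TRUE, TRUE, FALSE),
                  weights = c(1, 1, 1, 0), threshold = 0.05)
  expect_error(zdiffCausalExcluded(g2, g1, panel, noneLeft), "no causal")
})

test_that("replicate metrics conserve false-positive counts across strata", {
  cfg <- tinyConfig()
  r <- runReplicate(cfg, 1)
  nNull <- getParam(cfg, "nSnps") - getParam(cfg, "nCausal")
  # strata only partition the nulls when both strata are non-empty
  ok <- !r$degenerate & r$n_null_in_prs > 0 & r$n_null_in_prs < nNull
  lhs <- r$fpr_all_null[ok] * nNull
  rhs <- r$fpr_null_in_prs[ok] * r$n_null_in_prs[ok] +
    r$fpr_null_out_prs[ok] * (nNull - r$n_null_in_prs[ok])
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(r$n_false_pos[ok], lhs, tolerance = 1e-9)
  # one row per (overlap, threshold, alpha)
  expect_equal(nrow(r), 3 * 3 * 3)
})

test_that("an empty PRS is reported as a degenerate outcome, not an error", {
  cfg <- tinyConfig(nCausal = 0, h2Liab = 0, prsThresholds = 5e-8,
                    alphas = 0.05)
  r <- runReplicate(cfg, 1)
  expect_true(all(r$degenerate))
  expect_true(all(is.na(r$fpr_all_null)))
  agg <- aggregateReplicates(rbind(r, runReplicate(cfg, 2)))
  expect_true(all(agg$n_reps[agg$metric == "fpr_all_null"] %in% c(0, 1, 2)))
})

test_that("aggregation matches replicateSummary per cell", {
  cfg <- tinyConfig()
  reps <- rbind(runReplicate(cfg, 1), runReplicate(cfg, 2))
  agg <- aggregateReplicates(reps)
  cell <- reps$overlap == 0.5 & reps$prs_threshold == 0.05 &
    reps$alpha == 0.05
  ref <- replicateSummary(reps$fpr_all_null[cell])
  row <- agg[agg$overlap == 0.5 & agg$prs_threshold == 0.05 &
               agg$alpha == 0.05 & agg$metric == "fpr_all_null", ]
  expect_equal(row$mean, ref$mean)
  expect_equal(row$sem, ref$sem)
  expect_equal(c(row$ci_lo, row$ci_hi), ref$ci)
})

test_that("the pipeline is reproducible bit-for-bit from the master seed", {
  cfg <- tinyConfig()
  r1 <- runReplicate(cfg, 1)
  r2 <- runReplicate(cfg, 1)
  expect_identical(r1, r2)
  # and replicates differ from each other
  expect_false(identical(r1$fpr_all_null, runReplicate(cfg, 2)$fpr_all_null))
})

test_that("the primary GWAS passes its calibration check", {
  cfg <- smallConfig(nDiscovery = 20000)
  chk <- modelCheckPrimary(cfg)
  expect_true(chk$pass)
  expect_gt(chk$varZ, 0.95); expect_lt(chk$varZ, 1.05)
  # global-null variant passes too
  chk0 <- modelCheckPrimary(tinyConfig(nCausal = 0, h2Liab = 0,
                                       nDiscovery = 10000))
  expect_true(chk0$pass)
})

test_that("a deliberately broken design is caught by Var(Z)", {
  # duplicating every individual pretends to double the sample size, which
  # inflates null test statistics by a factor ~2 in variance; the Var(Z)
  # window [0.95, 1.05] must flag it while the honest analysis passes
  cfg <- smallConfig(nDiscovery = 8000)
  set.seed(43)
  p <- drawPanel(cfg)
  sim <- simulateCohort(p, 8000, cfg)
  y <- as.numeric(status(sim))
  dup <- rep(seq_len(8000), 2)
  resBad <- gwas(sim, y[dup], rows = dup)
  expect_gt(genomicInflation(resBad, !isCausal(p))$varZ, 1.5)
  resOk <- gwas(sim, y)
  vz <- genomicInflation(resOk, !isCausal(p))$varZ
  expect_gt(vz, 0.95); expect_lt(vz, 1.05)
})

test_that("runExperiment aggregates across replicates deterministically", {
  cfg <- tinyConfig()
  e1 <- runExperiment(cfg, verbose = FALSE)
  e2 <- runExperiment(cfg, verbose = FALSE)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$aggregate, e2$aggregate)
  expect_equal(sort(unique(e1$replicates$rep)), 1:2)
  f <- tempfile(fileext = ".tsv")
  writeMetricsTsv(e1$aggregate, f)
  expect_identical(nrow(read.table(f, header = TRUE, sep = "\t")),
                   nrow(e1$aggregate))
  unlink(f)
})
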