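mkGwas <- function(p, beta = rep(1, length(p)), poly = rep(TRUE, length(p))) {
  z <- qnorm(p / 2, lower.tail = FALSE) * sign(beta)
  new("GwasResult", beta = beta, se = rep(1, length(p)), z = z, p = p,
      polymorphic = poly, n = 100)
}

test_that("SNP selection respects the closed threshold and polymorphism", {
  g <- mkGwas(c(0.05, 0.051, 1e-9, 0.5, 1), beta = c(1, 2, -3, 4, 0),
              poly = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- selectSnps(g, 0.05)
  expect_identical(included(m), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(prsWeights(m), c(1, 0, -3, 0, 0))
  # threshold 1 includes every polymorphic SNP, never monomorphic ones
  m1 <- selectSnps(g, 1)
  expect_identical(included(m1), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # nesting: raising the threshold never removes SNPs
  for (pair in list(c(1e-10, 0.05), c(0.05, 0.5), c(0.5, 1))) {
    a <- selectSnps(g, pair[1]); b <- selectSnps(g, pair[2])
    expect_true(all(!included(a) | included(b)))
  }
  expect_error(selectSnps(g, 0), "0, 1")
  expect_error(selectSnps(g, 1.5), "0, 1")
})

test_that("null p-values enter the PRS at the threshold rate", {
  cfg <- simConfig(nSnps = 10000, nCausal = 0, h2Liab = 0, nDiscovery = 4000,
                   nTarget = 1000, masterSeed = 2)
  set.seed(31)
  p <- drawPanel(cfg)
  co <- simulateCohort(p, 4000, cfg)
  g <- gwas(co, as.numeric(status(co)))
  m <- selectSnps(g, 0.05)
  frac <- mean(included(m))
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 10000))
})

test_that("scoring is a weighted dosage sum, linear and order-equivariant", {
  dm <- matrix(c(0L, 1L, 2L,
                 2L, 0L, 1L,
                 1L, 1L, 0L), nrow = 3, byrow = TRUE)
  dos <- rawDosages(dm)
  w1 <- c(0.5, 0, -1); w2 <- c(0, 2, 0)
  mk <- function(w) new("PrsModel", included = w != 0, weights = w, threshold = 1)
  # brute-force sums
  expect_equal(scoreCohort(mk(w1), dos), drop(dm %*% w1))
  expect_equal(scoreCohort(mk(w2), dos), drop(dm %*% w2))
  # single included SNP with weight 1 returns that SNP's dosages
  expect_equal(scoreCohort(mk(c(0, 1, 0)), dos), as.numeric(dm[, 2]))
  # linearity in the weights
  expect_equal(scoreCohort(mk(w1 + w2), dos),
               scoreCohort(mk(w1), dos) + scoreCohort(mk(w2), dos))
  # permuting individuals permutes scores identically
  perm <- c(3, 1, 2)
  expect_equal(scoreCohort(mk(w1), rawDosages(dm[perm, ])),
               scoreCohort(mk(w1), dos)[perm])
  empty <- new("PrsModel", included = rep(FALSE, 3), weights = rep(0, 3),
               threshold = 1e-30)
  expect_error(scoreCohort(empty, dos), "empty")
})

test_that("extreme-tail phenotype keeps exactly the two balanced tails", {
  d <- deriveExtremePhenotype(1:20, 1:20, 0.1)
  expect_identical(ids(d), c(1L, 2L, 19L, 20L))
  expect_identical(status(d), c(FALSE, FALSE, TRUE, TRUE))

  n <- 300
  set.seed(32)
  sc <- rnorm(n)
  d2 <- deriveExtremePhenotype(sc, seq_len(n), 0.05)
  k <- round(0.05 * n)
  expect_equal(length(ids(d2)), 2 * k)
  expect_equal(sum(status(d2)), k)
  expect_true(min(d2@scores[d2@status]) >= max(sc[!seq_len(n) %in% ids(d2)]))

  # median split retains everyone
  d3 <- deriveExtremePhenotype(sc, seq_len(n), 0.5)
  expect_equal(length(ids(d3)), n)

  # deterministic id tie-break on constant scores
  d4 <- deriveExtremePhenotype(rep(1, 10), 10:1, 0.2)
  expect_identical(sort(ids(d4)[!status(d4)]), c(1L, 2L))
  expect_identical(sort(ids(d4)[status(d4)]), c(9L, 10L))

  expect_error(deriveExtremePhenotype(1:5, 1:5, 0.05), "insufficient")
})

test_that("liability-scale conversion recovers a known latent R2", {
  # latent-model oracle: liability = sqrt(r2)*S + sqrt(1-r2)*e with S the
  # (standardized) score, so the score explains exactly r2 of liability.
  set.seed(33)
  n <- 400000
  r2 <- 0.05; K <- 0.05
  S <- rnorm(n)
  L <- sqrt(r2) * S + sqrt(1 - r2) * rnorm(n)
  y <- L > liabilityThreshold(K)
  est <- liabilityR2(S, y, K)
  expect_lt(abs(est - r2) / r2, 0.10)
  # with P == K the ascertainment term vanishes: equals the simple conversion
  z <- dnorm(qnorm(1 - K))
  expect_equal(est, cor(S, as.numeric(y))^2 * K * (1 - K) / z^2,
               tolerance = 1e-12)
  # independent scores explain ~nothing
  expect_lt(liabilityR2(rnorm(n), y, K), 5e-4)
  expect_error(liabilityR2(S, rep(TRUE, n), K), "single class")
  expect_error(liabilityR2(rep(1, n), y, K), "constant")
})

test_that("ascertained conversion matches an independently coded formula", {
  # oracle: re-derive the Lee et al. conversion factor numerically from K, P
  # and the normal density at the threshold
  K <- 0.05; P <- 0.3
  t <- qnorm(1 - K); z <- dnorm(t); i <- z / K
  set.seed(34)
  S <- rnorm(5000); y <- rbinom(5000, 1, plogis(S)) # arbitrary joint draw
  r2o <- cor(S, y)^2
  Cfac <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  theta <- i * ((P - K) / (1 - K)) * (i * (P - K) / (1 - K) - t)
  expect_equal(liabilityR2(S, y, K, P), Cfac * r2o / (1 + Cfac * theta * r2o),
               tolerance = 1e-12)
})

test_that("PRS writers emit readable TSV", {
  w <- c(0.5, 0, -1)
  m <- new("PrsModel", included = w != 0, weights = w, threshold = 0.05)
  f <- tempfile(fileext = ".tsv")
  writePrsModelTsv(m, f)
  d <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(d$weight, w)
  sc <- c(3, 1, 2); idv <- c(10L, 20L, 30L)
  dp <- deriveExtremePhenotype(sc, idv, 0.34)
  writeScoresTsv(sc, idv, f, derived = dp)
  d2 <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(d2$derived_status, c(1L, 0L, NA_integer_))
  unlink(f)
})
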