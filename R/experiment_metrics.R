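#' False positive rate over a SNP mask
#'
#' Fraction of masked SNPs with p-value strictly below alpha.
#'
#' @param pvalues per-SNP p-values.
#' @param mask per-SNP flag selecting which SNPs count (at least one).
#' @param alpha significance threshold.
#' @return a fraction.
#' @examples
#' fpr(c(1e-9, 0.03, 0.9, 0.04), rep(TRUE, 4), 0.05)  # 0.75
#' @export
fpr <- function(pvalues, mask, alpha) {
  mask <- as.logical(mask)
  if (length(mask) != length(pvalues)) stop("mask length must match pvalues")
  if (!any(mask)) stop("the mask selects no SNPs")
  mean(pvalues[mask] < alpha)
}

#' Z-difference for causal SNPs excluded from the PRS
#'
#' For causal SNPs that did not enter the PRS, both GWAS Z statistics are
#' oriented to the allele that increases true liability, and the mean
#' difference Z_second - Z_primary is computed with a one-sample t-test
#' against zero. A negative mean is a power loss in the tail-phenotype GWAS
#' relative to the primary GWAS.
#'
#' @param secondGwas,primaryGwas \linkS4class{GwasResult} objects for the
#'   derived-phenotype and primary GWAS.
#' @param panel the \linkS4class{SnpPanel} (true effects give orientation).
#' @param model the \linkS4class{PrsModel} defining exclusion.
#' @return a list with meanDiff, p (NA when fewer than 2 SNPs) and n.
#' @export
zdiffCausalExcluded <- function(secondGwas, primaryGwas, panel, model) {
  stopifnot(is(secondGwas, "GwasResult"), is(primaryGwas, "GwasResult"),
            is(panel, "SnpPanel"), is(model, "PrsModel"))
  mask <- panel@isCausal & !model@included
  if (!any(mask)) stop("no causal SNPs are excluded from the PRS")
  s <- sign(panel@betaTrue[mask])
  d <- secondGwas@z[mask] * s - primaryGwas@z[mask] * s
  p <- if (length(d) >= 2 && sd(d) > 0) t.test(d)$p.value else NA_real_
  list(meanDiff = mean(d), p = p, n = length(d))
}

#' Run one simulation replicate
#'
#' One discovery cohort is simulated and GWAS'd once; for each overlap level
#' a target cohort is built (sharing individuals with discovery as required),
#' scored with each PRS threshold in a single genotype sweep, tail-selected,
#' and the second GWAS run. Metrics are recorded per (overlap, PRS threshold,
#' alpha). All randomness derives from the configuration's master seed and
#' the replicate index, so replicates are independently reproducible.
#'
#' A PRS threshold that includes no SNP (possible at genome-wide-significant
#' cutoffs) yields rows with NA metrics and \code{degenerate = TRUE} rather
#' than an error.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param repIndex replicate number (1-based).
#' @param verbose emit a progress message.
#' @return a data.frame of per-(overlap, threshold, alpha) replicate metrics:
#'   stratified null-SNP false positive rates, false-positive counts, Var(Z)
#'   over null SNPs, the mean oriented Z-difference for causal SNPs excluded
#'   from the PRS, the count of null SNPs in the PRS, and the realized
#'   liability-scale PRS R2 in the target cohort.
#' @export
runReplicate <- function(config, repIndex, verbose = FALSE) {
  stopifnot(is(config, "SimConfig"))
  ms <- config@masterSeed
  set.seed(childSeed(ms, repIndex, "panel"))
  panel <- drawPanel(config)
  nullMask <- !panel@isCausal
  nNull <- sum(nullMask)

  set.seed(childSeed(ms, repIndex, "discovery"))
  discovery <- simulateCohort(panel, config@nDiscovery, config)
  primary <- gwas(discovery, as.numeric(discovery@status),
                  blockSize = config@blockSize)
  models <- lapply(config@prsThresholds, function(th) selectSnps(primary, th))

  out <- list()
  for (oi in seq_along(config@overlaps)) {
    o <- config@overlaps[oi]
    set.seed(childSeed(ms, repIndex, paste0("target", oi)))
    target <- makeTargetWithOverlap(
      discovery, o, config@nTarget, panel, config,
      idStart = as.integer(config@nDiscovery) + 1L +
        (oi - 1L) * as.integer(config@nTarget))
    scores <- scoreCohortMulti(models, target)
    for (ti in seq_along(models)) {
      model <- models[[ti]]
      th <- config@prsThresholds[ti]
      base <- data.frame(rep = repIndex, overlap = o, prs_threshold = th,
                         alpha = config@alphas)
      if (!any(model@included)) {
        base$fpr_all_null <- NA_real_; base$fpr_null_in_prs <- NA_real_
        base$fpr_null_out_prs <- NA_real_; base$n_false_pos <- NA_real_
        base$var_z_null <- NA_real_
        base$mean_zdiff_causal_excluded <- NA_real_
        base$zdiff_p <- NA_real_
        base$n_null_in_prs <- 0L
        base$realized_prs_r2_liab <- NA_real_
        base$degenerate <- TRUE
        out[[length(out) + 1L]] <- base
        next
      }
      dp <- deriveExtremePhenotype(scores[, ti], target@ids,
                                   config@extremeFraction)
      rows <- match(dp@selectedIds, target@ids)
      second <- gwas(target, as.numeric(dp@status), rows = rows,
                     blockSize = config@blockSize)
      inPrs <- nullMask & model@included
      outPrs <- nullMask & !model@included
      zd <- if (any(panel@isCausal & !model@included))
        zdiffCausalExcluded(second, primary, panel, model)
      else list(meanDiff = NA_real_, p = NA_real_, n = 0L)
      r2l <- liabilityR2(scores[, ti], target@status, config@prevalence,
                         config@samplePrevalence)
      base$fpr_all_null <- vapply(config@alphas, function(a)
        fpr(second@p, nullMask, a), numeric(1))
      base$fpr_null_in_prs <- vapply(config@alphas, function(a)
        if (any(inPrs)) fpr(second@p, inPrs, a) else NA_real_, numeric(1))
      base$fpr_null_out_prs <- vapply(config@alphas, function(a)
        if (any(outPrs)) fpr(second@p, outPrs, a) else NA_real_, numeric(1))
      base$n_false_pos <- base$fpr_all_null * nNull
      base$var_z_null <- var(second@z[nullMask])
      base$mean_zdiff_causal_excluded <- zd$meanDiff
      base$zdiff_p <- zd$p
      base$n_null_in_prs <- sum(inPrs)
      base$realized_prs_r2_liab <- r2l
      base$degenerate <- FALSE
      out[[length(out) + 1L]] <- base
    }
    rm(target, scores)
  }
  if (verbose)
    message(sprintf("replicate %d done (%s)", repIndex, format(Sys.time())))
  do.call(rbind, out)
}

#' Summarise a vector of per-replicate values
#'
#' Mean, standard error of the mean (sample SD over the square root of the
#' replicate count) and the 99.9\% normal-approximation confidence interval
#' of the mean. With a single replicate the s.e.m. is undefined (NA).
#'
#' @param x per-replicate values; NA entries (degenerate replicates) are
#'   dropped.
#' @return a list with mean, sem, ci (length 2) and n.
#' @examples
#' replicateSummary(c(0, 0.2))  # mean 0.1, sem 0.1
#' @export
replicateSummary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("no replicate values")
  m <- mean(x)
  sem <- if (n >= 2) sd(x) / sqrt(n) else NA_real_
  half <- qnorm(0.9995) * sem
  list(mean = m, sem = sem, ci = c(m - half, m + half), n = n)
}

#' Aggregate replicate metrics
#'
#' Per (overlap, PRS threshold, alpha) cell and per metric: mean over
#' replicates, s.e.m. and the 99.9\% confidence interval of the mean.
#' Degenerate replicates (empty PRS) are excluded cell-wise; \code{n_reps}
#' reports how many replicates contributed.
#'
#' @param replicates the row-bound output of [runReplicate()].
#' @return a long-format data.frame with columns overlap, prs_threshold,
#'   alpha, metric, mean, sem, ci_lo, ci_hi, n_reps.
#' @export
aggregateReplicates <- function(replicates) {
  metrics <- c("fpr_all_null", "fpr_null_in_prs", "fpr_null_out_prs",
               "n_false_pos", "var_z_null", "mean_zdiff_causal_excluded",
               "n_null_in_prs", "realized_prs_r2_liab")
  if (nrow(replicates) == 0) stop("no replicates to aggregate")
  key <- interaction(replicates$overlap, replicates$prs_threshold,
                     replicates$alpha, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(replicates)), key), function(idx) {
    sub <- replicates[idx, ]
    do.call(rbind, lapply(metrics, function(mt) {
      x <- sub[[mt]]
      if (all(is.na(x)))
        return(data.frame(overlap = sub$overlap[1],
                          prs_threshold = sub$prs_threshold[1],
                          alpha = sub$alpha[1], metric = mt,
                          mean = NA_real_, sem = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, n_reps = 0L))
      s <- replicateSummary(x)
      data.frame(overlap = sub$overlap[1],
                 prs_threshold = sub$prs_threshold[1],
                 alpha = sub$alpha[1], metric = mt, mean = s$mean,
                 sem = s$sem, ci_lo = s$ci[1], ci_hi = s$ci[2], n_reps = s$n)
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$overlap, res$prs_threshold, res$alpha, res$metric), ]
}

#' Calibration check of the primary GWAS
#'
#' Simulates one panel and discovery cohort, runs the primary case-control
#' GWAS only, and reports the null-SNP false positive rate at each alpha, the
#' variance of null Z statistics and the genomic inflation factor. The check
#' passes when every FPR lies within 4 binomial standard deviations of its
#' alpha and Var(Z) lies in [0.95, 1.05] — i.e. the primary GWAS itself is
#' not inflated, so any inflation seen downstream is attributable to the
#' derived phenotype.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param repIndex replicate index used for seed derivation.
#' @return a list: \code{table} (data.frame of alpha, fpr, tolerance, pass),
#'   \code{varZ}, \code{lambda}, \code{nNull} and overall \code{pass}.
#' @export
modelCheckPrimary <- function(config, repIndex = 1L) {
  stopifnot(is(config, "SimConfig"))
  set.seed(childSeed(config@masterSeed, repIndex, "panel"))
  panel <- drawPanel(config)
  set.seed(childSeed(config@masterSeed, repIndex, "discovery"))
  discovery <- simulateCohort(panel, config@nDiscovery, config)
  res <- gwas(discovery, as.numeric(discovery@status),
              blockSize = config@blockSize)
  nullMask <- !panel@isCausal
  nNull <- sum(nullMask)
  infl <- genomicInflation(res, nullMask)
  tab <- do.call(rbind, lapply(config@alphas, function(a) {
    f <- fpr(res@p, nullMask, a)
    tol <- 4 * sqrt(a * (1 - a) / nNull)
    data.frame(alpha = a, fpr = f, tolerance = tol, pass = abs(f - a) <= tol)
  }))
  varOk <- infl$varZ >= 0.95 && infl$varZ <= 1.05
  list(table = tab, varZ = infl$varZ, lambda = infl$lambda, nNull = nNull,
       pass = all(tab$pass) && varOk)
}

#' Run the full replicated experiment
#'
#' Executes [runReplicate()] for every replicate in the configuration and
#' aggregates the metrics.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param verbose emit one progress message per replicate.
#' @return a list with \code{replicates} (per-replicate long data.frame),
#'   \code{aggregate} (from [aggregateReplicates()]) and \code{config}.
#' @export
runExperiment <- function(config, verbose = TRUE) {
  stopifnot(is(config, "SimConfig"))
  reps <- do.call(rbind, lapply(seq_len(as.integer(config@nReps)),
                                function(r) runReplicate(config, r, verbose)))
  list(replicates = reps, aggregate = aggregateReplicates(reps),
       config = config)
}

#' Write experiment tables as TSV
#'
#' @param x a data.frame (per-replicate or aggregate metrics).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMetricsTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bar plot of false positive rates by overlap
#'
#' A plain barplot of a metric's replicate mean per overlap level at one
#' significance threshold and PRS threshold, with 99.9\% confidence-interval
#' error bars.
#'
#' @param agg aggregate table from [aggregateReplicates()].
#' @param metric which metric to plot.
#' @param alpha,prsThreshold the cell to display.
#' @param ... passed to [graphics::barplot()].
#' @return the barplot midpoints, invisibly.
#' @export
plotFprBars <- function(agg, metric = "fpr_all_null", alpha = 5e-8,
                        prsThreshold = 0.05, ...) {
  sub <- agg[agg$metric == metric &
               abs(agg$alpha - alpha) < 1e-12 &
               abs(agg$prs_threshold - prsThreshold) < 1e-12, ]
  if (nrow(sub) == 0) stop("no aggregate rows match the requested cell")
  sub <- sub[order(sub$overlap), ]
  mid <- graphics::barplot(sub$mean, names.arg = paste0(100 * sub$overlap, "%"),
                           xlab = "sample overlap", ylab = metric,
                           ylim = c(0, max(sub$ci_hi, sub$mean) * 1.15), ...)
  graphics::arrows(mid, sub$ci_lo, mid, sub$ci_hi, angle = 90, code = 3,
                   length = 0.05)
  invisible(mid)
}
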