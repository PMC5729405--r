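#' Calibration and power studies on synthetic cohorts
#'
#' These functions run the full analysis on replicate simulated cohorts with
#' known ground truth and summarize operating characteristics: the
#' false-discovery rate of the two-level FDR + pruning pipeline under a
#' global null, the recovery rate of a 1-SD cis effect, REML heritability
#' recovery, and the calibration and power of the ASE caller. They are the
#' package's own evidence that the pipeline behaves as designed, and the
#' basis of the acceptance checks.
#'
#' @name calibrationStudies
NULL

#' @describeIn calibrationStudies Empirical FDR of the eGWAS pipeline under
#'   a global null (no true effects). Each cohort is analyzed with
#'   \code{runEgwas}, \code{twoLevelFdr} and \code{pruneToEqtlSnps}; under
#'   the null every surviving association is false, so the per-cohort false
#'   discovery proportion is 1 whenever anything survives and the empirical
#'   FDR is the mean of those proportions across cohorts.
#'
#' @param nCohorts number of replicate cohorts.
#' @param nSires,progenyPerSire cohort family structure.
#' @param nSnps,nProbes cohort dimensions.
#' @param h2 polygenic heritability of the simulated probes.
#' @param alpha nominal FDR level for both BH passes.
#' @param seed base seed; cohort r uses seed + r.
#' @return List with \code{fdr} (mean false-discovery proportion),
#'   \code{nRejections} (per-cohort surviving association counts).
#' @export
egwasNullFdrStudy <- function(nCohorts = 200, nSires = 6, progenyPerSire = 25,
                              nSnps = 200, nProbes = 50, h2 = 0.3,
                              alpha = 0.05, seed = 1L) {
  nRej <- integer(nCohorts)
  for (r in seq_len(nCohorts)) {
    cfg <- simConfig(nSires = nSires, progenyPerSire = progenyPerSire,
                     nSnps = nSnps, nProbes = nProbes, h2Polygenic = h2,
                     nCisEffects = 0, nTransEffects = 0,
                     nNegativeControlProbes = 0, seed = seed + r)
    co <- simulateCohort(cfg)
    eg <- twoLevelFdr(runEgwas(co$expr, co$geno),
                      alphaProbe = alpha, alphaGlobal = alpha)
    eqtl <- pruneToEqtlSnps(eg)
    nRej[r] <- nrow(eqtl)
  }
  list(fdr = mean(nRej > 0), nRejections = nRej)
}

#' @describeIn calibrationStudies Recovery of a single cis effect of
#'   \code{beta} phenotype SDs. Per seed, a cohort with one cis-regulated
#'   probe is simulated and analyzed end to end; success requires the cis
#'   probe to carry a significant association whose lead eQTL-SNP is
#'   classified local. Also records whether the estimated effect at the true
#'   SNP lies within 3 standard errors of the simulated beta.
#'
#' @param nSeeds replicate cohorts for the recovery rate.
#' @param maf generating minor-allele frequency of all SNPs.
#' @param beta simulated cis effect in SD units.
#' @return List with \code{recoveryRate}, \code{betaWithin3Se} (fraction),
#'   \code{betaHat} (per-seed estimates at the true SNP).
#' @export
cisRecoveryStudy <- function(nSeeds = 100, nSires = 10, progenyPerSire = 25,
                             nSnps = 60, nProbes = 8, maf = 0.3, beta = 1,
                             h2 = 0.4, seed = 1L) {
  recovered <- within3 <- logical(nSeeds)
  betaHat <- rep(NA_real_, nSeeds)
  for (r in seq_len(nSeeds)) {
    cfg <- simConfig(nSires = nSires, progenyPerSire = progenyPerSire,
                     nSnps = nSnps, nProbes = nProbes,
                     mafRange = c(maf, maf), h2Polygenic = h2,
                     nCisEffects = 1, nTransEffects = 0,
                     effectSizeSd = beta, nNegativeControlProbes = 0,
                     seed = seed + 7919L * r)
    co <- simulateCohort(cfg)
    eg <- twoLevelFdr(runEgwas(co$expr, co$geno))
    eqtl <- classifyLocalDistant(pruneToEqtlSnps(eg),
                                 probeAnnotation(co$expr))
    truePair <- co$arch$cis[1, ]
    rec <- eg$records[eg$records$probe == truePair$probe &
                        eg$records$snp == truePair$snp, ]
    betaHat[r] <- rec$beta
    se <- abs(rec$beta) / sqrt(rec$score)
    within3[r] <- is.finite(se) && abs(rec$beta - beta) <= 3 * se
    lead <- eqtl[eqtl$probe == truePair$probe, ]
    recovered[r] <- nrow(lead) > 0 && any(lead$regulation %in% "local")
  }
  list(recoveryRate = mean(recovered), betaWithin3Se = mean(within3),
       betaHat = betaHat)
}

#' @describeIn calibrationStudies REML heritability recovery on half-sib
#'   cohorts. For each true h2, \code{nReps} cohorts are simulated and the
#'   polygenic null is fit to one probe each; the first replicate is also
#'   profiled on a 0.001-spaced grid as an independent oracle.
#'
#' @param h2s true heritabilities to recover.
#' @param nReps replicate cohorts per h2.
#' @return data.frame per h2: \code{h2}, \code{medianH2Hat},
#'   \code{maxOracleGap} (|REML optimum - grid optimum| on the first
#'   replicate).
#' @export
h2RecoveryStudy <- function(h2s = c(0.2, 0.5, 0.8), nReps = 5,
                            nSires = 20, progenyPerSire = 25, nSnps = 200,
                            seed = 1L) {
  rows <- lapply(h2s, function(h2) {
    est <- numeric(nReps)
    oracleGap <- NA_real_
    for (r in seq_len(nReps)) {
      cfg <- simConfig(nSires = nSires, progenyPerSire = progenyPerSire,
                       nSnps = nSnps, nProbes = 1, h2Polygenic = h2,
                       nCisEffects = 0, nTransEffects = 0, batchEffectSd = 0,
                       sexEffectSd = 0, nNegativeControlProbes = 0,
                       seed = seed + round(1000 * h2) + r)
      co <- simulateCohort(cfg)
      K <- computeGenomicKinship(co$geno)
      y <- intensities(co$expr)[, 1]
      X <- matrix(1, length(y), 1)
      fit <- fitPolygenicNull(y, X, K)
      est[r] <- fit$h2
      if (r == 1) {
        ev <- eigen(kinshipValues(K), symmetric = TRUE)
        d <- pmax(ev$values, 0)
        yr <- as.vector(crossprod(ev$vectors, y))
        Xr <- as.vector(crossprod(ev$vectors, X))
        ll <- function(h) {
          v <- h * d + 1 - h
          w <- 1 / v
          b <- sum(w * Xr * yr) / sum(w * Xr^2)
          rss <- sum(w * (yr - Xr * b)^2)
          s2 <- rss / (length(y) - 1)
          -0.5 * ((length(y) - 1) * (log(s2) + 1) + sum(log(v)) +
                    log(sum(w * Xr^2)))
        }
        grid <- seq(0, 0.999, by = 0.001)
        oracleGap <- abs(fit$h2 - grid[which.max(vapply(grid, ll, 0))])
      }
    }
    data.frame(h2 = h2, medianH2Hat = median(est), maxOracleGap = oracleGap)
  })
  do.call(rbind, rows)
}

#' @describeIn calibrationStudies Calibration and power of the ASE caller on
#'   replicate cohorts of heterozygous-rich sites. In the null arm every
#'   site is balanced (alt fraction 0.5); the study reports the fraction of
#'   testable sites called ASE. In the power arm designated sites carry the
#'   configured imbalance and the study reports their detection rate.
#'
#' @param altFraction alt-allele fraction at designated true-ASE sites; 0.5
#'   makes the study a null calibration.
#' @param coverage mean read coverage.
#' @param nAnimals animals per cohort.
#' @param overdispersion negative-binomial coverage overdispersion.
#' @param nSitesPerCohort designated sites per cohort.
#' @return List with \code{rate} (fraction of designated, testable sites
#'   called ASE) and \code{nTestable}.
#' @export
aseCalibrationStudy <- function(nCohorts = 200, altFraction = 0.5,
                                coverage = 50, nAnimals = 38,
                                overdispersion = 0.1, nSitesPerCohort = 10,
                                seed = 1L) {
  called <- testable <- 0L
  isNull <- abs(altFraction - 0.5) < 1e-12
  for (r in seq_len(nCohorts)) {
    cfg <- simConfig(nSires = 2, progenyPerSire = ceiling(nAnimals / 2),
                     nSnps = max(40, 2 * nSitesPerCohort), nProbes = 4,
                     mafRange = c(0.3, 0.5),
                     nCisEffects = if (isNull) 0 else min(2, nSitesPerCohort),
                     nTransEffects = 0,
                     aseCoverageMean = coverage,
                     aseOverdispersion = overdispersion,
                     aseImbalanceFraction = if (isNull) 0.6 else altFraction,
                     nNullAseSites = if (isNull) nSitesPerCohort else 0,
                     seed = seed + r)
    gp <- simulateGenotypes(cfg)
    arch <- simulateArchitecture(gp$geno, cfg)
    if (isNull) arch$aseSites <- arch$aseSites[0, ]
    counts <- simulateAlleleCounts(gp$geno, arch, cfg)
    res <- runAse(counts)
    calls <- res$calls
    if (!isNull) {
      map <- snpMap(gp$geno)
      truePos <- map$pos[match(arch$aseSites$snp, map$snp)]
      calls <- calls[calls$position %in% truePos, , drop = FALSE]
    }
    testable <- testable + sum(!is.na(calls$is_ase))
    called <- called + sum(calls$is_ase, na.rm = TRUE)
  }
  list(rate = if (testable) called / testable else NA_real_,
       nTestable = testable)
}
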