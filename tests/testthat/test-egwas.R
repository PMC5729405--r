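# ------------------------------------------------------------------ null model

test_that("with K = I the model reduces to OLS and the variance split is flat", {
  set.seed(12)
  n <- 60
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, 0.5) + rnorm(n)
  fit <- fitPolygenicNull(y[, 1], X, diag(n))
  ols <- lm.fit(X, y[, 1])
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-6)
  # total variance matches the OLS residual variance regardless of the split
  expect_equal(fit$sigma2g + fit$sigma2e,
               sum(ols$residuals^2) / (n - 2), tolerance = 1e-6)
})

test_that("zero-noise response drives the residual variance to the floor", {
  set.seed(13)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- as.vector(X %*% c(1, 2))
  K <- diag(n)
  fit <- fitPolygenicNull(y, X, K)
  expect_lt(fit$sigma2, 1e-20)
  expect_equal(as.vector(X %*% fit$beta), y, tolerance = 1e-8)
})

test_that("the null model rejects degenerate inputs by name", {
  set.seed(14)
  n <- 20
  X <- cbind(intercept = 1, dup1 = rnorm(n))
  X <- cbind(X, dup2 = X[, "dup1"])
  expect_error(fitPolygenicNull(rnorm(n), X, diag(n)), "dup2")
  expect_error(fitPolygenicNull(c(rnorm(n - 1), NA), X[, 1:2], diag(n)),
               "non-finite")
})

test_that("REML h2 matches a grid-search oracle on a family cohort", {
  cfg <- simConfig(nSires = 8, progenyPerSire = 25, nSnps = 200, nProbes = 2,
                   h2Polygenic = 0.5, nCisEffects = 0, nTransEffects = 0,
                   seed = 15)
  co <- simulateCohort(cfg)
  K <- computeGenomicKinship(co$geno)
  y <- intensities(co$expr)[, 1]
  X <- matrix(1, length(y), 1)
  fit <- fitPolygenicNull(y, X, K)
  # independent oracle: profile the restricted likelihood on a fine grid
  ev <- eigen(kinshipValues(K), symmetric = TRUE)
  d <- pmax(ev$values, 0)
  yr <- crossprod(ev$vectors, y)
  Xr <- crossprod(ev$vectors, X)
  gridLl <- function(h2) {
    v <- h2 * d + 1 - h2
    w <- 1 / v
    b <- sum(w * Xr * yr) / sum(w * Xr^2)
    rss <- sum(w * (yr - Xr * b)^2)
    s2 <- rss / (length(y) - 1)
    -0.5 * ((length(y) - 1) * (log(s2) + 1) + sum(log(v)) +
              log(sum(w * Xr^2)))
  }
  grid <- seq(0, 0.99, by = 0.001)
  h2grid <- grid[which.max(vapply(grid, gridLl, 0))]
  expect_lt(abs(fit$h2 - h2grid), 0.005)
})

# ------------------------------------------------------------------ score test

test_that("score test with K = I equals the closed-form OLS score test", {
  set.seed(16)
  for (rep in 1:10) {
    n <- 50
    X <- cbind(1, rnorm(n))
    y <- rnorm(n)
    g <- rbinom(n, 2, 0.4)
    fit <- fitPolygenicNull(y, X, diag(n))
    mine <- scoreTest(fit, g)
    expect_equal(mine$p, olsScoreOracle(y, g, X), tolerance = 1e-10)
  }
  # no-covariate case (intercept only)
  n <- 40
  y <- rnorm(n); g <- rbinom(n, 2, 0.3)
  fit <- fitPolygenicNull(y, matrix(1, n, 1), diag(n))
  expect_equal(scoreTest(fit, g)$p, olsScoreOracle(y, g), tolerance = 1e-10)
})

test_that("monomorphic SNPs give NA, not an error", {
  set.seed(17)
  n <- 30
  fit <- fitPolygenicNull(rnorm(n), matrix(1, n, 1), diag(n))
  res <- scoreTest(fit, rep(2, n))
  expect_true(is.na(res$p))
  expect_true(is.na(res$beta))
})

test_that("vectorized and single-SNP score tests agree; missing dosages drop samples", {
  set.seed(18)
  n <- 80
  K <- diag(n)
  y <- rnorm(n)
  G <- matrix(rbinom(n * 5, 2, 0.4), n, 5, dimnames = list(NULL, paste0("s", 1:5)))
  fit <- fitPolygenicNull(y, matrix(1, n, 1), K)
  vec <- scoreTest(fit, G)
  for (j in 1:5)
    expect_equal(vec$p[j], scoreTest(fit, G[, j])$p, tolerance = 1e-12)
  # missing dosages: test equals the complete-sample oracle on the subset
  g <- G[, 1]; g[1:10] <- NA
  obs <- !is.na(g)
  res <- scoreTest(fit, g)
  expect_equal(res$p[1], olsScoreOracle(y[obs], g[obs]), tolerance = 1e-8)
})

test_that("score-test p-values are uniform under the null", {
  set.seed(19)
  n <- 150
  y <- rnorm(n)
  fit <- fitPolygenicNull(y, matrix(1, n, 1), diag(n))
  G <- matrix(rbinom(n * 500, 2, 0.3), n, 500)
  p <- scoreTest(fit, G)$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

# ------------------------------------------------------------------ runEgwas

test_that("runEgwas yields one record per probe x SNP and is permutation-invariant", {
  cfg <- simConfig(nSires = 4, progenyPerSire = 8, nSnps = 10, nProbes = 5,
                   nNegativeControlProbes = 0, seed = 20)
  co <- simulateCohort(cfg)
  eg <- runEgwas(co$expr, co$geno)
  expect_identical(nrow(eg$records), 50L)
  # permuting samples consistently leaves p-values unchanged
  perm <- sample(colnames(co$geno))
  eg2 <- runEgwas(co$expr[, perm], co$geno[, perm])
  ord <- order(eg$records$probe, eg$records$snp)
  ord2 <- order(eg2$records$probe, eg2$records$snp)
  expect_equal(eg$records$p[ord], eg2$records$p[ord2], tolerance = 1e-8)
})

test_that("runEgwas reports the sample-id mismatch", {
  cfg <- simConfig(nSires = 2, progenyPerSire = 5, nSnps = 10, nProbes = 3,
                   seed = 21)
  co <- simulateCohort(cfg)
  expect_error(runEgwas(co$expr[, 1:8], co$geno), "ind009")
})

# ------------------------------------------------------------------ two-level FDR

test_that("two-level FDR matches a hand step-up oracle on a toy table", {
  tab <- data.frame(
    probe = rep(c("A", "B"), each = 3),
    snp = rep(c("s1", "s2", "s3"), 2),
    p = c(0.001, 0.02, 0.9, 0.5, 0.6, 0.7))
  res <- twoLevelFdr(tab, alphaProbe = 0.05, alphaGlobal = 0.05)
  # hand BH within probe A: step-up over sorted (0.001, 0.02, 0.9) against
  # (1,2,3)*0.05/3: 0.02 <= 2*0.05/3 rejected, so threshold = 0.02.
  # probe B: nothing rejected.
  # global over six: only 0.001 <= 1*0.05/6; threshold = 0.001.
  # significant = below BOTH: only the 0.001 record.
  expect_identical(res$is_significant,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(attr(res, "global_threshold"), 0.001)
  expect_equal(unname(attr(res, "probe_thresholds")["A"]), 0.02)
  expect_equal(res$q_probe,
               c(p.adjust(tab$p[1:3], "BH"), p.adjust(tab$p[4:6], "BH")),
               tolerance = 1e-12)
  expect_equal(res$q_global, p.adjust(tab$p, "BH"), tolerance = 1e-12)
  # all p = 1: nothing significant
  tab1 <- data.frame(probe = "A", snp = c("s1", "s2"), p = c(1, 1))
  expect_false(any(twoLevelFdr(tab1)$is_significant))
})

test_that("significance requires clearing both thresholds", {
  # probe A has a strong hit; probe B's best p clears its own probe-level
  # threshold but not the global one
  tab <- data.frame(
    probe = rep(c("A", "B"), each = 4),
    snp = rep(paste0("s", 1:4), 2),
    p = c(1e-8, 1e-7, 0.8, 0.9, 0.04, 0.5, 0.6, 0.7))
  res <- twoLevelFdr(tab)
  sigB <- res$is_significant[res$probe == "B"]
  expect_false(any(sigB))
  expect_true(all(res$is_significant[res$probe == "A"][1:2]))
})

# ------------------------------------------------------------------ pruning

test_that("perfect-LD SNP pairs collapse to one eQTL-SNP with deterministic lead", {
  set.seed(23)
  n <- 120
  g <- rbinom(n, 2, 0.5)
  G <- cbind(s1 = g, s2 = g, s3 = rbinom(n, 2, 0.5))
  geno <- toyGenotypes(G, pos = c(1e6, 1.1e6, 30e6))
  y <- g * 1.2 + rnorm(n)
  expr <- toyExpression(cbind(y), start = 1e6)
  eg <- twoLevelFdr(runEgwas(expr, geno, K = idKinship(geno)))
  eqtl <- pruneToEqtlSnps(eg)
  expect_identical(nrow(eqtl), 1L)
  # identical dosages give identical p; tie broken by genomic position
  expect_identical(eqtl$snp, "s1")
  expect_identical(eqtl$n_pruned, 1L)
})

test_that("SNPs beyond the pruning window are never merged", {
  set.seed(24)
  n <- 150
  g1 <- rbinom(n, 2, 0.5)
  G <- cbind(s1 = g1, s2 = g1)  # perfectly correlated but 6 Mb apart
  geno <- toyGenotypes(G, pos = c(1e6, 7e6))
  y <- g1 * 1.5 + rnorm(n)
  expr <- toyExpression(cbind(y), start = 1e6)
  eg <- twoLevelFdr(runEgwas(expr, geno, K = idKinship(geno)))
  eqtl <- pruneToEqtlSnps(eg, windowBp = 5e6)
  expect_identical(sort(eqtl$snp), c("s1", "s2"))
})

test_that("independent causal SNPs within the window are both retained", {
  set.seed(25)
  n <- 250
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  G <- cbind(s1 = g1, s2 = g2)
  geno <- toyGenotypes(G, pos = c(1e6, 2e6))  # 1 Mb apart, inside 5 Mb window
  y <- g1 + g2 + rnorm(n)
  expr <- toyExpression(cbind(y), start = 1e6)
  eg <- twoLevelFdr(runEgwas(expr, geno, K = idKinship(geno)))
  eqtl <- pruneToEqtlSnps(eg)
  expect_identical(sort(eqtl$snp), c("s1", "s2"))
})

test_that("pruning output is invariant to record order and leads dominate", {
  set.seed(26)
  cfg <- simConfig(nSires = 8, progenyPerSire = 25, nSnps = 40, nProbes = 6,
                   ldDecayRho = 0.7, nCisEffects = 2, nTransEffects = 1,
                   seed = 26)
  co <- simulateCohort(cfg)
  eg <- twoLevelFdr(runEgwas(co$expr, co$geno))
  eqtl <- pruneToEqtlSnps(eg)
  egShuf <- eg
  ix <- sample(nrow(eg$records))
  egShuf$records <- eg$records[ix, ]
  eqtlShuf <- pruneToEqtlSnps(egShuf)
  o1 <- eqtl[order(eqtl$probe, eqtl$snp), ]
  o2 <- eqtlShuf[order(eqtlShuf$probe, eqtlShuf$snp), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # every lead's p <= every pruned-away significant p within its window
  sig <- eg$records[which(eg$records$is_significant), ]
  map <- snpMap(co$geno)
  for (i in seq_len(nrow(eqtl))) {
    lead <- eqtl[i, ]
    inWin <- sig$probe == lead$probe &
      map$chrom[match(sig$snp, map$snp)] == lead$chrom &
      abs(map$pos[match(sig$snp, map$snp)] - lead$pos) <= 5e6
    expect_true(all(lead$p <= sig$p[inWin] + 1e-15))
  }
})

# ------------------------------------------------ classification & statistics

test_that("local/distant classification applies the 1 Mb inclusive rule", {
  eqtl <- data.frame(
    probe = c("p1", "p1", "p2", "p3", "p4"),
    snp = c("a", "b", "c", "d", "e"),
    chrom = c("1", "2", "1", "1", "1"),
    pos = c(5e6, 5e6, 2e6, 1e6, 5e6),
    p = 1e-9, beta = 1)
  ann <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                    chrom = c("1", "1", "1", NA),
                    start = c(5e6, 1e6, 2e6, NA))
  res <- classifyLocalDistant(eqtl, ann)
  expect_identical(res$regulation, c("local", "distant", "local", "local", NA))
  expect_identical(res$distance_bp[2], Inf)
  expect_identical(res$distance_bp[3], 1e6)  # exactly 1 Mb: inclusive
  summ <- attr(res, "snp_summary")
  expect_identical(summ$label[summ$snp == "a"], "local")
  expect_identical(summ$label[summ$snp == "b"], "distant")
  # a SNP hitting both classes across probes is labelled "both"
  eqtl2 <- rbind(eqtl[1, ], transform(eqtl[1, ], probe = "p2"))
  res2 <- classifyLocalDistant(eqtl2, ann)
  expect_identical(attr(res2, "snp_summary")$label, "both")
})

test_that("effect/SD ratio follows its definition", {
  v <- c(1, 2, 3)
  expect_equal(effectSdRatio(sd(v), v), 1)        # |beta| = SD -> 1
  expect_equal(effectSdRatio(0, v), 0)            # beta = 0 -> 0
  x <- rnorm(20)
  x <- x / sd(x) * 0.75                           # SD exactly 0.75
  expect_equal(effectSdRatio(1.5, x), 2)
  expect_equal(effectSdRatio(-1.5, x), 2)         # sign-free
  expect_true(is.na(effectSdRatio(2, rep(1, 5)))) # zero SD -> NA
  expect_error(effectSdRatio(1, 1), "2 probe values")
  # matrix form with per-association probes
  M <- cbind(p1 = v, p2 = x[1:3])
  expect_equal(effectSdRatio(c(1, 1), M, probe = c("p1", "p2")),
               c(p1 = 1 / sd(v), p2 = 1 / sd(x[1:3])))
})

test_that("chromosome enrichment matches the hypergeometric tail", {
  # 10 of 100 on the chromosome vs 50 of 1000 genome-wide
  bg <- paste0("s", 1:1000)
  chrom <- stats::setNames(rep("2", 1000), bg)
  chrom[1:100] <- "1"
  feat <- c(bg[1:10], bg[101:140])
  res <- chromosomeEnrichment(feat, bg, chrom)
  r1 <- res[res$chrom == "1", ]
  expect_equal(r1$p_enrich, phyper(10 - 1, 100, 900, 50, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(r1$p_deplete, phyper(10, 100, 900, 50), tolerance = 1e-10)
  # feature set == background set: odds ratio 1-ish, p = 1
  resAll <- chromosomeEnrichment(bg, bg, chrom)
  expect_true(all(resAll$p_enrich == 1 | resAll$p_deplete == 1))
  expect_error(chromosomeEnrichment(c("zzz"), bg, chrom), "subset")
})

test_that("composition test flags chromosomes with skewed local/distant ratios", {
  lab <- c(rep("local", 40), rep("distant", 40), rep("local", 38), rep("distant", 2))
  chrom <- c(rep("1", 80), rep("2", 40))
  res <- regulationCompositionTest(lab, chrom)
  expect_lt(res$p_chisq[res$chrom == "2"], 0.05)
  # identical composition everywhere: no signal
  lab2 <- rep(c("local", "distant"), 60)
  res2 <- regulationCompositionTest(lab2, chrom)
  expect_true(all(res2$p_chisq > 0.05))
})
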