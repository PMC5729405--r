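#' Fit the polygenic null model for one probe
#'
#' Fits \code{y = X beta + u + e}, \code{u ~ N(0, sigma2_g K)},
#' \code{e ~ N(0, sigma2_e I)}, by restricted maximum likelihood profiled
#' over the heritability \code{h2 = sigma2_g / (sigma2_g + sigma2_e)}. The
#' model is rotated onto the eigenbasis of K (EMMA-style), making each
#' likelihood evaluation a weighted least-squares fit; the 1-D profile is
#' maximized with \code{optimize}. The eigendecomposition can be computed
#' once and shared across probes.
#'
#' @param y numeric response (probe expression), length n.
#' @param X fixed-effect design matrix (n x p), including the intercept.
#' @param K a \linkS4class{KinshipMatrix} or symmetric matrix; negative
#'   eigenvalues are clipped to 0.
#' @param eigenK optional precomputed \code{eigen(K, symmetric = TRUE)}.
#' @return Object of class \code{"PolygenicNullModel"}: list with
#'   \code{h2}, \code{sigma2g}, \code{sigma2e}, \code{beta} (fixed effects),
#'   \code{reml} (profiled restricted log-likelihood), plus cached rotation
#'   pieces (\code{U}, \code{d}, \code{Xr}, \code{yr}, \code{w},
#'   \code{resid} = rotated weighted-LS residuals, \code{sigma2} = total
#'   variance, \code{XtWXi}).
#' @export
fitPolygenicNull <- function(y, X, K, eigenK = NULL) {
  if (!is.matrix(X)) X <- cbind(intercept = X)
  n <- length(y)
  if (!all(is.finite(y))) stop("non-finite values in y")
  if (nrow(X) != n) stop("X and y dimensions differ")
  if (n < ncol(X) + 2) stop("need n >= p + 2 observations")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  Kv <- if (is(K, "KinshipMatrix")) kinshipValues(K) else K
  if (is.null(eigenK)) eigenK <- eigen(Kv, symmetric = TRUE)
  d <- pmax(eigenK$values, 0)
  U <- eigenK$vectors
  yr <- as.vector(crossprod(U, y))
  Xr <- crossprod(U, X)
  p <- ncol(X)

  remlAt <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xr, w * Xr)
    beta <- solve(XtWX, crossprod(Xr, w * yr))
    r <- yr - Xr %*% beta
    rss <- sum(w * r^2)
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(sigma2) + 1) + sum(log(v)) +
                    determinant(XtWX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), beta = beta, resid = as.vector(r), w = w,
         sigma2 = sigma2, XtWXi = solve(XtWX))
  }
  opt <- optimize(function(h2) remlAt(h2)$ll, interval = c(0, 0.9999),
                  maximum = TRUE, tol = 1e-6)
  # compare against the boundary at h2 = 0 (optimize can miss a boundary max)
  h2 <- opt$maximum
  at0 <- remlAt(0)
  fit <- remlAt(h2)
  if (at0$ll >= fit$ll) { h2 <- 0; fit <- at0 }
  model <- list(h2 = h2,
                sigma2g = h2 * fit$sigma2,
                sigma2e = (1 - h2) * fit$sigma2,
                sigma2 = fit$sigma2,
                beta = stats::setNames(as.vector(fit$beta), colnames(X)),
                reml = fit$ll,
                U = U, d = d, Xr = Xr, yr = yr, w = fit$w,
                resid = fit$resid, XtWXi = fit$XtWXi, n = n, p = p,
                yraw = y, Xraw = X)
  class(model) <- "PolygenicNullModel"
  model
}

#' @export
print.PolygenicNullModel <- function(x, ...) {
  cat("Polygenic null model: n =", x$n, "\n")
  cat("  h2 =", signif(x$h2, 4), " sigma2_g =", signif(x$sigma2g, 4),
      " sigma2_e =", signif(x$sigma2e, 4), "\n")
  cat("  fixed effects:", paste(signif(x$beta, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Family-based score test for a SNP effect
#'
#' Score (FASTA-type) test of a single SNP added to a fitted polygenic null:
#' \deqn{T = \frac{(\tilde g' \hat V^{-1} \tilde y)^2}{\tilde g' \hat V^{-1} \tilde g}
#'       \sim \chi^2_1,}
#' with g and y residualized on the fixed effects under the fitted
#' covariance. The effect estimate is
#' \code{beta = (g' V^-1 y_res) / (g' V^-1 g_res)}.
#'
#' @param model a \code{\link{fitPolygenicNull}} fit.
#' @param g numeric dosage vector in the model's sample order, or an
#'   n x m dosage matrix for vectorized testing.
#' @return data.frame with columns \code{beta}, \code{score}, \code{p};
#'   monomorphic SNPs yield NA rows.
#' @export
scoreTest <- function(model, g) {
  gm <- if (is.matrix(g)) g else matrix(g, ncol = 1)
  if (nrow(gm) != model$n) stop("dosage length does not match model")
  out <- data.frame(beta = rep(NA_real_, ncol(gm)),
                    score = NA_real_, p = NA_real_)
  rownames(out) <- colnames(gm)
  complete <- !colSums(is.na(gm))
  ok <- complete & apply(gm, 2, function(x) {
    x <- x[!is.na(x)]; length(unique(x)) > 1
  })
  if (any(!complete & apply(gm, 2, function(x) length(unique(x[!is.na(x)])) > 1))) {
    # pairwise-complete fallback: refit on the observed subset per SNP
    for (j in which(!complete)) {
      x <- gm[, j]
      obs <- !is.na(x)
      if (length(unique(x[obs])) < 2 || sum(obs) < model$p + 2) next
      Kv <- model$U %*% (model$d * t(model$U))
      sub <- fitPolygenicNull(model$yraw[obs], model$Xraw[obs, , drop = FALSE],
                              Kv[obs, obs])
      out[j, ] <- scoreTest(sub, x[obs])[1, ]
    }
  }
  idx <- which(ok)
  if (length(idx)) {
    Gr <- crossprod(model$U, gm[, idx, drop = FALSE])
    w <- model$w
    # residualize on X under W
    H <- model$XtWXi %*% crossprod(model$Xr, w * Gr)
    Gt <- Gr - model$Xr %*% H
    num <- as.vector(crossprod(Gt, w * model$resid))
    den <- colSums(w * Gt^2)
    T <- num^2 / (model$sigma2 * den)
    out$beta[idx] <- num / den
    out$score[idx] <- T
    out$p[idx] <- pchisq(T, df = 1, lower.tail = FALSE)
  }
  out
}

#' Run the expression GWAS
#'
#' Tests every expressed probe against every SNP with the polygenic
#' mixed-model score test, sharing one eigendecomposition of the kinship
#' matrix across probes. Probes and SNPs are treated independently.
#'
#' @param expr an \linkS4class{ExpressionExperiment} (experimental probes
#'   only are tested; negative controls are skipped).
#' @param geno a \linkS4class{GenotypeExperiment}, samples aligned with
#'   \code{expr} by sample id.
#' @param covars data.frame of fixed-effect covariates (e.g. batch, sex),
#'   rownames = sample ids; NULL uses \code{colData(expr)} columns batch and
#'   sex when present, else intercept only.
#' @param K a \linkS4class{KinshipMatrix}; NULL computes it from \code{geno}.
#' @param verbose log progress every 50 probes.
#' @return Object of class \code{"EgwasResult"}: list with \code{records}
#'   (data.frame probe, snp, beta, score, p), \code{models} (per-probe null
#'   fits), \code{design}, sample ids, and the inputs needed downstream.
#' @export
runEgwas <- function(expr, geno, covars = NULL, K = NULL, verbose = FALSE) {
  ids <- colnames(expr)
  if (!setequal(ids, colnames(geno))) {
    d1 <- setdiff(ids, colnames(geno))
    d2 <- setdiff(colnames(geno), ids)
    stop("sample ids differ between expression and genotypes; ",
         "expression-only: {", paste(d1, collapse = ","),
         "}, genotype-only: {", paste(d2, collapse = ","), "}")
  }
  geno <- geno[, ids]
  if (is.null(covars)) {
    cd <- as.data.frame(colData(expr))
    covars <- cd[, intersect(c("batch", "sex"), colnames(cd)), drop = FALSE]
  } else {
    covars <- covars[match(ids, rownames(covars)), , drop = FALSE]
  }
  X <- if (ncol(covars)) {
    model.matrix(~ ., data = as.data.frame(lapply(covars, function(x)
      if (is.character(x)) factor(x) else x)))
  } else matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
  rownames(X) <- ids
  if (is.null(K)) K <- computeGenomicKinship(geno)
  eigenK <- eigen(kinshipValues(K)[ids, ids], symmetric = TRUE)

  E <- intensities(expr)                      # samples x probes
  pa <- probeAnnotation(expr)
  testProbes <- pa$probe[pa$probe_class == "experimental"]
  G <- dosages(geno)                          # samples x SNPs

  models <- vector("list", length(testProbes))
  names(models) <- testProbes
  recs <- vector("list", length(testProbes))
  for (i in seq_along(testProbes)) {
    pr <- testProbes[i]
    fit <- fitPolygenicNull(E[, pr], X, K, eigenK = eigenK)
    models[[pr]] <- fit
    st <- scoreTest(fit, G)
    recs[[i]] <- data.frame(probe = pr, snp = colnames(G), beta = st$beta,
                            score = st$score, p = st$p,
                            stringsAsFactors = FALSE)
    if (verbose && i %% 50 == 0)
      message("tested probe ", i, "/", length(testProbes))
  }
  res <- list(records = do.call(rbind, recs), models = models, design = X,
              samples = ids, geno = geno, expr = expr, K = K)
  class(res) <- "EgwasResult"
  res
}

#' @export
print.EgwasResult <- function(x, ...) {
  cat("EgwasResult:", length(x$models), "probes x",
      length(unique(x$records$snp)), "SNPs =", nrow(x$records), "tests\n")
  if (!is.null(x$records$is_significant))
    cat("  significant associations:", sum(x$records$is_significant, na.rm = TRUE), "\n")
  invisible(x)
}

#' Two-level FDR correction
#'
#' Applies Benjamini-Hochberg step-up twice: within each probe (across its
#' SNPs) and globally (across all probe x SNP tests). Each pass defines a
#' p-value threshold (the largest rejected p, step-up semantics); an
#' association is significant iff its p-value is at or below both
#' thresholds.
#'
#' @param records data.frame with columns \code{probe}, \code{snp}, \code{p}
#'   (e.g. \code{runEgwas(...)$records}), or an \code{"EgwasResult"}.
#' @param alphaProbe per-probe FDR level (default 0.05).
#' @param alphaGlobal global FDR level (default 0.05).
#' @return The records augmented with \code{q_probe}, \code{q_global},
#'   \code{is_significant}, and attributes \code{probe_thresholds} (named
#'   vector) and \code{global_threshold}. For an EgwasResult input, the
#'   result with updated \code{records} and \code{thresholds}.
#' @export
twoLevelFdr <- function(records, alphaProbe = 0.05, alphaGlobal = 0.05) {
  isResult <- inherits(records, "EgwasResult")
  tab <- if (isResult) records$records else records
  stopifnot(all(c("probe", "p") %in% colnames(tab)))
  ok <- !is.na(tab$p)
  tab$q_probe <- NA_real_
  tab$q_global <- NA_real_
  probeThresh <- tapply(seq_len(nrow(tab)), tab$probe, function(ix) {
    ix <- ix[!is.na(tab$p[ix])]
    if (!length(ix)) return(-Inf)
    q <- p.adjust(tab$p[ix], method = "BH")
    tab$q_probe[ix] <<- q
    rej <- tab$p[ix][q <= alphaProbe]
    if (length(rej)) max(rej) else -Inf
  })
  tab$q_global[ok] <- p.adjust(tab$p[ok], method = "BH")
  rejG <- tab$p[ok][tab$q_global[ok] <= alphaGlobal]
  globalThresh <- if (length(rejG)) max(rejG) else -Inf
  tab$is_significant <- as.vector(ok & tab$p <= probeThresh[tab$probe] &
                                    tab$p <= globalThresh)
  attr(tab, "probe_thresholds") <- probeThresh
  attr(tab, "global_threshold") <- globalThresh
  if (isResult) {
    records$records <- tab
    records$thresholds <- list(probe = probeThresh, global = globalThresh,
                               alphaProbe = alphaProbe, alphaGlobal = alphaGlobal)
    records
  } else tab
}

#' Prune significant SNPs to lead eQTL-SNPs by conditional retesting
#'
#' Per probe: take the most significant remaining SNP as the lead eQTL-SNP
#' (ties broken by chromosome then position); retest every other
#' significant SNP within \code{windowBp} of the lead on the same chromosome
#' with the lead's dosage added to the fixed effects; SNPs whose conditional
#' p-value no longer clears the stored significance threshold(s) are
#' redundant and removed, the rest stay eligible to seed their own eQTL.
#' Repeats until all significant SNPs are assigned.
#'
#' @param egwas an \code{"EgwasResult"} that has been through
#'   \code{\link{twoLevelFdr}}.
#' @param windowBp pruning window around the lead SNP (default 5 Mb).
#' @param conditionalThresholds which stored thresholds the conditional
#'   retest must clear: \code{"both"} (default), \code{"probe"} or
#'   \code{"global"}.
#' @return data.frame of eQTL-SNPs: \code{probe}, \code{snp}, \code{beta},
#'   \code{p}, \code{chrom}, \code{pos}, \code{n_pruned} (SNPs absorbed),
#'   one row per retained probe-lead pair.
#' @export
pruneToEqtlSnps <- function(egwas, windowBp = 5e6,
                            conditionalThresholds = c("both", "probe", "global")) {
  conditionalThresholds <- match.arg(conditionalThresholds)
  stopifnot(inherits(egwas, "EgwasResult"), !is.null(egwas$thresholds))
  tab <- egwas$records
  sig <- tab[which(tab$is_significant), , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(probe = character(0), snp = character(0),
                      beta = numeric(0), p = numeric(0),
                      chrom = character(0), pos = integer(0),
                      n_pruned = integer(0), stringsAsFactors = FALSE))
  map <- snpMap(egwas$geno)
  sig$chrom <- map$chrom[match(sig$snp, map$snp)]
  sig$pos <- map$pos[match(sig$snp, map$snp)]
  G <- dosages(egwas$geno)
  probeThresh <- egwas$thresholds$probe
  globalThresh <- egwas$thresholds$global
  passes <- function(p, probe) {
    if (is.na(p)) return(FALSE)
    pt <- p <= probeThresh[probe]
    gt <- p <= globalThresh
    switch(conditionalThresholds, both = pt && gt, probe = pt, global = gt)
  }

  out <- list()
  for (pr in unique(sig$probe)) {
    rem <- sig[sig$probe == pr, , drop = FALSE]
    rem <- rem[order(rem$p, chromOrder(rem$chrom), rem$pos), , drop = FALSE]
    model0 <- egwas$models[[pr]]
    while (nrow(rem)) {
      lead <- rem[1, ]
      rem <- rem[-1, , drop = FALSE]
      inWin <- rem$chrom == lead$chrom & abs(rem$pos - lead$pos) <= windowBp
      nPruned <- 0L
      if (any(inWin)) {
        Xc <- cbind(model0$Xraw, lead_dosage = G[, lead$snp])
        condModel <- tryCatch(
          fitPolygenicNull(model0$yraw, Xc, kinshipValues(egwas$K)),
          error = function(e) NULL)
        for (ix in which(inWin)) {
          if (is.null(condModel)) { keepSnp <- FALSE } else {
            cp <- scoreTest(condModel, G[, rem$snp[ix]])$p[1]
            keepSnp <- passes(cp, pr)
          }
          if (!keepSnp) {
            inWin[ix] <- TRUE
          } else inWin[ix] <- FALSE
        }
        nPruned <- sum(inWin)
        rem <- rem[!inWin, , drop = FALSE]
      }
      out[[length(out) + 1L]] <-
        data.frame(probe = pr, snp = lead$snp, beta = lead$beta, p = lead$p,
                   chrom = lead$chrom, pos = lead$pos, n_pruned = nPruned,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify eQTL-SNP associations as local or distant
#'
#' An association is local iff the SNP lies on the same chromosome as the
#' probe and within \code{windowBp} (inclusive) of the probe start; all
#' other mapped pairs are distant. Unmapped probes get NA. Also returns a
#' per-SNP summary label across its probes: local, distant, or both.
#'
#' @param eqtl data.frame from \code{\link{pruneToEqtlSnps}} (columns probe,
#'   snp, chrom, pos).
#' @param annotation probe annotation data.frame (probe, chrom, start).
#' @param windowBp local window (default 1 Mb, inclusive boundary).
#' @return The eqtl table with \code{distance_bp} and \code{regulation}
#'   (\code{"local"}/\code{"distant"}/NA) columns, plus attribute
#'   \code{snp_summary}: data.frame (snp, label).
#' @export
classifyLocalDistant <- function(eqtl, annotation, windowBp = 1e6) {
  i <- match(eqtl$probe, annotation$probe)
  pChrom <- annotation$chrom[i]
  pStart <- annotation$start[i]
  sameChrom <- !is.na(pStart) & !is.na(pChrom) & eqtl$chrom == pChrom
  dist <- ifelse(sameChrom, abs(eqtl$pos - pStart), Inf)
  eqtl$distance_bp <- dist
  eqtl$regulation <- ifelse(is.na(pStart), NA_character_,
                            ifelse(sameChrom & dist <= windowBp,
                                   "local", "distant"))
  summ <- tapply(eqtl$regulation, eqtl$snp, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) NA_character_
    else if (all(r == "local")) "local"
    else if (all(r == "distant")) "distant"
    else "both"
  })
  attr(eqtl, "snp_summary") <- data.frame(snp = names(summ),
                                          label = as.character(summ),
                                          stringsAsFactors = FALSE)
  eqtl
}

#' Ratio of SNP effect to probe expression SD
#'
#' @param beta SNP effect estimate (numeric vector).
#' @param probeValues numeric vector of the probe's expression values, or a
#'   matrix (samples x probes) with \code{probe} naming the column per beta.
#' @param probe optional probe ids when \code{probeValues} is a matrix.
#' @return |beta| / sample SD (n-1 denominator); NA when the SD is zero.
#' @export
effectSdRatio <- function(beta, probeValues, probe = NULL) {
  s <- if (is.matrix(probeValues)) {
    stopifnot(!is.null(probe))
    apply(probeValues[, probe, drop = FALSE], 2, sd)
  } else {
    if (length(probeValues) < 2) stop("need at least 2 probe values")
    sd(probeValues)
  }
  ifelse(s > 0, abs(beta) / s, NA_real_)
}

#' Per-chromosome enrichment of a feature set
#'
#' For each chromosome, builds the 2x2 table (on-chromosome feature /
#' non-feature vs off-chromosome feature / non-feature) and reports
#' one-sided Fisher exact p-values for enrichment and depletion, plus the
#' odds ratio.
#'
#' @param feature character vector of feature item ids (subset of
#'   \code{background}).
#' @param background character vector of all item ids.
#' @param chrom named character vector mapping item id to chromosome.
#' @return data.frame: chrom, n_feature, n_background, p_enrich, p_deplete,
#'   odds_ratio (NA rows for chromosomes with no background items).
#' @export
chromosomeEnrichment <- function(feature, background, chrom) {
  if (!all(feature %in% background))
    stop("feature items must be a subset of the background")
  chroms <- unique(chrom[background])
  chroms <- chroms[!is.na(chroms)]
  nF <- length(unique(feature))
  nB <- length(unique(background))
  res <- lapply(chroms, function(ch) {
    onBg <- sum(chrom[unique(background)] == ch, na.rm = TRUE)
    onF <- sum(chrom[unique(feature)] == ch, na.rm = TRUE)
    if (onBg == 0)
      return(data.frame(chrom = ch, n_feature = 0L, n_background = 0L,
                        p_enrich = NA_real_, p_deplete = NA_real_,
                        odds_ratio = NA_real_))
    m <- matrix(c(onF, onBg - onF, nF - onF, (nB - onBg) - (nF - onF)), 2)
    fe <- fisher.test(m, alternative = "greater")
    fd <- fisher.test(m, alternative = "less")
    data.frame(chrom = ch, n_feature = onF, n_background = onBg,
               p_enrich = fe$p.value, p_deplete = fd$p.value,
               odds_ratio = unname(fe$estimate), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-chromosome composition test of regulation classes
#'
#' Chi-square test comparing, for each chromosome, the local / distant /
#' both composition of its items against the rest of the genome.
#'
#' @param label character vector of class labels per item.
#' @param chrom character vector of chromosomes per item (same length).
#' @return data.frame: chrom, n, p_chisq.
#' @export
regulationCompositionTest <- function(label, chrom) {
  ok <- !is.na(label) & !is.na(chrom)
  label <- factor(label[ok])
  chrom <- chrom[ok]
  res <- lapply(unique(chrom), function(ch) {
    onChrom <- table(label[chrom == ch])
    offChrom <- table(label[chrom != ch])
    p <- if (sum(onChrom) == 0 || sum(offChrom) == 0) NA_real_ else
      suppressWarnings(chisq.test(rbind(onChrom, offChrom))$p.value)
    data.frame(chrom = ch, n = sum(onChrom), p_chisq = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
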