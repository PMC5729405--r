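#' KinshipMatrix: genomic relatedness estimate
#'
#' Symmetric samples x samples matrix of standardized genotype
#' cross-products over autosomal SNPs (Amin/GenABEL-style per-SNP
#' standardization), with the number of SNPs that entered the estimate.
#'
#' @slot values symmetric numeric matrix, samples x samples.
#' @slot snpCount integer, SNPs contributing to the estimate.
#' @export
setClass("KinshipMatrix",
         representation(values = "matrix", snpCount = "integer"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("kinship matrix must be square")
  if (!isSymmetric(unname(v), tol = 1e-8)) return("kinship matrix must be symmetric")
  TRUE
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix:", nrow(object@values), "samples, from",
      object@snpCount, "SNPs\n")
  cat("  mean diagonal:", signif(mean(diag(object@values)), 4),
      " mean off-diagonal:",
      signif(mean(object@values[upper.tri(object@values)]), 4), "\n")
  invisible(NULL)
})

#' @rdname kinshipValues
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))
#' Extract the kinship matrix values
#' @param x a KinshipMatrix.
#' @return numeric matrix.
#' @name kinshipValues
#' @export
setMethod("kinshipValues", "KinshipMatrix", function(x) x@values)

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test conditioning on allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts no more probable than the
#' observed one (Wigginton-style tail sum).
#'
#' @param nAA,nAB,nBB genotype counts (vectors allowed, recycled).
#' @return numeric vector of exact p-values.
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n == 0) return(NA_real_)
    nA <- 2 * aa + ab
    nB <- 2 * bb + ab
    rare <- min(nA, nB)
    hets <- seq(rare %% 2, rare, by = 2)  # parity fixed by allele count
    # log P(n_AB = h | nA, nB), normalized explicitly for stability
    logp <- sapply(hets, function(h) {
      a <- (rare - h) / 2            # rare-allele homozygotes
      b <- (2 * n - rare - h) / 2    # common-allele homozygotes
      lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
        h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
    })
    prob <- exp(logp - max(logp))
    prob <- prob / sum(prob)
    obs <- prob[match(ab, hets)]
    sum(prob[prob <= obs * (1 + 1e-7)])
  }, nAA, nAB, nBB)
}

#' Genotype quality control
#'
#' Applies, in order: sample call-rate filter, SNP call-rate filter, MAF
#' filter (strict: MAF must exceed \code{minMaf}), and an exact
#' Hardy-Weinberg test whose p-values are Benjamini-Hochberg adjusted across
#' SNPs (SNPs with q below \code{hweFdr} are dropped).
#'
#' @param geno a GenotypeExperiment.
#' @param minCallRate minimum per-sample and per-SNP call rate (default 0.95).
#' @param minMaf minimum minor allele frequency, exclusive bound (default 0.05).
#' @param hweFdr FDR level for the HWE exclusion (default 0.01).
#' @param hweTest \code{"exact"} (default) or \code{"chisq"}.
#' @return List with \code{geno} (filtered GenotypeExperiment) and
#'   \code{report} (data.frame item, type, reason, value).
#' @export
filterGenotypes <- function(geno, minCallRate = 0.95, minMaf = 0.05,
                            hweFdr = 0.01, hweTest = c("exact", "chisq")) {
  hweTest <- match.arg(hweTest)
  if (ncol(geno) < 2) stop("need at least 2 samples")
  d <- assay(geno, "dosage")  # SNPs x samples
  report <- data.frame(item = character(0), type = character(0),
                       reason = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  addReport <- function(items, type, reason, value) {
    if (length(items))
      rbind(report, data.frame(item = items, type = type, reason = reason,
                               value = value, stringsAsFactors = FALSE))
    else report
  }

  sampleCall <- colMeans(!is.na(d))
  dropS <- sampleCall < minCallRate
  report <- addReport(colnames(d)[dropS], "sample", "call_rate",
                      sampleCall[dropS])
  d <- d[, !dropS, drop = FALSE]

  snpCall <- rowMeans(!is.na(d))
  dropCall <- snpCall < minCallRate
  report <- addReport(rownames(d)[dropCall], "snp", "call_rate", snpCall[dropCall])

  p <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  dropMaf <- !dropCall & !(maf > minMaf)
  report <- addReport(rownames(d)[dropMaf], "snp", "maf", maf[dropMaf])

  keepSoFar <- !dropCall & !dropMaf
  hweP <- rep(NA_real_, nrow(d))
  idx <- which(keepSoFar)
  if (length(idx)) {
    nAA <- rowSums(d[idx, , drop = FALSE] == 0, na.rm = TRUE)
    nAB <- rowSums(d[idx, , drop = FALSE] == 1, na.rm = TRUE)
    nBB <- rowSums(d[idx, , drop = FALSE] == 2, na.rm = TRUE)
    hweP[idx] <- if (hweTest == "exact") {
      hweExactTest(nAA, nAB, nBB)
    } else {
      nTot <- nAA + nAB + nBB
      pA <- (2 * nAA + nAB) / (2 * nTot)
      ex <- cbind(nTot * pA^2, 2 * nTot * pA * (1 - pA), nTot * (1 - pA)^2)
      stat <- rowSums((cbind(nAA, nAB, nBB) - ex)^2 / pmax(ex, 1e-300))
      pchisq(stat, df = 1, lower.tail = FALSE)
    }
    hweQ <- rep(NA_real_, nrow(d))
    hweQ[idx] <- p.adjust(hweP[idx], method = "BH")
    dropHwe <- !is.na(hweQ) & hweQ < hweFdr
    report <- addReport(rownames(d)[dropHwe], "snp", "hwe", hweQ[dropHwe])
  } else dropHwe <- rep(FALSE, nrow(d))

  keep <- keepSoFar & !dropHwe
  if (!any(keep))
    stop("all SNPs removed by QC (call rate: ", sum(dropCall),
         ", MAF: ", sum(dropMaf), ", HWE: ", sum(dropHwe), ")")
  out <- geno[rownames(d)[keep], colnames(d)]
  list(geno = out, report = report)
}

#' Genomic kinship matrix
#'
#' Per-SNP standardized estimator:
#' \deqn{K_{ij} = \frac{1}{M} \sum_k \frac{(g_{ik} - 2p_k)(g_{jk} - 2p_k)}{2 p_k (1 - p_k)}}
#' over autosomal SNPs. Missing dosages are handled pairwise-complete: each
#' pair is averaged over the SNPs where both samples are observed.
#' Monomorphic SNPs (p of 0 or 1) are excluded.
#'
#' @param geno a GenotypeExperiment (post-QC).
#' @param autosomesOnly drop SNPs on chromosomes labelled X, Y, MT (default TRUE).
#' @return A \linkS4class{KinshipMatrix}.
#' @export
computeGenomicKinship <- function(geno, autosomesOnly = TRUE) {
  map <- snpMap(geno)
  keep <- rep(TRUE, nrow(map))
  if (autosomesOnly) {
    sexChrom <- toupper(sub("^chr", "", map$chrom)) %in% c("X", "Y", "MT", "M", "XY")
    keep <- keep & !sexChrom
  }
  G <- dosages(geno)[, keep, drop = FALSE]  # samples x SNPs
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  if (!ncol(G)) stop("no polymorphic autosomal SNPs available for kinship")
  Z <- sweep(G, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(G))
  obs <- !is.na(Z)
  Z[!obs] <- 0
  num <- tcrossprod(Z)
  den <- tcrossprod(obs * 1)
  K <- num / pmax(den, 1)
  dimnames(K) <- list(rownames(G), rownames(G))
  new("KinshipMatrix", values = (K + t(K)) / 2, snpCount = ncol(G))
}
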