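#' Simulation configuration for synthetic half-sib cohorts
#'
#' Bundles all generator parameters with defaults emulating a paternal
#' half-sib pig cohort: several unrelated sires each mated to many dams, one
#' progeny per dam (so progeny of one sire are half sibs unless
#' \code{damsPerSire} is reduced below \code{progenyPerSire}, which creates
#' full-sib pairs). Expression is controlled by a known cis/trans
#' architecture on top of a polygenic background, and allele-specific read
#' counts are overdispersed binomial.
#'
#' @param nSires number of sires.
#' @param progenyPerSire progeny per sire; cohort size = nSires * progenyPerSire.
#' @param damsPerSire dams per sire; default = progenyPerSire (all half sibs).
#' @param nSnps total SNP count, split as evenly as possible across chromosomes.
#' @param nProbes number of experimental probes.
#' @param nChromosomes number of autosomes.
#' @param chromLengthBp chromosome length in bp.
#' @param mafRange range of generating minor allele frequencies, in (0, 0.5].
#' @param ldDecayRho latent AR(1) correlation between adjacent SNPs, in [0, 1).
#' @param h2Polygenic polygenic heritability of each probe, in [0, 1).
#' @param nCisEffects,nTransEffects number of cis / trans eQTL effects.
#' @param effectSizeSd effect size beta in phenotype-SD units (per alt-allele copy).
#' @param batchLevels number of batch levels (fixed-effect nuisance).
#' @param batchEffectSd SD of batch level effects, in phenotype-SD units.
#' @param sexEffectSd additive male-vs-female shift, in phenotype-SD units.
#' @param aseCoverageMean mean total read coverage per sample x site.
#' @param aseOverdispersion negative-binomial overdispersion of coverage
#'   (variance = mean + overdispersion * mean^2); 0 gives Poisson coverage.
#' @param aseImbalanceFraction expected alt-allele fraction at true-ASE sites,
#'   in (0,1) and != 0.5.
#' @param nNullAseSites number of designated null (balanced) ASE sites.
#' @param nNegativeControlProbes number of negative-control probes.
#' @param baselineIntensity baseline log2 intensity added to all probes.
#' @param backgroundOffset how far (log2 units) negative controls sit below
#'   the experimental baseline.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simConfig <- function(nSires = 10, progenyPerSire = 20, damsPerSire = progenyPerSire,
                      nSnps = 200, nProbes = 50, nChromosomes = 2,
                      chromLengthBp = 5e7, mafRange = c(0.1, 0.5),
                      ldDecayRho = 0.3, h2Polygenic = 0.3,
                      nCisEffects = 2, nTransEffects = 1, effectSizeSd = 1,
                      batchLevels = 2, batchEffectSd = 0.5, sexEffectSd = 0.3,
                      aseCoverageMean = 50, aseOverdispersion = 0.1,
                      aseImbalanceFraction = 0.8, nNullAseSites = 20,
                      nNegativeControlProbes = 10,
                      baselineIntensity = 8, backgroundOffset = 3, seed = 1L) {
  cfg <- list(nSires = nSires, progenyPerSire = progenyPerSire,
              damsPerSire = damsPerSire, nSnps = nSnps, nProbes = nProbes,
              nChromosomes = nChromosomes, chromLengthBp = chromLengthBp,
              mafRange = mafRange, ldDecayRho = ldDecayRho,
              h2Polygenic = h2Polygenic, nCisEffects = nCisEffects,
              nTransEffects = nTransEffects, effectSizeSd = effectSizeSd,
              batchLevels = batchLevels, batchEffectSd = batchEffectSd,
              sexEffectSd = sexEffectSd, aseCoverageMean = aseCoverageMean,
              aseOverdispersion = aseOverdispersion,
              aseImbalanceFraction = aseImbalanceFraction,
              nNullAseSites = nNullAseSites,
              nNegativeControlProbes = nNegativeControlProbes,
              baselineIntensity = baselineIntensity,
              backgroundOffset = backgroundOffset, seed = as.integer(seed))
  validateSimConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  counts <- c("nSires", "progenyPerSire", "damsPerSire", "nSnps", "nProbes",
              "nChromosomes", "batchLevels")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      stop("config field '", f, "' must be a positive count")
  if (cfg$nSnps < cfg$nChromosomes)
    stop("nSnps must be >= nChromosomes")
  if (cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5 ||
      cfg$mafRange[1] > cfg$mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  if (cfg$ldDecayRho < 0 || cfg$ldDecayRho >= 1)
    stop("ldDecayRho must be in [0, 1)")
  if (cfg$h2Polygenic < 0 || cfg$h2Polygenic >= 1)
    stop("h2Polygenic must be in [0, 1)")
  if (cfg$aseOverdispersion < 0) stop("aseOverdispersion must be >= 0")
  if (cfg$aseImbalanceFraction <= 0 || cfg$aseImbalanceFraction >= 1)
    stop("aseImbalanceFraction must be in (0, 1)")
  invisible(TRUE)
}

# one founder haplotype: latent AR(1) Gaussian copula thresholded at qnorm(p).
# Adjacent-SNP latent correlation rho induces (approximately) allele
# correlation rho; chromosomes are independent.
.simHaplotype <- function(p, chromIdx, rho) {
  m <- length(p)
  z <- numeric(m)
  eps <- rnorm(m)
  z[1] <- eps[1]
  if (m > 1) {
    newChrom <- c(TRUE, chromIdx[-1] != chromIdx[-m])
    for (k in 2:m) {
      z[k] <- if (newChrom[k]) eps[k] else rho * z[k - 1] + sqrt(1 - rho^2) * eps[k]
    }
    z[1] <- eps[1]
  }
  as.integer(z < qnorm(p))
}

# recombine two parental haplotypes into one gamete; Haldane map at 1 cM/Mb
.simGamete <- function(h1, h2, posBp, chromIdx) {
  m <- length(h1)
  d <- c(Inf, diff(posBp))
  d[c(TRUE, chromIdx[-1] != chromIdx[-m])[seq_len(m)]] <- Inf
  rProb <- 0.5 * (1 - exp(-2 * d / 1e8))  # Morgans = bp / 1e8
  rProb[!is.finite(d)] <- 0.5             # independent assortment across chromosomes
  switch_ <- runif(m) < rProb
  phase <- cumsum(switch_) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate half-sib genotypes
#'
#' Draws founder haplotypes under a first-order Gaussian-copula LD model,
#' builds diploid sires and dams, and generates progeny by Mendelian gamete
#' sampling with per-interval recombination (Haldane, 1 cM/Mb). Each sire's
#' progeny are half sibs through the sire; progeny sharing a dam (when
#' \code{damsPerSire < progenyPerSire}) are full sibs.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return List with \code{geno} (a \linkS4class{GenotypeExperiment} of the
#'   progeny) and \code{pedigree} (data.frame id, sire, dam).
#' @export
simulateGenotypes <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  n <- config$nSires * config$progenyPerSire
  m <- config$nSnps
  perChrom <- diff(round(seq(0, m, length.out = config$nChromosomes + 1)))
  chromIdx <- rep(seq_len(config$nChromosomes), perChrom)
  pos <- unlist(lapply(perChrom, function(k)
    sort(sample.int(config$chromLengthBp - 1, k))), use.names = FALSE)
  p <- runif(m, config$mafRange[1], config$mafRange[2])  # alt = minor allele

  rho <- config$ldDecayRho
  sireHaps <- lapply(seq_len(config$nSires), function(i)
    list(.simHaplotype(p, chromIdx, rho), .simHaplotype(p, chromIdx, rho)))
  nDams <- config$nSires * config$damsPerSire
  damHaps <- lapply(seq_len(nDams), function(i)
    list(.simHaplotype(p, chromIdx, rho), .simHaplotype(p, chromIdx, rho)))

  dosage <- matrix(0L, nrow = m, ncol = n)
  ped <- data.frame(id = character(n), sire = character(n), dam = character(n),
                    stringsAsFactors = FALSE)
  k <- 0L
  for (s in seq_len(config$nSires)) {
    for (j in seq_len(config$progenyPerSire)) {
      k <- k + 1L
      damLocal <- ((j - 1L) %% config$damsPerSire) + 1L
      damIdx <- (s - 1L) * config$damsPerSire + damLocal
      gs <- .simGamete(sireHaps[[s]][[1]], sireHaps[[s]][[2]], pos, chromIdx)
      gd <- .simGamete(damHaps[[damIdx]][[1]], damHaps[[damIdx]][[2]], pos, chromIdx)
      dosage[, k] <- gs + gd
      ped$id[k] <- sprintf("ind%03d", k)
      ped$sire[k] <- sprintf("sire%02d", s)
      ped$dam[k] <- sprintf("dam%03d", damIdx)
    }
  }
  colnames(dosage) <- ped$id
  snpIds <- sprintf("snp%04d", seq_len(m))
  rownames(dosage) <- snpIds
  map <- data.frame(snp = snpIds, chrom = as.character(chromIdx),
                    pos = as.integer(pos),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  sex <- rep_len(c("M", "F"), n)
  geno <- GenotypeExperiment(dosage, map,
                             sampleData = data.frame(sex = sex, row.names = ped$id),
                             sort = FALSE)
  metadata(geno)$generating_maf <- stats::setNames(p, snpIds)
  list(geno = geno, pedigree = ped)
}

#' Draw a cis/trans architecture compatible with a genotype set
#'
#' Selects cis pairs (SNP within 1 Mb of the probe start, same chromosome),
#' trans pairs (different chromosome), and designates true-ASE sites among
#' the cis SNPs. Probe starts are placed near their cis SNP; remaining
#' mapped probes are scattered uniformly.
#'
#' @param geno a GenotypeExperiment.
#' @param config a \code{\link{simConfig}}.
#' @return List of class \code{"TrueArchitecture"}: \code{cis}, \code{trans}
#'   (data.frames snp, probe, beta), \code{aseSites} (data.frame snp, gene,
#'   altFraction), \code{probeAnnotation} (data.frame), \code{h2}.
#' @export
simulateArchitecture <- function(geno, config) {
  validateSimConfig(config)
  set.seed(config$seed + 1L)
  map <- snpMap(geno)
  nP <- config$nProbes
  if (config$nCisEffects + config$nTransEffects > nP)
    stop("more effects than probes")
  probes <- sprintf("probe%04d", seq_len(nP))
  genes <- sprintf("GENE%04d", seq_len(nP))
  chrom <- sample(unique(map$chrom), nP, replace = TRUE)
  start <- sapply(chrom, function(ch) sample.int(config$chromLengthBp, 1))

  effSnps <- sample(map$snp, config$nCisEffects + config$nTransEffects)
  cisIdx <- seq_len(config$nCisEffects)
  cis <- trans <- data.frame(snp = character(0), probe = character(0),
                             beta = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_along(effSnps)) {
    snp <- effSnps[i]
    srow <- map[map$snp == snp, ]
    probe <- probes[i]
    if (i %in% cisIdx) {
      chrom[i] <- srow$chrom
      off <- sample(-5e5:5e5, 1)
      start[i] <- min(max(1, srow$pos + off), config$chromLengthBp)
      cis <- rbind(cis, data.frame(snp = snp, probe = probe,
                                   beta = config$effectSizeSd,
                                   stringsAsFactors = FALSE))
    } else {
      others <- setdiff(unique(map$chrom), srow$chrom)
      if (length(others)) chrom[i] <- sample(others, 1)
      trans <- rbind(trans, data.frame(snp = snp, probe = probe,
                                       beta = config$effectSizeSd,
                                       stringsAsFactors = FALSE))
    }
  }
  aseSites <- if (nrow(cis)) {
    data.frame(snp = cis$snp, gene = genes[match(cis$probe, probes)],
               altFraction = config$aseImbalanceFraction,
               stringsAsFactors = FALSE)
  } else data.frame(snp = character(0), gene = character(0),
                    altFraction = numeric(0))
  pa <- data.frame(probe = probes, chrom = as.character(chrom),
                   start = as.integer(start), strand = "+", gene = genes,
                   probe_class = "experimental", stringsAsFactors = FALSE)
  if (config$nNegativeControlProbes > 0) {
    nc <- data.frame(probe = sprintf("negctrl%03d", seq_len(config$nNegativeControlProbes)),
                     chrom = NA_character_, start = NA_integer_,
                     strand = NA_character_, gene = NA_character_,
                     probe_class = "negative_control", stringsAsFactors = FALSE)
    pa <- rbind(pa, nc)
  }
  arch <- list(cis = cis, trans = trans, aseSites = aseSites,
               probeAnnotation = pa, h2 = config$h2Polygenic)
  class(arch) <- "TrueArchitecture"
  arch
}

#' Simulate probe expression under a known architecture
#'
#' Generates \code{y = mu + batch + sex + sum(beta * g) + u + e} per probe,
#' with polygenic values \code{u ~ N(0, h2 * K)} (K the genomic kinship of
#' the simulated cohort) and residuals \code{e ~ N(0, (1 - h2) I)}, so each
#' probe's non-fixed variance is 1 and effect sizes are in SD units.
#' Negative-control probes are pure noise at background intensity.
#'
#' @param geno a GenotypeExperiment.
#' @param arch a TrueArchitecture from \code{\link{simulateArchitecture}}.
#' @param config a \code{\link{simConfig}}.
#' @return An \linkS4class{ExpressionExperiment} with covariates (batch, sex)
#'   in \code{colData}.
#' @export
simulateExpression <- function(geno, arch, config) {
  validateSimConfig(config)
  stopifnot(inherits(arch, "TrueArchitecture"))
  set.seed(config$seed + 2L)
  G <- dosages(geno)          # samples x SNPs
  n <- nrow(G)
  pa <- arch$probeAnnotation
  badSnp <- setdiff(c(arch$cis$snp, arch$trans$snp), colnames(G))
  if (length(badSnp))
    stop("architecture references unknown SNP id(s): ",
         paste(badSnp, collapse = ", "))
  badProbe <- setdiff(c(arch$cis$probe, arch$trans$probe), pa$probe)
  if (length(badProbe))
    stop("architecture references unknown probe id(s): ",
         paste(badProbe, collapse = ", "))

  # contiguous blocks, so batch is not confounded with the alternating sex
  batch <- factor(rep(paste0("batch", seq_len(config$batchLevels)),
                      each = ceiling(n / config$batchLevels), length.out = n))
  batchEff <- rnorm(config$batchLevels, 0, config$batchEffectSd)
  sex <- colData(geno)$sex
  if (is.null(sex)) sex <- rep_len(c("M", "F"), n)
  sexEff <- ifelse(sex == "M", config$sexEffectSd / 2, -config$sexEffectSd / 2)

  h2 <- config$h2Polygenic
  nProbesTotal <- nrow(pa)
  E <- matrix(0, nrow = n, ncol = nProbesTotal,
              dimnames = list(rownames(G), pa$probe))
  if (h2 > 0) {
    K <- computeGenomicKinship(geno)
    ev <- eigen(K@values, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    Khalf <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  }
  exprIdx <- which(pa$probe_class == "experimental")
  for (j in exprIdx) {
    u <- if (h2 > 0) sqrt(h2) * as.vector(Khalf %*% rnorm(n)) else 0
    e <- rnorm(n, 0, sqrt(1 - h2))
    E[, j] <- config$baselineIntensity + batchEff[as.integer(batch)] + sexEff + u + e
  }
  for (tab in list(arch$cis, arch$trans)) {
    if (nrow(tab)) for (i in seq_len(nrow(tab))) {
      j <- match(tab$probe[i], pa$probe)
      E[, j] <- E[, j] + tab$beta[i] * G[, tab$snp[i]]
    }
  }
  ncIdx <- which(pa$probe_class == "negative_control")
  for (j in ncIdx)
    E[, j] <- rnorm(n, config$baselineIntensity - config$backgroundOffset, 1)

  ExpressionExperiment(t(E), pa,
                       sampleData = data.frame(batch = batch, sex = sex,
                                               row.names = rownames(G)))
}

#' Simulate allele-specific read counts
#'
#' For every sample x site in the designated site set (all true-ASE sites
#' plus \code{nNullAseSites} balanced sites), draws total coverage from a
#' negative binomial (mean \code{aseCoverageMean}, variance
#' \code{mean + overdispersion * mean^2}) and, for heterozygous samples, alt
#' counts from Binomial(total, altFraction) — altFraction = 0.5 at null
#' sites. Homozygous samples emit single-allele counts.
#'
#' @param geno a GenotypeExperiment.
#' @param arch a TrueArchitecture.
#' @param config a \code{\link{simConfig}}.
#' @return data.frame (sample, contig, position, ref, alt, refCount,
#'   altCount, genotype) in ASEReadCounter-like column order.
#' @export
simulateAlleleCounts <- function(geno, arch, config) {
  validateSimConfig(config)
  set.seed(config$seed + 3L)
  map <- snpMap(geno)
  G <- dosages(geno)
  nullCandidates <- setdiff(map$snp, arch$aseSites$snp)
  nNull <- min(config$nNullAseSites, length(nullCandidates))
  nullSnps <- sample(nullCandidates, nNull)
  sites <- data.frame(snp = c(arch$aseSites$snp, nullSnps),
                      altFraction = c(arch$aseSites$altFraction,
                                      rep(0.5, nNull)),
                      stringsAsFactors = FALSE)
  mu <- config$aseCoverageMean
  disp <- config$aseOverdispersion
  drawCoverage <- function(k) {
    if (disp > 0) rnbinom(k, size = 1 / disp, mu = mu) else rpois(k, mu)
  }
  out <- vector("list", nrow(sites))
  samples <- rownames(G)
  for (i in seq_len(nrow(sites))) {
    srow <- map[map$snp == sites$snp[i], ]
    g <- G[, sites$snp[i]]
    tot <- drawCoverage(length(g))
    altc <- integer(length(g))
    het <- !is.na(g) & g == 1L
    altc[het] <- rbinom(sum(het), tot[het], sites$altFraction[i])
    altc[!is.na(g) & g == 2L] <- tot[!is.na(g) & g == 2L]
    gcall <- c("hom_ref", "het", "hom_alt")[g + 1L]
    gcall[is.na(g)] <- "missing"
    out[[i]] <- data.frame(sample = samples, contig = srow$chrom,
                           position = srow$pos, ref = srow$ref, alt = srow$alt,
                           refCount = tot - altc, altCount = altc,
                           genotype = gcall, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  counts
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running \code{\link{simulateGenotypes}},
#' \code{\link{simulateArchitecture}}, \code{\link{simulateExpression}} and
#' \code{\link{simulateAlleleCounts}} under one seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List with \code{geno}, \code{pedigree}, \code{arch}, \code{expr},
#'   \code{alleleCounts}, \code{config}.
#' @export
simulateCohort <- function(config = simConfig()) {
  gp <- simulateGenotypes(config)
  arch <- simulateArchitecture(gp$geno, config)
  expr <- simulateExpression(gp$geno, arch, config)
  counts <- simulateAlleleCounts(gp$geno, arch, config)
  list(geno = gp$geno, pedigree = gp$pedigree, arch = arch, expr = expr,
       alleleCounts = counts, config = config)
}
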