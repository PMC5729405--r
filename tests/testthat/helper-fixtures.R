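# Small builders shared across test files. Everything is generated in code;
# seeds are fixed so fixtures are reproducible.

toyGenotypes <- function(dosage, chrom = NULL, pos = NULL) {
  # dosage: samples x SNPs matrix
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  snps <- paste0("s", seq_len(m))
  colnames(dosage) <- snps
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  GenotypeExperiment(t(dosage),
                     data.frame(snp = snps, chrom = chrom, pos = pos,
                                ref = "A", alt = "G", stringsAsFactors = FALSE),
                     sort = FALSE)
}

toyExpression <- function(values, chrom = NULL, start = NULL, gene = NULL,
                          probe_class = NULL, batch = NULL, sex = NULL) {
  # values: samples x probes
  k <- ncol(values)
  probes <- paste0("p", seq_len(k))
  colnames(values) <- probes
  if (is.null(rownames(values))) rownames(values) <- paste0("i", seq_len(nrow(values)))
  pa <- data.frame(probe = probes,
                   chrom = if (is.null(chrom)) rep("1", k) else chrom,
                   start = if (is.null(start)) seq_len(k) * 1000L else start,
                   strand = "+",
                   gene = if (is.null(gene)) paste0("G", seq_len(k)) else gene,
                   probe_class = if (is.null(probe_class)) "experimental" else probe_class,
                   stringsAsFactors = FALSE)
  sd <- data.frame(row.names = rownames(values))
  if (!is.null(batch)) sd$batch <- batch
  if (!is.null(sex)) sd$sex <- sex
  ExpressionExperiment(t(values), pa, sampleData = if (ncol(sd)) sd else NULL)
}

# one allele-count row set for a single site over samples
toyCounts <- function(sample, refCount, altCount, genotype,
                      contig = "1", position = 100L, ref = "A", alt = "G") {
  data.frame(sample = sample, contig = contig, position = position,
             ref = ref, alt = alt, refCount = refCount, altCount = altCount,
             genotype = genotype, stringsAsFactors = FALSE)
}

# independent OLS score-test oracle: residualize y and g on X by lm,
# T = (sum(gr * yr))^2 / (sigma2_0 * sum(gr^2)), sigma2_0 = RSS/(n - p)
olsScoreOracle <- function(y, g, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  yr <- lm.fit(X, y)$residuals
  gr <- lm.fit(X, g)$residuals
  sigma2 <- sum(yr^2) / (n - ncol(X))
  T <- sum(gr * yr)^2 / (sigma2 * sum(gr^2))
  pchisq(T, 1, lower.tail = FALSE)
}

# identity kinship for toy fixtures with too few SNPs for a genomic estimate
idKinship <- function(geno) {
  ids <- colnames(geno)
  new("KinshipMatrix", values = diag(length(ids)) |>
        `dimnames<-`(list(ids, ids)), snpCount = 0L)
}

# brute-force connected components by flood fill on an undirected edge list
floodFillComponents <- function(nodes, from, to) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- c(to[from == v], from[to == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# brute-force PCIT oracle: naive triple loop, written independently
pcitBruteForce <- function(r) {
  nv <- ncol(r)
  keep <- matrix(TRUE, nv, nv)
  for (i in seq_len(nv)) for (j in seq_len(nv)) for (k in seq_len(nv)) {
    if (i >= j || k == i || k == j) next
    rij <- r[i, j]; rik <- r[i, k]; rjk <- r[j, k]
    if (max(abs(c(rij, rik, rjk))) >= 1 - 1e-12) next
    pc <- function(a, b, c_) (a - b * c_) / sqrt((1 - b^2) * (1 - c_^2))
    eps <- (pc(rij, rik, rjk) / rij + pc(rik, rij, rjk) / rik +
              pc(rjk, rij, rik) / rjk) / 3
    if (abs(rij) <= abs(eps * rik) && abs(rij) <= abs(eps * rjk))
      keep[i, j] <- keep[j, i] <- FALSE
  }
  diag(keep) <- TRUE
  keep
}

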