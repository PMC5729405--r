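#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Filter allele-count entries and sites
#'
#' Applies, in order: per-entry read-depth filter (ref + alt must reach
#' \code{minReads}), a cohort-wide minor allele count filter (sites whose
#' total reads supporting the rarer allele do not exceed \code{minMac} are
#' dropped — strict inequality), and a biallelic filter (a site observed
#' with more than one ref or alt allele is dropped).
#'
#' @param counts data.frame with columns sample, contig, position, ref, alt,
#'   refCount, altCount, genotype (ASEReadCounter-like).
#' @param minReads minimum reads per sample x site entry (default 10).
#' @param minMac cohort-wide minor allele count bound, strict (default 3).
#' @return List with \code{counts} (filtered data.frame) and
#'   \code{registry} (data.frame site, reason for each exclusion).
#' @export
filterAseSites <- function(counts, minReads = 10, minMac = 3) {
  need <- c("sample", "contig", "position", "ref", "alt", "refCount",
            "altCount", "genotype")
  miss <- setdiff(need, colnames(counts))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(counts$refCount < 0 | counts$altCount < 0))
    stop("negative read counts")
  siteKey <- paste(counts$contig, counts$position, sep = ":")
  registry <- data.frame(site = character(0), reason = character(0),
                         stringsAsFactors = FALSE)

  depth <- counts$refCount + counts$altCount
  lowDepth <- depth < minReads
  if (any(lowDepth))
    registry <- rbind(registry,
                      data.frame(site = unique(siteKey[lowDepth]),
                                 reason = "entries_below_min_reads",
                                 stringsAsFactors = FALSE))
  counts <- counts[!lowDepth, , drop = FALSE]
  siteKey <- siteKey[!lowDepth]

  if (nrow(counts)) {
    nAlleles <- tapply(seq_len(nrow(counts)), siteKey, function(ix)
      length(unique(counts$ref[ix])) > 1 || length(unique(counts$alt[ix])) > 1)
    multi <- names(nAlleles)[nAlleles]
    if (length(multi)) {
      registry <- rbind(registry, data.frame(site = multi,
                                             reason = "non_biallelic",
                                             stringsAsFactors = FALSE))
      keep <- !(siteKey %in% multi)
      counts <- counts[keep, , drop = FALSE]
      siteKey <- siteKey[keep]
    }
  }
  if (nrow(counts)) {
    mac <- tapply(seq_len(nrow(counts)), siteKey, function(ix)
      min(sum(counts$refCount[ix]), sum(counts$altCount[ix])))
    lowMac <- names(mac)[!(mac > minMac)]
    if (length(lowMac)) {
      registry <- rbind(registry, data.frame(site = lowMac,
                                             reason = "minor_allele_count",
                                             stringsAsFactors = FALSE))
      keep <- !(siteKey %in% lowMac)
      counts <- counts[keep, , drop = FALSE]
    }
  }
  rownames(counts) <- NULL
  list(counts = counts, registry = registry)
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests alt ~ Binomial(ref + alt, 0.5). The two-sided p-value sums the
#' probabilities of all outcomes no more probable than the observed one
#' (the "minlike" convention of the exact binomial test).
#'
#' @param refCount,altCount non-negative read counts (vectors recycled).
#' @return numeric vector of p-values.
#' @export
binomialAseTest <- function(refCount, altCount) {
  if (any(refCount < 0 | altCount < 0)) stop("negative read counts")
  mapply(function(r, a) {
    n <- r + a
    if (n < 1) return(NA_real_)
    probs <- dbinom(0:n, n, 0.5)
    obs <- probs[a + 1]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, refCount, altCount)
}

#' Per-animal FDR correction
#'
#' Benjamini-Hochberg step-up within one animal's tested heterozygous
#' sites; a site is flagged significant iff its q-value is at or below
#' \code{alpha}.
#'
#' @param p numeric vector of one animal's binomial p-values.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with \code{q} and \code{significant}.
#' @export
perAnimalFdr <- function(p, alpha = 0.05) {
  if (!length(p)) return(data.frame(q = numeric(0), significant = logical(0)))
  q <- p.adjust(p, method = "BH")
  data.frame(q = q, significant = !is.na(q) & q <= alpha)
}

#' Call ASE-SNPs from filtered allele counts
#'
#' Runs the exact binomial test on every heterozygous sample x site entry,
#' corrects p-values per animal (BH at \code{alpha}), and aggregates across
#' animals: a site is an ASE-SNP iff significant animals exceed
#' \code{hetFraction} of its heterozygous animals (strict inequality by
#' default). Sites with no heterozygous animal are untestable (NA verdict).
#'
#' @param counts filtered allele-count data.frame
#'   (\code{\link{filterAseSites}}).
#' @param alpha per-animal FDR level (default 0.05).
#' @param hetFraction aggregation threshold on the significant fraction
#'   (default 1/3).
#' @param strict require strictly greater than \code{hetFraction} (default
#'   TRUE, per the aggregation rule; FALSE uses >=).
#' @return List with \code{calls} (data.frame contig, position, ref, alt,
#'   n_het, n_significant, is_ase) and \code{perAnimal} (entry-level
#'   data.frame with p, q, significant for heterozygous entries).
#' @export
aggregateAse <- function(counts, alpha = 0.05, hetFraction = 1 / 3,
                         strict = TRUE) {
  het <- counts[counts$genotype == "het", , drop = FALSE]
  if (nrow(het)) {
    het$p <- binomialAseTest(het$refCount, het$altCount)
    het$q <- NA_real_
    het$significant <- FALSE
    for (s in unique(het$sample)) {
      ix <- which(het$sample == s)
      fdr <- perAnimalFdr(het$p[ix], alpha = alpha)
      het$q[ix] <- fdr$q
      het$significant[ix] <- fdr$significant
    }
  } else {
    het$p <- het$q <- numeric(0)
    het$significant <- logical(0)
  }
  siteKey <- unique(counts[, c("contig", "position", "ref", "alt")])
  hk <- paste(het$contig, het$position, sep = ":")
  sk <- paste(siteKey$contig, siteKey$position, sep = ":")
  calls <- data.frame(siteKey,
                      n_het = as.integer(table(factor(hk, levels = sk))),
                      stringsAsFactors = FALSE)
  nSig <- tapply(het$significant, factor(hk, levels = sk), sum)
  calls$n_significant <- as.integer(ifelse(is.na(nSig), 0L, nSig))
  frac <- calls$n_significant / calls$n_het
  calls$is_ase <- ifelse(calls$n_het == 0, NA,
                         if (strict) frac > hetFraction else frac >= hetFraction)
  rownames(calls) <- NULL
  list(calls = calls, perAnimal = het)
}

#' Map ASE sites to genes and build the detectable-gene universe
#'
#' Assigns each site to every overlapping gene interval (1-based inclusive,
#' strand-agnostic). The detectable universe is the set of expressed genes
#' (at least \code{minGeneReads} reads in at least one sample) that overlap
#' at least one heterozygous tested site. A gene is an ASE-gene iff it
#' contains at least one ASE-SNP.
#'
#' @param calls site-level calls from \code{\link{aggregateAse}}.
#' @param geneIntervals data.frame with columns gene, contig, start, end
#'   (1-based inclusive).
#' @param geneReads named numeric vector or genes x samples matrix of gene
#'   read counts used for the expressed-gene rule; a vector is taken as the
#'   per-gene maximum over samples.
#' @param minGeneReads expression threshold (default 10).
#' @return List with \code{siteGenes} (site-to-gene assignments),
#'   \code{aseGenes} (data.frame gene, n_ase_snps, is_ase), and
#'   \code{universe} (character vector of detectable genes).
#' @export
mapSitesToGenes <- function(calls, geneIntervals, geneReads,
                            minGeneReads = 10) {
  stopifnot(all(c("gene", "contig", "start", "end") %in% colnames(geneIntervals)))
  if (any(geneIntervals$end < geneIntervals$start))
    stop("malformed gene interval (end < start)")
  maxReads <- if (is.matrix(geneReads)) {
    apply(geneReads, 1, max)
  } else geneReads
  expressed <- names(maxReads)[maxReads >= minGeneReads]

  gr <- GRanges(geneIntervals$contig,
                IRanges(geneIntervals$start, geneIntervals$end))
  sr <- GRanges(calls$contig, IRanges(calls$position, calls$position))
  hits <- findOverlaps(sr, gr, ignore.strand = TRUE)
  siteGenes <- data.frame(contig = calls$contig[queryHits(hits)],
                          position = calls$position[queryHits(hits)],
                          gene = geneIntervals$gene[subjectHits(hits)],
                          is_ase = calls$is_ase[queryHits(hits)],
                          tested = calls$n_het[queryHits(hits)] > 0,
                          stringsAsFactors = FALSE)
  withHet <- unique(siteGenes$gene[siteGenes$tested])
  universe <- intersect(expressed, withHet)

  aseBySite <- siteGenes[!is.na(siteGenes$is_ase) & siteGenes$is_ase, ,
                         drop = FALSE]
  nAse <- table(aseBySite$gene)
  genes <- unique(siteGenes$gene)
  aseGenes <- data.frame(gene = genes,
                         n_ase_snps = as.integer(nAse[genes]),
                         stringsAsFactors = FALSE)
  aseGenes$n_ase_snps[is.na(aseGenes$n_ase_snps)] <- 0L
  aseGenes$is_ase <- aseGenes$n_ase_snps > 0
  list(siteGenes = siteGenes, aseGenes = aseGenes, universe = universe)
}

#' End-to-end ASE calling
#'
#' Convenience wrapper: \code{\link{filterAseSites}} then
#' \code{\link{aggregateAse}}, optionally followed by
#' \code{\link{mapSitesToGenes}}.
#'
#' @param counts raw allele-count data.frame.
#' @param geneIntervals,geneReads optional gene mapping inputs.
#' @param minReads,minMac,alpha,hetFraction,strict,minGeneReads see the
#'   component functions.
#' @return List combining the component outputs: \code{counts},
#'   \code{registry}, \code{calls}, \code{perAnimal}, and (when gene inputs
#'   are given) \code{siteGenes}, \code{aseGenes}, \code{universe}.
#' @export
runAse <- function(counts, geneIntervals = NULL, geneReads = NULL,
                   minReads = 10, minMac = 3, alpha = 0.05,
                   hetFraction = 1 / 3, strict = TRUE, minGeneReads = 10) {
  filt <- filterAseSites(counts, minReads = minReads, minMac = minMac)
  agg <- aggregateAse(filt$counts, alpha = alpha, hetFraction = hetFraction,
                      strict = strict)
  out <- c(filt, agg)
  if (!is.null(geneIntervals) && !is.null(geneReads)) {
    out <- c(out, mapSitesToGenes(agg$calls, geneIntervals, geneReads,
                                  minGeneReads = minGeneReads))
  }
  out
}

#' Integrate eGWAS and ASE results at the gene level
#'
#' Flags each gene for local eQTL, distant eQTL, and ASE evidence, and
#' assigns a category: \code{cis_validated} (local eQTL + ASE),
#' \code{cis_trans_candidate} (distant eQTL + ASE; subcategory flag
#' \code{distant_other_chrom} when the distant eQTL-SNP is on another
#' chromosome than the gene), \code{egwas_only}, \code{ase_only}.
#'
#' @param eqtl classified eQTL table (\code{\link{classifyLocalDistant}})
#'   with a \code{gene} column (add via probe annotation).
#' @param aseGenes ASE gene table (\code{\link{mapSitesToGenes}}).
#' @param geneChrom optional named vector gene -> chromosome for the
#'   other-chromosome subcategory.
#' @return data.frame per gene: flags \code{local_eqtl},
#'   \code{distant_eqtl}, \code{ase}, \code{distant_other_chrom},
#'   \code{category}; attribute \code{counts} is the category count table.
#' @export
integrateEgwasAse <- function(eqtl, aseGenes, geneChrom = NULL) {
  stopifnot("gene" %in% colnames(eqtl))
  eq <- eqtl[!is.na(eqtl$gene), , drop = FALSE]
  aseSet <- aseGenes$gene[aseGenes$is_ase]
  genes <- union(unique(eq$gene), aseSet)
  if (!length(genes))
    return(data.frame(gene = character(0), local_eqtl = logical(0),
                      distant_eqtl = logical(0), ase = logical(0),
                      distant_other_chrom = logical(0),
                      category = character(0), stringsAsFactors = FALSE))
  localSet <- unique(eq$gene[eq$regulation %in% "local"])
  distantSet <- unique(eq$gene[eq$regulation %in% "distant"])
  otherChrom <- if (!is.null(geneChrom)) {
    unique(eq$gene[eq$regulation %in% "distant" &
                     eq$chrom != geneChrom[eq$gene]])
  } else character(0)
  out <- data.frame(gene = genes,
                    local_eqtl = genes %in% localSet,
                    distant_eqtl = genes %in% distantSet,
                    ase = genes %in% aseSet,
                    distant_other_chrom = genes %in% otherChrom,
                    stringsAsFactors = FALSE)
  out$category <- ifelse(out$ase & out$local_eqtl, "cis_validated",
                  ifelse(out$ase & out$distant_eqtl, "cis_trans_candidate",
                  ifelse(out$local_eqtl | out$distant_eqtl, "egwas_only",
                         "ase_only")))
  attr(out, "counts") <- table(out$category)
  out
}
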