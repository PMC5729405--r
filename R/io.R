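#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom tools md5sum
NULL

# provenance header lines for an output TSV
.provenanceHeader <- function(config = NULL, seed = NULL) {
  c(sprintf("# polyQTL %s", as.character(packageVersion("polyQTL"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config)) sprintf("# config_hash: %s", configHash(config)))
}

#' Hash a configuration object
#'
#' Stable md5 of the deparsed configuration, used in provenance headers.
#'
#' @param config any R object.
#' @return character md5 hash.
#' @export
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(md5sum(f))
}

#' Write a table with a provenance header
#'
#' @param x data.frame.
#' @param path output path.
#' @param config,seed optional provenance fields.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(config, seed), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headered table
#'
#' @param path file path; leading \code{#} lines are skipped.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read genotypes from TSV or PLINK ped/map files
#'
#' The TSV dialect expects a dosage table (first column \code{sample}, one
#' column per SNP, values 0/1/2/NA) plus a SNP map TSV (columns snp, chrom,
#' pos, optionally ref, alt). The ped/map dialect reads PLINK text files:
#' allele pairs are recoded to dosages counting the minor allele.
#'
#' @param path dosage TSV or .ped path.
#' @param mapPath SNP map TSV or .map path.
#' @param dialect \code{"tsv"} or \code{"ped_map"}.
#' @return A \linkS4class{GenotypeExperiment}, SNPs sorted by (chrom, pos).
#' @export
readGenotypes <- function(path, mapPath, dialect = c("tsv", "ped_map")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(mapPath)) stop("file not found: ", mapPath)
  if (dialect == "tsv") {
    tab <- readTsv(path)
    if (colnames(tab)[1] != "sample")
      stop("genotype TSV must have 'sample' as its first column")
    if (anyDuplicated(tab$sample))
      stop("duplicate sample id: ",
           paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
    map <- readTsv(mapPath)
    d <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(!(is.na(d) | d %in% 0:2), arr.ind = TRUE)
    if (nrow(bad))
      stop("malformed dosage at line ", bad[1, 1] + 1, ", column '",
           colnames(d)[bad[1, 2]], "': ", d[bad[1, , drop = FALSE]])
    rownames(d) <- tab$sample
    missingSnps <- setdiff(colnames(d), map$snp)
    if (length(missingSnps))
      stop("SNP(s) absent from map: ", paste(head(missingSnps, 5), collapse = ", "))
    GenotypeExperiment(t(d[, map$snp, drop = FALSE]), map)
  } else {
    map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(map) < 4) stop("malformed .map: need 4 columns")
    colnames(map)[1:4] <- c("chrom", "snp", "cm", "pos")
    if (anyDuplicated(map$snp))
      stop("duplicate SNP id in .map: ",
           paste(unique(map$snp[duplicated(map$snp)]), collapse = ", "))
    ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    nFix <- 6
    m <- nrow(map)
    if (ncol(ped) != nFix + 2 * m)
      stop("malformed .ped: expected ", nFix + 2 * m, " columns, got ", ncol(ped))
    ids <- as.character(ped[[2]])
    if (anyDuplicated(ids))
      stop("duplicate sample id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
    a1 <- as.matrix(ped[, nFix + 2 * seq_len(m) - 1, drop = FALSE])
    a2 <- as.matrix(ped[, nFix + 2 * seq_len(m), drop = FALSE])
    d <- matrix(NA_integer_, nrow = length(ids), ncol = m,
                dimnames = list(ids, map$snp))
    ref <- alt <- character(m)
    for (k in seq_len(m)) {
      al <- c(a1[, k], a2[, k])
      obs <- al[al != "0"]
      alleles <- sort(unique(obs))
      if (length(alleles) > 2)
        stop("SNP ", map$snp[k], " has >2 alleles in .ped")
      counts <- table(factor(obs, levels = alleles))
      minor <- if (length(alleles) == 2) names(which.min(counts)) else alleles[1]
      major <- setdiff(alleles, minor)
      if (!length(major)) major <- minor
      ref[k] <- major[1]; alt[k] <- minor
      ok <- a1[, k] != "0" & a2[, k] != "0"
      d[ok, k] <- (a1[ok, k] == minor) + (a2[ok, k] == minor)
    }
    sex <- c("1" = "M", "2" = "F")[as.character(ped[[5]])]
    GenotypeExperiment(t(d),
                       data.frame(snp = map$snp, chrom = as.character(map$chrom),
                                  pos = map$pos, ref = ref, alt = alt,
                                  stringsAsFactors = FALSE),
                       sampleData = data.frame(sex = sex, row.names = ids))
  }
}

#' Write genotypes and SNP map as TSV
#'
#' @param geno a GenotypeExperiment.
#' @param path,mapPath output paths for dosages and SNP map.
#' @param config,seed provenance fields.
#' @return invisible NULL.
#' @export
writeGenotypes <- function(geno, path, mapPath, config = NULL, seed = NULL) {
  d <- dosages(geno)
  tab <- data.frame(sample = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  writeTsv(tab, path, config, seed)
  writeTsv(snpMap(geno), mapPath, config, seed)
  invisible(NULL)
}

#' Read an expression matrix with probe annotation
#'
#' @param path expression TSV (first column \code{sample}, one column per
#'   probe).
#' @param annotationPath probe annotation TSV (columns probe, chrom, start,
#'   strand, gene, probe_class; unmapped fields may be NA).
#' @return An \linkS4class{ExpressionExperiment}.
#' @export
readExpression <- function(path, annotationPath) {
  tab <- readTsv(path)
  if (colnames(tab)[1] != "sample")
    stop("expression TSV must have 'sample' as its first column")
  pa <- readTsv(annotationPath)
  e <- as.matrix(tab[, -1, drop = FALSE])
  rownames(e) <- tab$sample
  ExpressionExperiment(t(e), pa)
}

#' Write an expression matrix and its probe annotation
#'
#' @param expr an ExpressionExperiment.
#' @param path,annotationPath output paths.
#' @param config,seed provenance fields.
#' @return invisible NULL.
#' @export
writeExpression <- function(expr, path, annotationPath, config = NULL,
                            seed = NULL) {
  e <- intensities(expr)
  writeTsv(data.frame(sample = rownames(e), e, check.names = FALSE),
           path, config, seed)
  writeTsv(probeAnnotation(expr), annotationPath, config, seed)
  invisible(NULL)
}

#' Read an allele-count table
#'
#' @param path TSV with ASEReadCounter-like columns (sample, contig,
#'   position, ref, alt, refCount, altCount, genotype).
#' @return data.frame.
#' @export
readAlleleCounts <- function(path) {
  tab <- readTsv(path)
  need <- c("sample", "contig", "position", "ref", "alt", "refCount",
            "altCount", "genotype")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("allele-count table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab$contig <- as.character(tab$contig)
  tab
}

#' Export ASE-SNP sites as minimal VCF
#'
#' Writes a VCFv4.2 file of the site coordinates and alleles of ASE-SNPs,
#' with the significant/heterozygous animal counts as INFO fields.
#'
#' @param calls site-level calls (\code{\link{aggregateAse}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAseVcf <- function(calls, path) {
  ase <- calls[!is.na(calls$is_ase) & calls$is_ase, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=NHET,Number=1,Type=Integer,Description=\"Heterozygous animals\">",
               "##INFO=<ID=NSIG,Number=1,Type=Integer,Description=\"Animals with significant imbalance\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(ase))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNHET=%d;NSIG=%d",
                       ase$contig, ase$position, ase$ref, ase$alt,
                       ase$n_het, ase$n_significant), con)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Serializes a \code{\link{simulateCohort}} result: genotypes + SNP map,
#' expression + probe annotation, covariates, allele counts, and the ground
#' truth (JSON).
#'
#' @param cohort list from \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort$config
  seed <- cfg$seed
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             snp_map = file.path(dir, "snp_map.tsv"),
             expression = file.path(dir, "expression.tsv"),
             probe_annotation = file.path(dir, "probe_annotation.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             allele_counts = file.path(dir, "allele_counts.tsv"),
             truth = file.path(dir, "truth.json"))
  writeGenotypes(cohort$geno, paths["genotypes"], paths["snp_map"], cfg, seed)
  writeExpression(cohort$expr, paths["expression"], paths["probe_annotation"],
                  cfg, seed)
  cd <- as.data.frame(colData(cohort$expr))
  writeTsv(data.frame(sample = rownames(cd), cd), paths["covariates"], cfg, seed)
  writeTsv(cohort$alleleCounts, paths["allele_counts"], cfg, seed)
  truth <- list(cis = cohort$arch$cis, trans = cohort$arch$trans,
                ase_sites = cohort$arch$aseSites, h2 = cohort$arch$h2,
                pedigree = cohort$pedigree,
                config = unclass(cfg))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Reads a cohort from disk, then runs genotype QC, kinship estimation,
#' probe filtering, the polygenic eGWAS with two-level FDR and conditional
#' pruning, local/distant classification, ASE calling with gene mapping,
#' eGWAS x ASE integration, and network construction. All result tables are
#' written to \code{outDir} with provenance headers; per-stage counts are
#' logged with \code{message}.
#'
#' @param inputDir directory holding the files \code{\link{writeCohort}}
#'   produces (truth.json is not read).
#' @param outDir output directory.
#' @param alphaProbe,alphaGlobal,pruneWindowBp,localWindowBp,minCallRate,minMaf,hweFdr
#'   eGWAS-side thresholds (defaults 0.05, 0.05, 5 Mb, 1 Mb, 0.95, 0.05, 0.01).
#' @param aseMinReads,aseMinMac,aseAlpha,hetFraction ASE-side thresholds
#'   (defaults 10, 3, 0.05, 1/3).
#' @param masterMinTargets master-regulator degree threshold (default 10).
#' @param quantileNorm quantile-normalize the expression matrix (default
#'   TRUE).
#' @param seed provenance seed recorded in outputs.
#' @return List of all result objects plus \code{counts} (named per-stage
#'   record counts) and \code{paths}.
#' @export
runPipeline <- function(inputDir, outDir,
                        alphaProbe = 0.05, alphaGlobal = 0.05,
                        pruneWindowBp = 5e6, localWindowBp = 1e6,
                        minCallRate = 0.95, minMaf = 0.05, hweFdr = 0.01,
                        aseMinReads = 10, aseMinMac = 3, aseAlpha = 0.05,
                        hetFraction = 1 / 3, masterMinTargets = 10,
                        quantileNorm = TRUE, seed = NULL) {
  cfg <- as.list(environment())[setdiff(names(formals(runPipeline)),
                                        c("inputDir", "outDir"))]
  need <- c(genotypes = "genotypes.tsv", snp_map = "snp_map.tsv",
            expression = "expression.tsv",
            probe_annotation = "probe_annotation.tsv",
            covariates = "covariates.tsv", allele_counts = "allele_counts.tsv")
  paths <- file.path(inputDir, need)
  names(paths) <- names(need)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing input file(s): ", paste(need[missing], collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  geno <- stage("read", readGenotypes(paths["genotypes"], paths["snp_map"]))
  expr <- stage("read", readExpression(paths["expression"],
                                       paths["probe_annotation"]))
  covars <- stage("read", readTsv(paths["covariates"]))
  rownames(covars) <- covars$sample
  covars <- covars[, setdiff(colnames(covars), "sample"), drop = FALSE]
  alleleCounts <- stage("read", readAlleleCounts(paths["allele_counts"]))

  qc <- stage("qc", filterGenotypes(geno, minCallRate = minCallRate,
                                    minMaf = minMaf, hweFdr = hweFdr))
  message("qc: ", nrow(qc$geno), "/", nrow(geno), " SNPs pass")
  K <- stage("qc", computeGenomicKinship(qc$geno))

  pa <- probeAnnotation(expr)
  e <- assay(expr, "exprs")
  filt <- stage("preprocess",
                filterExpressedProbes(2^e, pa$probe_class, minArrays = 4,
                                      margin = 0.10))
  eKeep <- e[filt$keep, , drop = FALSE]
  if (quantileNorm) eKeep <- quantileNormalize(eKeep)
  exprF <- ExpressionExperiment(eKeep, pa[pa$probe %in% filt$keep, ],
                                sampleData = as.data.frame(colData(expr)))
  message("preprocess: ", nrow(exprF), "/", sum(pa$probe_class == "experimental"),
          " probes expressed")

  eg <- stage("egwas", runEgwas(exprF, qc$geno, covars = covars, K = K))
  eg <- stage("egwas", twoLevelFdr(eg, alphaProbe = alphaProbe,
                                   alphaGlobal = alphaGlobal))
  nSig <- sum(eg$records$is_significant, na.rm = TRUE)
  message("egwas: ", nSig, " significant associations of ", nrow(eg$records))
  eqtl <- stage("egwas", pruneToEqtlSnps(eg, windowBp = pruneWindowBp))
  eqtl <- stage("egwas", classifyLocalDistant(eqtl, probeAnnotation(exprF),
                                              windowBp = localWindowBp))
  eqtl$gene <- probeAnnotation(exprF)$gene[match(eqtl$probe,
                                                 probeAnnotation(exprF)$probe)]
  E <- intensities(exprF)
  eqtl$effect_sd_ratio <- effectSdRatio(eqtl$beta, E, probe = eqtl$probe)
  snpSummary <- attr(eqtl, "snp_summary")
  message("egwas: ", nrow(eqtl), " eQTL-SNP associations (",
          sum(eqtl$regulation %in% "local"), " local, ",
          sum(eqtl$regulation %in% "distant"), " distant)")

  enr <- stage("egwas", {
    map <- snpMap(qc$geno)
    chromOf <- stats::setNames(map$chrom, map$snp)
    chromosomeEnrichment(unique(eqtl$snp), map$snp, chromOf)
  })

  geneIntervals <- stage("ase", {
    mapped <- pa[!is.na(pa$start) & !is.na(pa$gene), , drop = FALSE]
    data.frame(gene = mapped$gene, contig = mapped$chrom,
               start = pmax(1L, mapped$start - 1000L),
               end = mapped$start + 1000L, stringsAsFactors = FALSE)
  })
  geneReads <- stage("ase", {
    tot <- tapply(alleleCounts$refCount + alleleCounts$altCount,
                  paste(alleleCounts$contig, alleleCounts$position, sep = ":"),
                  max)
    # gene-level proxy: max site depth within the gene's interval
    gr <- GRanges(geneIntervals$contig,
                  IRanges(geneIntervals$start, geneIntervals$end))
    sitePos <- do.call(rbind, strsplit(names(tot), ":", fixed = TRUE))
    sr <- GRanges(sitePos[, 1],
                  IRanges(as.integer(sitePos[, 2]), as.integer(sitePos[, 2])))
    hits <- findOverlaps(sr, gr)
    reads <- tapply(tot[queryHits(hits)], geneIntervals$gene[subjectHits(hits)],
                    max)
    v <- stats::setNames(rep(0, length(unique(geneIntervals$gene))),
                         unique(geneIntervals$gene))
    v[names(reads)] <- reads
    v
  })
  ase <- stage("ase", runAse(alleleCounts, geneIntervals = geneIntervals,
                             geneReads = geneReads, minReads = aseMinReads,
                             minMac = aseMinMac, alpha = aseAlpha,
                             hetFraction = hetFraction))
  nAse <- sum(ase$calls$is_ase, na.rm = TRUE)
  message("ase: ", nAse, " ASE-SNPs; ",
          sum(ase$aseGenes$is_ase), " ASE genes")

  overlap <- stage("integrate", {
    geneChrom <- stats::setNames(pa$chrom, pa$gene)
    integrateEgwasAse(eqtl, ase$aseGenes, geneChrom = geneChrom)
  })

  net <- stage("network", buildAssociationGraph(eqtl))
  comp <- stage("network", componentSummary(net))
  masters <- stage("network", findMasterRegulators(net,
                                                   minTargets = masterMinTargets))

  outPaths <- c(qc_report = "qc_report.tsv", kinship = "kinship.tsv",
                associations = "associations.tsv", eqtl_snps = "eqtl_snps.tsv",
                snp_summary = "eqtl_snp_summary.tsv",
                enrichment = "enrichment.tsv", ase_snps = "ase_snps.tsv",
                ase_genes = "ase_genes.tsv", universe = "universe.tsv",
                overlap = "overlap_genes.tsv", network_sif = "network.sif",
                edges = "edges.tsv", masters = "masters.tsv",
                summary = "summary.json")
  outPaths <- stats::setNames(file.path(outDir, outPaths), names(outPaths))
  writeTsv(qc$report, outPaths["qc_report"], cfg, seed)
  kv <- kinshipValues(K)
  writeTsv(data.frame(sample = rownames(kv), kv, check.names = FALSE),
           outPaths["kinship"], cfg, seed)
  writeTsv(eg$records[which(eg$records$is_significant), , drop = FALSE],
           outPaths["associations"], cfg, seed)
  writeTsv(eqtl, outPaths["eqtl_snps"], cfg, seed)
  writeTsv(snpSummary, outPaths["snp_summary"], cfg, seed)
  writeTsv(enr, outPaths["enrichment"], cfg, seed)
  writeTsv(ase$calls, outPaths["ase_snps"], cfg, seed)
  writeTsv(ase$aseGenes, outPaths["ase_genes"], cfg, seed)
  writeTsv(data.frame(gene = ase$universe), outPaths["universe"], cfg, seed)
  writeTsv(overlap, outPaths["overlap"], cfg, seed)
  exportNetwork(net, outPaths["network_sif"], "sif")
  exportNetwork(net, outPaths["edges"], "edges")
  writeTsv(masters, outPaths["masters"], cfg, seed)

  labelTab <- snpSummary$label
  counts <- c(snps_pass_qc = nrow(qc$geno),
              probes_expressed = nrow(exprF),
              associations = nSig,
              eqtl_snps = length(unique(eqtl$snp)),
              local_snps = sum(labelTab == "local", na.rm = TRUE),
              distant_snps = sum(labelTab == "distant", na.rm = TRUE),
              both_snps = sum(labelTab == "both", na.rm = TRUE),
              ase_snps = nAse,
              ase_genes = sum(ase$aseGenes$is_ase),
              overlap_genes = sum(overlap$ase &
                                    (overlap$local_eqtl | overlap$distant_eqtl)))
  jsonlite::write_json(as.list(counts), outPaths["summary"], auto_unbox = TRUE,
                       digits = NA)
  message("pipeline: ", paste(names(counts), counts, sep = "=", collapse = " "))
  list(qc = qc, K = K, expr = exprF, egwas = eg, eqtl = eqtl,
       snpSummary = snpSummary, enrichment = enr, ase = ase,
       overlap = overlap, network = net, components = comp,
       masters = masters, counts = counts, paths = outPaths)
}
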