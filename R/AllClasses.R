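#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' GenotypeExperiment: SNP dosages with a SNP map
#'
#' A \linkS4class{SummarizedExperiment} holding biallelic SNP dosages
#' (assay \code{"dosage"}, SNPs x samples, values in \{0, 1, 2, NA\}) together
#' with the SNP map in \code{rowData} (columns \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}) and per-sample covariates in \code{colData}
#' (at least \code{sex} when available).
#'
#' Dosages count copies of the alternative (minor, for PLINK input) allele.
#' Positions are 1-based and strictly increasing within a chromosome after
#' \code{sortSnps}.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

#' ExpressionExperiment: probe intensities with probe annotation
#'
#' A \linkS4class{SummarizedExperiment} holding log2 probe intensities
#' (assay \code{"exprs"}, probes x samples) with probe annotation in
#' \code{rowData}: \code{chrom}, \code{start} (1-based probe start, NA when
#' unmapped), \code{strand}, \code{gene} (symbol or NA), and
#' \code{probe_class} (\code{"experimental"} or \code{"negative_control"}).
#' Sample covariates (\code{batch}, \code{sex}) live in \code{colData}.
#'
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

.validGenotype <- function(object) {
  msg <- NULL
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  need <- c("chrom", "pos")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
  else if (nrow(rd) && any(is.na(rd$pos)))
    msg <- c(msg, "SNP positions must not be NA")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate SNP ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeExperiment", .validGenotype)

.validExpression <- function(object) {
  msg <- NULL
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  rd <- rowData(object)
  if (!"probe_class" %in% colnames(rd))
    msg <- c(msg, "rowData lacks 'probe_class'")
  else if (nrow(rd) && !all(rd$probe_class %in% c("experimental", "negative_control")))
    msg <- c(msg, "probe_class must be 'experimental' or 'negative_control'")
  if (all(c("chrom", "start") %in% colnames(rd)) && nrow(rd)) {
    mapped <- !is.na(rd$start)
    if (any(mapped & is.na(rd$chrom)))
      msg <- c(msg, "mapped probes (non-NA start) must have a chromosome")
    if (any(mapped & rd$start < 1))
      msg <- c(msg, "probe start positions are 1-based (>= 1)")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids")
  if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionExperiment", .validExpression)

#' Construct a GenotypeExperiment
#'
#' @param dosages numeric matrix, either SNPs x samples or samples x SNPs
#'   (orientation inferred from dimnames against \code{snpMap$snp}); values in
#'   \{0,1,2,NA\}.
#' @param snpMap data.frame with columns \code{snp}, \code{chrom}, \code{pos}
#'   and optionally \code{ref}, \code{alt}.
#' @param sampleData optional data.frame of per-sample covariates, rownames =
#'   sample ids.
#' @param sort sort SNPs by (chrom, pos)? Default TRUE.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
GenotypeExperiment <- function(dosages, snpMap, sampleData = NULL, sort = TRUE) {
  stopifnot(is.matrix(dosages), is.data.frame(snpMap),
            all(c("snp", "chrom", "pos") %in% colnames(snpMap)))
  if (anyDuplicated(snpMap$snp)) stop("duplicate SNP id in snpMap")
  if (!is.null(rownames(dosages)) && !is.null(colnames(dosages))) {
    if (all(colnames(dosages) %in% snpMap$snp) &&
        !all(rownames(dosages) %in% snpMap$snp))
      dosages <- t(dosages)
  }
  if (nrow(dosages) != nrow(snpMap))
    stop("dosage matrix does not match snpMap (", nrow(dosages), " rows vs ",
         nrow(snpMap), " SNPs)")
  if (is.null(rownames(dosages))) rownames(dosages) <- snpMap$snp
  dosages <- dosages[match(snpMap$snp, rownames(dosages)), , drop = FALSE]
  rd <- DataFrame(chrom = as.character(snpMap$chrom),
                  pos = as.integer(snpMap$pos),
                  row.names = snpMap$snp)
  for (col in c("ref", "alt")) if (col %in% colnames(snpMap))
    rd[[col]] <- as.character(snpMap[[col]])
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(dosages))
  } else DataFrame(sampleData[match(colnames(dosages), rownames(sampleData)), ,
                              drop = FALSE], row.names = colnames(dosages))
  obj <- new("GenotypeExperiment",
             SummarizedExperiment(assays = list(dosage = dosages),
                                  rowData = rd, colData = cd))
  if (sort) obj <- sortSnps(obj)
  obj
}

#' Construct an ExpressionExperiment
#'
#' @param values numeric matrix, probes x samples or samples x probes
#'   (orientation inferred from dimnames against \code{probeAnnotation$probe}).
#' @param probeAnnotation data.frame with column \code{probe} and optionally
#'   \code{chrom}, \code{start}, \code{strand}, \code{gene},
#'   \code{probe_class}.
#' @param sampleData optional data.frame of covariates (batch, sex), rownames
#'   = sample ids.
#' @return An \linkS4class{ExpressionExperiment}.
#' @export
ExpressionExperiment <- function(values, probeAnnotation, sampleData = NULL) {
  stopifnot(is.matrix(values), is.data.frame(probeAnnotation),
            "probe" %in% colnames(probeAnnotation))
  pa <- probeAnnotation
  if (!is.null(rownames(values)) && !is.null(colnames(values))) {
    if (all(colnames(values) %in% pa$probe) && !all(rownames(values) %in% pa$probe))
      values <- t(values)
  }
  if (nrow(values) != nrow(pa))
    stop("expression matrix does not match probe annotation")
  if (is.null(rownames(values))) rownames(values) <- pa$probe
  values <- values[match(pa$probe, rownames(values)), , drop = FALSE]
  rd <- DataFrame(row.names = pa$probe)
  rd$chrom <- if ("chrom" %in% colnames(pa)) as.character(pa$chrom) else NA_character_
  rd$start <- if ("start" %in% colnames(pa)) as.integer(pa$start) else NA_integer_
  rd$strand <- if ("strand" %in% colnames(pa)) as.character(pa$strand) else NA_character_
  rd$gene <- if ("gene" %in% colnames(pa)) as.character(pa$gene) else NA_character_
  rd$probe_class <- if ("probe_class" %in% colnames(pa)) {
    as.character(pa$probe_class)
  } else "experimental"
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(values))
  } else DataFrame(sampleData[match(colnames(values), rownames(sampleData)), ,
                              drop = FALSE], row.names = colnames(values))
  new("ExpressionExperiment",
      SummarizedExperiment(assays = list(exprs = values),
                           rowData = rd, colData = cd))
}

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", nrow(object), "SNPs x", ncol(object), "samples\n")
  ch <- unique(rowData(object)$chrom)
  cat("  chromosomes:", paste(head(ch, 8), collapse = ", "),
      if (length(ch) > 8) "..." else "", "\n")
  nmiss <- sum(is.na(assay(object, "dosage")))
  cat("  missing dosages:", nmiss, "\n")
  invisible(NULL)
})

setMethod("show", "ExpressionExperiment", function(object) {
  rd <- rowData(object)
  cat("ExpressionExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  experimental:", sum(rd$probe_class == "experimental"),
      " negative controls:", sum(rd$probe_class == "negative_control"), "\n")
  cat("  mapped probes:", sum(!is.na(rd$start)), "\n")
  invisible(NULL)
})
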