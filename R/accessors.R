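#' @include AllClasses.R
NULL

#' Accessors for GenotypeExperiment and ExpressionExperiment
#'
#' \code{dosages} returns the samples x SNPs dosage matrix (the orientation
#' the association model consumes); \code{snpMap} the SNP map data.frame;
#' \code{intensities} the samples x probes expression matrix;
#' \code{probeAnnotation} the probe annotation data.frame.
#'
#' @param x a GenotypeExperiment or ExpressionExperiment.
#' @return A matrix or data.frame; see the method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeExperiment", function(x) t(assay(x, "dosage")))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setMethod("snpMap", "GenotypeExperiment", function(x) {
  rd <- rowData(x)
  out <- data.frame(snp = rownames(x), chrom = rd$chrom, pos = rd$pos,
                    stringsAsFactors = FALSE)
  for (col in c("ref", "alt")) if (col %in% colnames(rd)) out[[col]] <- rd[[col]]
  out
})

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "ExpressionExperiment", function(x) t(assay(x, "exprs")))

#' @rdname accessors
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))
#' @rdname accessors
#' @export
setMethod("probeAnnotation", "ExpressionExperiment", function(x) {
  rd <- rowData(x)
  data.frame(probe = rownames(x), chrom = rd$chrom, start = rd$start,
             strand = rd$strand, gene = rd$gene, probe_class = rd$probe_class,
             stringsAsFactors = FALSE)
})

#' Sort SNPs by genomic position
#'
#' Orders SNPs by (chromosome, position). Chromosomes sort numerically when
#' their labels are numeric-like, lexicographically otherwise.
#'
#' @param x a GenotypeExperiment.
#' @return The object with rows reordered.
#' @export
setGeneric("sortSnps", function(x) standardGeneric("sortSnps"))
#' @rdname sortSnps
#' @export
setMethod("sortSnps", "GenotypeExperiment", function(x) {
  rd <- rowData(x)
  x[order(chromOrder(rd$chrom), rd$pos), ]
})

# numeric-aware chromosome ordering key
chromOrder <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(ch))
  key <- ifelse(is.na(num), Inf, num)
  order(order(key, ch))  # rank, stable for non-numeric labels
}

#' Per-SNP alternative allele frequency
#'
#' @param x a GenotypeExperiment.
#' @return Named numeric vector of alt-allele frequencies (NA-aware).
#' @export
alleleFrequency <- function(x) {
  d <- assay(x, "dosage")
  rowMeans(d, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' @param x a GenotypeExperiment.
#' @return Named numeric vector, \code{pmin(p, 1-p)} of the alt frequency.
#' @export
minorAlleleFrequency <- function(x) {
  p <- alleleFrequency(x)
  pmin(p, 1 - p)
}
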