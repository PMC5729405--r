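#' @importFrom igraph graph_from_data_frame components degree V vcount ecount
#'   as_data_frame
NULL

#' Build the bipartite association network
#'
#' One node per distinct eQTL-SNP and per distinct probe (or gene, when
#' \code{collapseToGenes} and a \code{gene} column are available: probes of
#' the same gene merge into one node and parallel SNP-gene edges are
#' recorded as multi-edge weight). Edges are directed SNP -> probe/gene and
#' labelled with the local/distant regulation class.
#'
#' @param eqtl classified eQTL table (\code{\link{classifyLocalDistant}});
#'   needs columns snp, probe, regulation, p, optionally gene.
#' @param collapseToGenes merge probes of one gene (default FALSE).
#' @return Object of class \code{"RegulatoryNetwork"}: list with
#'   \code{graph} (igraph, directed), \code{edges} (data.frame snp, target,
#'   regulation, p, weight), \code{nodeType} (named vector).
#' @export
buildAssociationGraph <- function(eqtl, collapseToGenes = FALSE) {
  if (!nrow(eqtl)) {
    net <- list(graph = igraph::make_empty_graph(directed = TRUE),
                edges = data.frame(snp = character(0), target = character(0),
                                   regulation = character(0), p = numeric(0),
                                   weight = numeric(0), stringsAsFactors = FALSE),
                nodeType = character(0))
    class(net) <- "RegulatoryNetwork"
    return(net)
  }
  target <- if (collapseToGenes && "gene" %in% colnames(eqtl)) {
    ifelse(is.na(eqtl$gene), eqtl$probe, eqtl$gene)
  } else eqtl$probe
  edges <- data.frame(snp = eqtl$snp, target = target,
                      regulation = eqtl$regulation,
                      p = eqtl$p, stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(weight = rep(1, nrow(edges))) ~ snp + target,
                          data = edges, FUN = sum)
  first <- !duplicated(paste(edges$snp, edges$target))
  edges1 <- edges[first, , drop = FALSE]
  edges1$weight <- agg$weight[match(paste(edges1$snp, edges1$target),
                                    paste(agg$snp, agg$target))]
  snpNodes <- unique(edges1$snp)
  tgtNodes <- unique(edges1$target)
  overlap <- intersect(snpNodes, tgtNodes)
  if (length(overlap)) stop("node id used as both SNP and target: ",
                            paste(overlap, collapse = ", "))
  g <- graph_from_data_frame(
    edges1[, c("snp", "target", "regulation", "p", "weight")],
    directed = TRUE,
    vertices = data.frame(name = c(snpNodes, tgtNodes),
                          type = rep(c("eqtl_snp", "target"),
                                     c(length(snpNodes), length(tgtNodes)))))
  net <- list(graph = g, edges = edges1,
              nodeType = stats::setNames(
                rep(c("eqtl_snp", "target"),
                    c(length(snpNodes), length(tgtNodes))),
                c(snpNodes, tgtNodes)))
  class(net) <- "RegulatoryNetwork"
  net
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("RegulatoryNetwork:", sum(x$nodeType == "eqtl_snp"), "eQTL-SNPs,",
      sum(x$nodeType == "target"), "probes/genes,",
      nrow(x$edges), "associations\n")
  invisible(x)
}

#' Summarize network components
#'
#' Connected components of the undirected skeleton, the size histogram of
#' components with at least \code{minNodes} nodes, and the mean neighbor
#' count (undirected degree) over all nodes.
#'
#' @param network a \code{"RegulatoryNetwork"}.
#' @param minNodes minimum component size for the histogram (default 3).
#' @return List with \code{membership} (named vector), \code{sizes}
#'   (all component sizes), \code{histogram} (table over sizes >=
#'   \code{minNodes}), \code{nComponents} (count >= \code{minNodes}),
#'   \code{meanDegree}.
#' @export
componentSummary <- function(network, minNodes = 3) {
  comp <- components(network$graph, mode = "weak")
  deg <- degree(network$graph, mode = "all")
  big <- comp$csize[comp$csize >= minNodes]
  list(membership = comp$membership, sizes = comp$csize,
       histogram = table(big), nComponents = length(big),
       meanDegree = mean(deg))
}

#' Find master-regulator eQTL-SNPs
#'
#' SNP nodes associated with at least \code{minTargets} distinct probes or
#' genes, sorted by out-degree (descending) then SNP id.
#'
#' @param network a \code{"RegulatoryNetwork"}.
#' @param minTargets minimum number of distinct targets (default 10).
#' @return data.frame: snp, n_targets.
#' @export
findMasterRegulators <- function(network, minTargets = 10) {
  tab <- table(network$edges$snp)
  keep <- tab[tab >= minTargets]
  out <- data.frame(snp = names(keep), n_targets = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$n_targets, out$snp), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' PCIT co-expression edge filter
#'
#' Partial Correlation and Information Theory algorithm (Reverter & Chan
#' 2008). For every unordered trio (x, y, z) of variables the three
#' first-order partial correlations
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'       {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' define the trio tolerance \eqn{\epsilon = \frac13 (r_{xy.z}/r_{xy} +
#' r_{xz.y}/r_{xz} + r_{yz.x}/r_{yz})}. An edge (x, y) is flagged
#' non-significant if, for some third variable z, \eqn{|r_{xy}| \le
#' |\epsilon\, r_{xz}|} and \eqn{|r_{xy}| \le |\epsilon\, r_{yz}|}. Trios
#' with a unit correlation in a denominator are skipped with a warning.
#'
#' @param mat numeric matrix, observations x variables (>= 3 variables,
#'   >= 4 observations), or a precomputed correlation matrix when
#'   \code{isCorrelation = TRUE}.
#' @param isCorrelation treat \code{mat} as a correlation matrix.
#' @return Object of class \code{"PcitResult"}: list with \code{r}
#'   (correlations), \code{keep} (symmetric logical mask; TRUE = edge
#'   significant), \code{epsilon} (per-trio tolerances, named
#'   "i|j|k"), \code{skipped} (trios skipped as degenerate).
#' @export
pcitFilter <- function(mat, isCorrelation = FALSE) {
  if (isCorrelation) {
    r <- mat
  } else {
    stopifnot(is.matrix(mat))
    if (ncol(mat) < 2) stop("need at least 2 variables")
    if (nrow(mat) < 4) stop("need at least 4 observations")
    r <- cor(mat)
  }
  nv <- ncol(r)
  vn <- colnames(r)
  if (is.null(vn)) vn <- paste0("V", seq_len(nv))
  keep <- matrix(TRUE, nv, nv, dimnames = list(vn, vn))
  eps <- numeric(0)
  skipped <- character(0)
  if (nv >= 3) {
    trios <- utils::combn(nv, 3)
    epsNames <- character(ncol(trios))
    epsVals <- rep(NA_real_, ncol(trios))
    for (t in seq_len(ncol(trios))) {
      i <- trios[1, t]; j <- trios[2, t]; k <- trios[3, t]
      rij <- r[i, j]; rik <- r[i, k]; rjk <- r[j, k]
      epsNames[t] <- paste(vn[i], vn[j], vn[k], sep = "|")
      if (any(abs(c(rij, rik, rjk)) >= 1 - 1e-12)) {
        skipped <- c(skipped, epsNames[t])
        next
      }
      rij.k <- (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
      rik.j <- (rik - rij * rjk) / sqrt((1 - rij^2) * (1 - rjk^2))
      rjk.i <- (rjk - rij * rik) / sqrt((1 - rij^2) * (1 - rik^2))
      e <- (rij.k / rij + rik.j / rik + rjk.i / rjk) / 3
      epsVals[t] <- e
      if (abs(rij) <= abs(e * rik) && abs(rij) <= abs(e * rjk))
        keep[i, j] <- keep[j, i] <- FALSE
      if (abs(rik) <= abs(e * rij) && abs(rik) <= abs(e * rjk))
        keep[i, k] <- keep[k, i] <- FALSE
      if (abs(rjk) <= abs(e * rij) && abs(rjk) <= abs(e * rik))
        keep[j, k] <- keep[k, j] <- FALSE
    }
    eps <- stats::setNames(epsVals, epsNames)
    if (length(skipped))
      warning("skipped ", length(skipped), " degenerate trio(s) with |r| = 1")
  }
  diag(keep) <- TRUE
  res <- list(r = r, keep = keep, epsilon = eps, skipped = skipped)
  class(res) <- "PcitResult"
  res
}

#' @export
print.PcitResult <- function(x, ...) {
  nv <- ncol(x$r)
  ut <- upper.tri(x$r)
  cat("PcitResult:", nv, "variables;", sum(x$keep[ut]), "of", sum(ut),
      "edges kept\n")
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes SIF (\code{node <tab> relation <tab> node}, relation =
#' local/distant) or an edge-list TSV including p-values and multi-edge
#' weights. Both round-trip losslessly through
#' \code{\link{readNetworkEdges}}.
#'
#' @param network a \code{"RegulatoryNetwork"}.
#' @param path output file path.
#' @param format \code{"sif"} or \code{"edges"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(network, path, format = c("sif", "edges")) {
  if (!is.character(format) || !all(format %in% c("sif", "edges")))
    stop("unknown format '", paste(setdiff(format, c("sif", "edges")),
                                   collapse = ", "),
         "'; supported formats: sif, edges")
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", e$snp,
                     ifelse(is.na(e$regulation), "association", e$regulation),
                     e$target)
    writeLines(lines, path)
  } else {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network edge list
#'
#' Reads the SIF or edge-list TSV written by \code{\link{exportNetwork}}.
#'
#' @param path file path.
#' @param format \code{"sif"} or \code{"edges"}.
#' @return data.frame with columns snp, target, regulation (and p, weight
#'   for the edges format).
#' @export
readNetworkEdges <- function(path, format = c("sif", "edges")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(snp = vapply(parts, `[`, "", 1),
               regulation = vapply(parts, `[`, "", 2),
               target = vapply(parts, `[`, "", 3),
               stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}
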