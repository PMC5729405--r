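#' Normal+exponential background correction
#'
#' Per array, models observed intensity as X = B + S with background
#' B ~ N(mu, sigma^2) and signal S ~ Exp(mean alpha), estimates
#' (mu, sigma, alpha) by the method of moments (third central moment
#' identifies alpha: E[(X - EX)^3] = 2 alpha^3), and replaces each intensity
#' by the posterior expected signal
#' \deqn{E[S | X = x] = a + \sigma \phi(a/\sigma) / \Phi(a/\sigma), \quad
#'       a = x - \mu - \sigma^2/\alpha.}
#' The output is strictly positive and monotone nondecreasing in x within an
#' array. This is the method-of-moments dialect of the normexp correction;
#' it differs from limma's saddle-point MLE in the parameter estimates, not
#' in the posterior-mean formula.
#'
#' @param values numeric matrix of positive raw intensities, samples in
#'   columns (arrays) and probes in rows.
#' @return Matrix of background-corrected intensities, same shape.
#' @export
normexpBackground <- function(values) {
  stopifnot(is.matrix(values))
  if (any(values <= 0, na.rm = TRUE)) stop("raw intensities must be positive")
  out <- values
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    pars <- .normexpMoments(x)
    if (is.null(pars)) {
      warning("array ", j, " is degenerate (zero variance); passed through")
      next
    }
    out[, j] <- .normexpSignal(x, pars["mu"], pars["sigma"], pars["alpha"])
  }
  out
}

# method-of-moments fit; returns NULL for degenerate arrays
.normexpMoments <- function(x) {
  x <- x[is.finite(x)]
  m1 <- mean(x)
  m2 <- mean((x - m1)^2)
  if (m2 <= 0) return(NULL)
  m3 <- mean((x - m1)^3)
  alpha <- if (m3 > 0) (m3 / 2)^(1 / 3) else sqrt(m2) / 10
  sigma2 <- m2 - alpha^2
  if (sigma2 <= 0) {           # nearly pure-exponential array
    sigma2 <- m2 / 100
    alpha <- sqrt(m2 - sigma2)
  }
  mu <- m1 - alpha
  c(mu = mu, sigma = sqrt(sigma2), alpha = alpha)
}

# posterior mean E[S | X = x]; Mills ratio evaluated on the log scale so the
# far-left tail (a/sigma << 0) stays finite and positive
.normexpSignal <- function(x, mu, sigma, alpha) {
  a <- x - mu - sigma^2 / alpha
  z <- a / sigma
  mills <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  s <- a + sigma * mills
  pmax(s, 1e-10)
}

#' Quantile normalization
#'
#' Forces every array onto the common distribution given by the row-wise
#' mean of sorted arrays; ties receive the mean of their would-be quantile
#' values and within-array rank order is preserved. Delegates to
#' \code{limma::normalizeQuantiles(..., ties = TRUE)}.
#'
#' @param values numeric matrix, probes x samples; needs >= 2 arrays.
#' @return Normalized matrix, same shape and dimnames.
#' @export
quantileNormalize <- function(values) {
  stopifnot(is.matrix(values))
  if (ncol(values) < 2) stop("quantile normalization needs at least 2 arrays")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Filter probes by expression above negative controls
#'
#' Keeps a probe iff its intensity exceeds \code{(1 + margin)} times the
#' per-array negative-control summary (the mean of negative-control probes
#' on that array, by default) on at least \code{minArrays} arrays.
#'
#' @param values numeric matrix, probes x samples, on the scale the filter
#'   should apply to (background-corrected raw scale by default usage).
#' @param probeClass character vector per probe, \code{"experimental"} or
#'   \code{"negative_control"}.
#' @param minArrays minimum number of arrays on which a probe must clear the
#'   threshold (default 4).
#' @param margin fractional margin above the control summary (default 0.10).
#' @param controlSummary function summarizing negative-control intensities
#'   per array (default \code{mean}).
#' @return List with \code{keep} (character vector of kept experimental
#'   probe ids) and \code{passCount} (named integer vector, arrays passed
#'   per experimental probe).
#' @export
filterExpressedProbes <- function(values, probeClass, minArrays = 4,
                                  margin = 0.10, controlSummary = mean) {
  stopifnot(is.matrix(values), length(probeClass) == nrow(values))
  nc <- probeClass == "negative_control"
  if (!any(nc)) stop("no negative-control probes present")
  ctrl <- apply(values[nc, , drop = FALSE], 2, controlSummary)
  thresh <- (1 + margin) * ctrl
  exper <- values[!nc, , drop = FALSE]
  pass <- exper > rep(thresh, each = nrow(exper))
  passCount <- rowSums(pass)
  keep <- rownames(exper)[passCount >= minArrays]
  list(keep = keep, passCount = passCount)
}

#' Microarray-style preprocessing pipeline
#'
#' Runs normexp background correction on raw intensities, log2 transform,
#' quantile normalization, and the negative-control expression filter (the
#' filter is evaluated on the background-corrected raw scale). Returns an
#' \linkS4class{ExpressionExperiment} restricted to the kept experimental
#' probes.
#'
#' @param raw an \linkS4class{ExpressionExperiment} whose \code{exprs} assay
#'   holds positive raw intensities, or a probes x samples matrix plus
#'   \code{annotation}.
#' @param annotation probe annotation data.frame (see
#'   \code{\link{ExpressionExperiment}}); ignored when \code{raw} is already
#'   an ExpressionExperiment.
#' @param minArrays,margin filter parameters (see
#'   \code{\link{filterExpressedProbes}}).
#' @return List with \code{expr} (normalized, filtered
#'   ExpressionExperiment), \code{keep}, \code{passCount}.
#' @export
preprocessExpression <- function(raw, annotation = NULL, minArrays = 4,
                                 margin = 0.10) {
  if (is(raw, "ExpressionExperiment")) {
    values <- assay(raw, "exprs")
    pa <- probeAnnotation(raw)
    cd <- as.data.frame(colData(raw))
  } else {
    stopifnot(is.matrix(raw), !is.null(annotation))
    values <- raw
    pa <- annotation
    cd <- NULL
  }
  corrected <- normexpBackground(values)
  filt <- filterExpressedProbes(corrected, pa$probe_class, minArrays = minArrays,
                                margin = margin)
  normalized <- quantileNormalize(log2(corrected))
  keepIdx <- rownames(normalized) %in% filt$keep
  expr <- ExpressionExperiment(normalized[keepIdx, , drop = FALSE],
                               pa[pa$probe %in% filt$keep, , drop = FALSE],
                               sampleData = cd)
  list(expr = expr, keep = filt$keep, passCount = filt$passCount)
}
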