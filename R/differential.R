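## Normalisation factors, moderated differential testing, FDR and the
## DE/DB classification rules, applied identically to peak-count and
## gene-count tables.

#' Filter features by counts-per-million
#'
#' Removes features whose CPM is at or below \code{minCpm} in every sample;
#' a feature is kept as soon as one sample exceeds the threshold (strict
#' \code{>}).
#'
#' @param table a \linkS4class{CountTable}.
#' @param minCpm CPM threshold (default 1).
#' @return the filtered \code{CountTable} (spike-in rows untouched).
#' @export
cpmFilter <- function(table, minCpm = 1) {
  m <- countsOf(table)
  if (any(colSums(m) <= 0)) stop("library sizes must be > 0")
  cpm <- edgeR::cpm(m)
  keep <- rowSums(cpm > minCpm) > 0
  CountTable(m[keep, , drop = FALSE], spikeinCounts(table))
}

#' TMM normalisation factors
#'
#' Trimmed-mean-of-M-values factors (Robinson-Oshlack) computed by
#' \code{edgeR::calcNormFactors}: the reference sample is the one whose
#' upper quartile is closest to the mean upper quartile, M-values are doubly
#' trimmed (30\% on M, 5\% on A) and precision-weighted, and factors are
#' rescaled to geometric mean 1.
#'
#' @param table a \linkS4class{CountTable} (>= 2 samples).
#' @param trimM,trimA trim fractions on M and A values.
#' @return A \linkS4class{NormFactors}.
#' @export
tmmFactors <- function(table, trimM = 0.30, trimA = 0.05) {
  m <- countsOf(table)
  if (ncol(m) < 2) stop("TMM needs >= 2 samples")
  if (any(colSums(m) == 0)) stop("all-zero sample")
  f <- edgeR::calcNormFactors(m, method = "TMM", logratioTrim = trimM,
                              sumTrim = trimA)
  new("NormFactors", factors = stats::setNames(f, colnames(m)),
      method = "TMM")
}

#' Spike-in size factors (median of ratios)
#'
#' For each sample the factor is the median over spike-in features of the
#' ratio of the observed count to the feature's geometric mean across
#' samples; features containing any zero are excluded from the reference
#' set, following the median-of-ratios convention.
#'
#' @param table a \linkS4class{CountTable} with spike-in counts, or a bare
#'   spike-in matrix.
#' @return A \linkS4class{NormFactors} (method \code{spikein_median_ratio}).
#' @examples
#' sp <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2,
#'              dimnames = list(paste0("s", 1:3), c("a", "b")))
#' normFactors(spikeinSizeFactors(sp))  # ~ (0.707, 1.414)
#' @export
spikeinSizeFactors <- function(table) {
  m <- if (methods::is(table, "CountTable")) {
    s <- spikeinCounts(table)
    if (is.null(s)) stop("count table has no spike-in companion")
    s
  } else as.matrix(table)
  usable <- rowSums(m == 0) == 0
  if (!any(usable))
    stop("no usable spike-in features (all contain zeros)")
  lm <- log(m[usable, , drop = FALSE])
  logGeo <- rowMeans(lm)
  f <- apply(exp(lm - logGeo), 2, stats::median)
  new("NormFactors", factors = stats::setNames(f, colnames(m)),
      method = "spikein_median_ratio")
}

#' Effective library sizes under a normalisation
#'
#' TMM factors multiply the raw library sizes (edgeR convention); spike-in
#' size factors replace them, rescaled so their geometric mean matches the
#' geometric mean raw library size.
#'
#' @param table a \linkS4class{CountTable}.
#' @param norm a \linkS4class{NormFactors} or \code{NULL} (raw library
#'   sizes).
#' @return named numeric vector of effective library sizes.
#' @export
effectiveLibSizes <- function(table, norm = NULL) {
  m <- countsOf(table)
  lib <- colSums(m)
  if (is.null(norm)) return(lib)
  f <- normFactors(norm)[colnames(m)]
  if (anyNA(f)) stop("normalisation factors missing for some samples")
  if (norm@method == "TMM") lib * f
  else f / exp(mean(log(f))) * exp(mean(log(lib)))
}

#' Moderated two-group differential test
#'
#' Log2-CPM values (pseudo-count 0.5) are fitted per feature with a
#' two-group mean model; residual variances are shrunk towards a common
#' prior estimated by moment matching on the log-variance distribution
#' (an empirical-Bayes scheme), and moderated t statistics with
#' \code{d + d0} degrees of freedom give two-sided p-values; q-values are
#' Benjamini-Hochberg.
#'
#' @param table a \linkS4class{CountTable}.
#' @param design character/factor of two group labels, one per sample; the
#'   reported log2 fold change is second level minus first level.
#' @param norm optional \linkS4class{NormFactors}.
#' @param priorDf force the prior degrees of freedom d0 (e.g. \code{0} for
#'   an ordinary t-test, \code{Inf} for fully pooled variances); default
#'   \code{NULL} estimates d0 from the data.
#' @return data.frame with columns \code{feature_id}, \code{log2fc},
#'   \code{t}, \code{p_value}, \code{fdr}, \code{mean_cpm}, plus attributes
#'   \code{d0} and \code{s02}.
#' @export
moderatedTest <- function(table, design, norm = NULL, priorDf = NULL) {
  m <- countsOf(table)
  design <- as.factor(design)
  if (nlevels(design) != 2) stop("design must have exactly two groups")
  if (any(table(design) < 2)) stop("each group needs >= 2 replicates")
  lib <- effectiveLibSizes(table, norm)
  cpm <- t(t(m + 0.5) / (lib + 1)) * 1e6
  y <- log2(cpm)
  g1 <- design == levels(design)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, g2, drop = FALSE])
  rss <- rowSums((y[, g1, drop = FALSE] - m1)^2) +
    rowSums((y[, g2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- rss / d
  s2 <- pmax(s2, 1e-12)

  if (is.null(priorDf)) {
    fit <- fitScaledInvChisq(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- priorDf
    s02 <- if (is.finite(d0) && d0 == 0) 0 else
      exp(mean(log(s2)) - digamma(d / 2) + log(d / 2))
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  dfTotal <- d + d0
  p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  out <- data.frame(feature_id = rownames(m), log2fc = m2 - m1, t = tstat,
                    p_value = p, fdr = bhFdr(p),
                    mean_cpm = rowMeans(t(t(m) / lib) * 1e6),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

## Moment-matched fit of a scaled inverse chi-square prior to observed
## residual variances: log s2 ~ log s02 + log F(d, d0), so
## var(log s2) - trigamma(d/2) = trigamma(d0/2).
fitScaledInvChisq <- function(s2, d) {
  z <- log(s2)
  evar <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigammaInverse(evar)
    s02 <- exp(mean(z) - digamma(d / 2) + digamma(d0 / 2) - log(d0 / d))
  }
  list(d0 = d0, s02 = s02)
}

## Newton solve of trigamma(x) = y.
trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement.
#'
#' @param p numeric p-values in [0, 1]; NaN is rejected.
#' @return q-values in [0, 1].
#' @export
bhFdr <- function(p) {
  if (any(is.nan(p)) || anyNA(p)) stop("NaN/NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify differential-binding results
#'
#' up: log2FC >= \code{minAbsLog2fc} and FDR <= \code{maxFdr}; down:
#' log2FC <= -\code{minAbsLog2fc} and FDR <= \code{maxFdr}; otherwise
#' unchanged. Bounds are inclusive.
#'
#' @param result data.frame with \code{log2fc} and \code{fdr} columns.
#' @param minAbsLog2fc fold-change threshold (default 1).
#' @param maxFdr FDR threshold (default 0.05).
#' @return character vector in \code{{"up", "down", "unchanged"}}.
#' @export
classifyDb <- function(result, minAbsLog2fc = 1, maxFdr = 0.05) {
  lab <- rep("unchanged", nrow(result))
  sig <- result$fdr <= maxFdr
  lab[sig & result$log2fc >= minAbsLog2fc] <- "up"
  lab[sig & result$log2fc <= -minAbsLog2fc] <- "down"
  lab
}

#' Classify differential-expression results
#'
#' Same rule as \code{\link{classifyDb}} plus a mean-CPM requirement
#' (\code{mean_cpm >= minCpm}), the stringent DE-gene cutoff.
#'
#' @param result data.frame with \code{log2fc}, \code{fdr} and
#'   \code{mean_cpm} columns.
#' @param minAbsLog2fc fold-change threshold (default 1).
#' @param maxPadj adjusted-p threshold (default 0.05).
#' @param minCpm mean CPM threshold (default 1).
#' @return character vector in \code{{"up", "down", "unchanged"}}.
#' @export
classifyDe <- function(result, minAbsLog2fc = 1, maxPadj = 0.05,
                       minCpm = 1) {
  lab <- classifyDb(result, minAbsLog2fc, maxPadj)
  lab[result$mean_cpm < minCpm] <- "unchanged"
  lab
}
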