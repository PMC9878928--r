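## PWM scanning with exact score p-values, +/-20 bp flank extraction around
## motif matches, hamming-distance clustering, information-content logos and
## flank-signature quantification.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Log-odds score matrix of a PWM
#'
#' Scores in bits: \code{s(j, b) = log2(p'(j, b) / bg(b))} where each column
#' is first mixed with \code{pseudocount * background} and renormalised, so
#' all cells are finite.
#'
#' @param pwm a \linkS4class{PWMotif}.
#' @return 4 x W numeric matrix of scores in bits.
#' @export
logOdds <- function(pwm) {
  bg <- pwm@background
  if (any(bg <= 0)) stop("background probabilities must be > 0")
  p <- sweep(pwm@probs + pwm@pseudocount * bg, 2,
             1 + pwm@pseudocount, "/")
  log2(p / bg)
}

#' Exact null distribution of the log-odds score
#'
#' The score of a random W-mer drawn from the background model is discretised
#' on a grid of \code{resolution} bits and its exact distribution obtained by
#' position-wise convolution, giving \code{p(s) = P(score >= s)}. The same
#' discretised integer scores are used by \code{\link{scanMotif}}, so scan
#' p-values are exact with respect to the discretised score.
#'
#' @param pwm a \linkS4class{PWMotif} of width <= 30.
#' @param resolution score grid step in bits (must be <= 0.01).
#' @return list with \code{intScores} (4 x W integer matrix),
#'   \code{resolution}, \code{minScore} (integer offset) and \code{tail}
#'   (numeric vector: \code{tail[k]} = P(intScore >= minScore + k - 1)).
#' @export
scorePvalueTable <- function(pwm, resolution = 0.001) {
  if (motifWidth(pwm) > 30) stop("exact score distribution limited to W <= 30")
  if (resolution > 0.01)
    stop("resolution too coarse: must be <= 0.01 bits")
  s <- logOdds(pwm)
  int <- round(s / resolution)
  storage.mode(int) <- "integer"
  bg <- pwm@background
  ## convolve position by position over the integer score grid
  dist <- c(1)
  off <- 0L
  for (j in seq_len(ncol(int))) {
    colLo <- min(int[, j])
    newOff <- off + colLo
    newLen <- (off + max(int[, j])) - newOff + length(dist)
    nd <- numeric(newLen)
    for (b in seq_len(4)) {
      sh <- int[b, j] - colLo
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
    off <- newOff
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  list(intScores = int, resolution = resolution, minScore = off,
       tail = tail)
}

## P(score >= s) for integer scores s on the table's grid.
tailProb <- function(table, s) {
  k <- s - table$minScore + 1L
  k <- pmin(pmax(k, 1L), length(table$tail) + 1L)
  out <- numeric(length(s))
  inRange <- k <= length(table$tail)
  out[inRange] <- table$tail[k[inRange]]
  out[!inRange] <- 0
  out[s <= table$minScore] <- 1
  out
}

#' Scan sequences with a PWM
#'
#' Both strands are scanned with discretised log-odds scores; windows
#' containing N are skipped. Hits with exact p-value <= \code{pThreshold}
#' are reported and the best-p hit per sequence is flagged for flank
#' extraction.
#'
#' @param seqs named \code{DNAStringSet} or character vector.
#' @param pwm a \linkS4class{PWMotif}.
#' @param pThreshold p-value threshold (default 1e-4).
#' @param background \code{"uniform"}, \code{"seqs"} (0-order model
#'   estimated from the scanned sequences) or \code{"pwm"} (keep the motif's
#'   stored background).
#' @param resolution score grid step in bits.
#' @return data.frame of hits: \code{seq_id}, \code{offset} (0-based match
#'   start on the plus strand), \code{strand}, \code{score} (bits),
#'   \code{p_value}, \code{best} (best hit of its sequence).
#' @export
scanMotif <- function(seqs, pwm, pThreshold = 1e-4,
                      background = c("seqs", "uniform", "pwm"),
                      resolution = 0.001) {
  background <- match.arg(background)
  nms <- names(seqs)
  chars <- toupper(as.character(seqs))
  names(chars) <- if (is.null(nms)) paste0("seq", seq_along(chars)) else nms
  if (background == "uniform") {
    pwm <- PWMotif(pwm@probs, pseudocount = pwm@pseudocount)
  } else if (background == "seqs") {
    tab <- table(factor(strsplit(paste(chars, collapse = ""), "")[[1]],
                        levels = BASES))
    freq <- as.numeric(tab) / sum(tab)
    freq <- (freq + 1e-3) / sum(freq + 1e-3)
    pwm <- PWMotif(pwm@probs, background = stats::setNames(freq, BASES),
                   pseudocount = pwm@pseudocount)
  }
  tabl <- scorePvalueTable(pwm, resolution)
  int <- tabl$intScores
  W <- ncol(int)
  hits <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    v <- strsplit(chars[i], "")[[1]]
    L <- length(v)
    if (L < W) next
    code <- match(v, BASES)                    # NA for N
    rcCode <- rev(5L - code)                   # reverse complement codes
    scoreStrand <- function(cd) {
      nWin <- L - W + 1
      sc <- integer(nWin)
      ok <- rep(TRUE, nWin)
      for (j in seq_len(W)) {
        cj <- cd[j:(j + nWin - 1)]
        bad <- is.na(cj)
        ok <- ok & !bad
        cj[bad] <- 1L
        sc <- sc + int[cbind(cj, j)]
      }
      list(sc = sc, ok = ok)
    }
    fw <- scoreStrand(code)
    rv <- scoreStrand(rcCode)
    pf <- tailProb(tabl, fw$sc)
    pr <- tailProb(tabl, rv$sc)
    keepF <- fw$ok & pf <= pThreshold
    keepR <- rv$ok & pr <= pThreshold
    if (!any(keepF) && !any(keepR)) next
    offF <- which(keepF) - 1L
    offRrc <- which(keepR) - 1L
    hits[[i]] <- data.frame(
      seq_id = names(chars)[i],
      offset = c(offF, L - offRrc - W),
      strand = c(rep("+", length(offF)), rep("-", length(offRrc))),
      score = c(fw$sc[keepF], rv$sc[keepR]) * tabl$resolution,
      p_value = c(pf[keepF], pr[keepR]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), best = logical()))
  o <- order(out$seq_id, out$p_value, -out$score, out$offset)
  out <- out[o, , drop = FALSE]
  out$best <- !duplicated(out$seq_id)
  rownames(out) <- NULL
  out
}

#' Extract orientation-normalised flanks around motif hits
#'
#' Each site's window spans \code{flankBp} bases on each side of the motif
#' core; minus-strand hits are reverse complemented, so column +1..+flank is
#' always downstream (3') of the core in motif orientation. Windows running
#' past a sequence end are padded with N (with a warning).
#'
#' @param hits data.frame from \code{\link{scanMotif}}; only rows with
#'   \code{best = TRUE} are used (one hit per site).
#' @param seqs the scanned sequences.
#' @param coreWidth motif width.
#' @param flankBp flank width (default 20).
#' @return A \linkS4class{FlankAlignment}; row names are sequence ids.
#' @export
extractFlanks <- function(hits, seqs, coreWidth, flankBp = 20) {
  best <- hits[hits$best, , drop = FALSE]
  nms <- names(seqs)
  chars <- toupper(as.character(seqs))
  names(chars) <- if (is.null(nms)) paste0("seq", seq_along(chars)) else nms
  W <- as.integer(coreWidth)
  fl <- as.integer(flankBp)
  total <- W + 2L * fl
  m <- matrix("N", nrow(best), total)
  padded <- 0L
  for (r in seq_len(nrow(best))) {
    v <- strsplit(chars[[best$seq_id[r]]], "")[[1]]
    L <- length(v)
    from <- best$offset[r] + 1L - fl         # 1-based window start
    to <- best$offset[r] + W + fl
    idx <- from:to
    inside <- idx >= 1 & idx <= L
    row <- rep("N", total)
    row[inside] <- v[idx[inside]]
    if (!all(inside)) padded <- padded + 1L
    if (best$strand[r] == "-") row <- rev(COMPLEMENT[row])
    m[r, ] <- row
  }
  if (padded > 0)
    warning(padded, " window(s) truncated at a sequence end were N-padded")
  rownames(m) <- best$seq_id
  new("FlankAlignment", seqs = m, coreWidth = W, flank = fl,
      cluster = rep(NA_integer_, nrow(m)))
}

## Column index of a core-relative offset: negative = upstream of the core
## 5' end, positive = downstream of the core 3' end, in motif orientation.
flankColumn <- function(aln, offset) {
  if (offset == 0 || abs(offset) > aln@flank)
    stop("offset must lie within +/-", aln@flank, ", excluding 0")
  if (offset > 0) aln@flank + aln@coreWidth + offset
  else aln@flank + 1L + offset
}

#' Cluster flank alignments by hamming distance
#'
#' Pairwise normalised hamming distance (positions where either base is N
#' count half a mismatch), average-linkage agglomerative clustering, tree
#' cut at \code{k} clusters, rows ordered by the dendrogram for heatmaps.
#'
#' @param aln a \linkS4class{FlankAlignment}.
#' @param k number of clusters (default 5).
#' @return list with \code{alignment} (cluster slot filled), \code{order}
#'   (dendrogram row order) and \code{hclust} (the tree).
#' @export
hammingCluster <- function(aln, k = 5) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (k > n) stop("k exceeds the number of sites")
  L <- ncol(m)
  nonN <- (m != "N") * 1
  both <- tcrossprod(nonN)                   # positions where both non-N
  matches <- matrix(0, n, n)
  for (b in BASES) matches <- matches + tcrossprod((m == b) * 1)
  mism <- (both - matches) + 0.5 * (L - both)
  D <- stats::as.dist(mism / L)
  hc <- stats::hclust(D, method = "average")
  cl <- stats::cutree(hc, k = k)
  aln@cluster <- as.integer(cl)
  list(alignment = aln, order = hc$order, hclust = hc)
}

#' Per-column information content and logo table
#'
#' Information content per column in bits, \code{IC = 2 + sum f log2 f}
#' over A, C, G, T frequencies with N excluded from the counts; all-N
#' columns score 0. Logo heights are \code{f * IC}.
#'
#' @param aln a \linkS4class{FlankAlignment} or a character base matrix.
#' @param cluster optional cluster id: restrict to that cluster's rows.
#' @return data.frame with \code{position} (core-relative: negative
#'   upstream, 1..W core, positive downstream offsets prefixed), columns
#'   \code{A}, \code{C}, \code{G}, \code{T} (logo heights in bits) and
#'   \code{ic} (total column information).
#' @export
columnInformation <- function(aln, cluster = NULL) {
  if (methods::is(aln, "FlankAlignment")) {
    m <- alignmentMatrix(aln)
    if (!is.null(cluster)) m <- m[clusterIds(aln) %in% cluster, , drop = FALSE]
    fl <- aln@flank; W <- aln@coreWidth
    pos <- c(-(fl:1), paste0("c", seq_len(W)), paste0("+", seq_len(fl)))
  } else {
    m <- aln
    pos <- as.character(seq_len(ncol(m)))
  }
  if (nrow(m) < 1) stop("alignment must have at least one row")
  heights <- t(apply(m, 2, function(col) {
    col <- col[col != "N"]
    if (!length(col)) return(c(A = 0, C = 0, G = 0, T = 0))
    f <- table(factor(col, levels = BASES)) / length(col)
    f <- as.numeric(f)
    ic <- 2 + sum(ifelse(f > 0, f * log2(f), 0))
    stats::setNames(f * ic, BASES)
  }))
  data.frame(position = pos, heights, ic = rowSums(heights),
             stringsAsFactors = FALSE)
}

#' Fraction of sites carrying a base at a flank position
#'
#' Counts the rows of the alignment with the given base at a core-relative
#' offset, with a Wilson 95\% confidence interval; a control alignment can
#' be supplied to report an enrichment ratio.
#'
#' @param aln a \linkS4class{FlankAlignment}.
#' @param offset core-relative position (positive = downstream of the core
#'   3' end; e.g. +4).
#' @param base the base (e.g. "G").
#' @param control optional control \code{FlankAlignment}.
#' @param conf confidence level of the Wilson interval.
#' @return list with \code{fraction}, \code{n}, \code{ciLow}, \code{ciHigh}
#'   and, when a control is given, \code{controlFraction} and
#'   \code{enrichment}.
#' @export
signatureFraction <- function(aln, offset, base, control = NULL,
                              conf = 0.95) {
  col <- flankColumn(aln, offset)
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  x <- sum(m[, col] == base)
  ci <- wilsonInterval(x, n, conf)
  out <- list(fraction = x / n, n = n, ciLow = ci[1], ciHigh = ci[2])
  if (!is.null(control)) {
    cm <- alignmentMatrix(control)
    cf <- mean(cm[, flankColumn(control, offset)] == base)
    out$controlFraction <- cf
    out$enrichment <- (x / n) / cf
  }
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector (lower, upper).
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(0, 1))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}
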