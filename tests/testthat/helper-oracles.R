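## Independent brute-force oracles used to check the package implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Non-dominated sorting straight from the definition: peel maxima until the
## set is exhausted (dominated = other >= in both objectives, > in one).
bruteParetoLevels <- function(x, y) {
  n <- length(x)
  lev <- integer(n)
  rem <- seq_len(n)
  l <- 0L
  while (length(rem)) {
    l <- l + 1L
    nonDom <- vapply(rem, function(i) {
      !any(x[rem] >= x[i] & y[rem] >= y[i] &
             (x[rem] > x[i] | y[rem] > y[i]))
    }, logical(1))
    lev[rem[nonDom]] <- l
    rem <- rem[!nonDom]
  }
  lev
}

## O(N*M) all-pairs fragment counting: extend each read to fragmentSize from
## its 5' end, then count >=1 bp overlaps per peak.
bruteCountFragments <- function(reads, peaks, fragmentSize) {
  rs <- start(reads); re <- end(reads)
  minus <- as.character(strand(reads)) == "-"
  fs <- ifelse(minus, re - fragmentSize + 1, rs)
  fe <- fs + fragmentSize - 1
  vapply(seq_along(peaks), function(i) {
    sum(fe >= start(peaks)[i] & fs <= end(peaks)[i])
  }, integer(1))
}

## Step-up BH from the definition: q_(i) = min_{j >= i} m * p_(j) / j.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sortedQ <- vapply(seq_len(m), function(i) {
    min(m * p[o][i:m] / (i:m))
  }, numeric(1))
  q[o] <- pmin(sortedQ, 1)
  q
}

## Exact tail probabilities of the discretised log-odds score by exhaustive
## enumeration of all 4^W words under the motif's background.
bruteScoreTail <- function(pwm, resolution) {
  lo <- zfintegrate::logOdds(pwm)
  int <- round(lo / resolution)
  W <- ncol(int)
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- rowSums(matrix(int[cbind(as.vector(words),
                                 rep(seq_len(W), each = nrow(words)))],
                       nrow(words), W))
  bg <- pwm@background
  wp <- apply(matrix(bg[as.vector(words)], nrow(words), W), 1, prod)
  list(scores = sc, probs = wp)
}

randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 1e6,
                            stranded = TRUE) {
  s <- sort(sample.int(maxPos, n))
  w <- sample(50:500, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w),
          strand = if (stranded) sample(c("+", "-"), n, TRUE) else "*")
}
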