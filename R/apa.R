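## Aggregate peak analysis (P2LL) on contact maps, loop-set comparison
## across conditions, and anchor classification into P/E/CTCF.

#' Aggregate peak analysis with P2LL score
#'
#' For each usable loop the (2w+1) x (2w+1) submatrix centred on the loop
#' pixel (anchor1 bin, anchor2 bin) is cut out, optionally divided by its
#' own mean ("normed" aggregation), and submatrices are averaged
#' element-wise. P2LL is the ratio of the centre pixel(s) to the mean of the
#' lower-left corner block (the corner closest to the diagonal). Loops whose
#' window would cross the matrix edge or come within 2w bins of the
#' diagonal are skipped and counted.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param loops a \linkS4class{LoopSet} in the same coordinates.
#' @param window half-window w in bins (default 10).
#' @param corner lower-left corner block size in bins (default 6).
#' @param center 1 (the central pixel) or 3 (mean of the 3x3 centre block).
#' @param normed divide each submatrix by its own mean before averaging
#'   (default TRUE); set FALSE for raw aggregation.
#' @return An \linkS4class{APAResult}.
#' @export
apaAggregate <- function(map, loops, window = 10, corner = 6, center = 1,
                         normed = TRUE) {
  w <- as.integer(window)
  n <- nrow(map@matrix)
  b1 <- binIndexOf(anchorOne(loops), map@binSize)
  b2 <- binIndexOf(anchorTwo(loops), map@binSize)
  swap <- b1 > b2
  tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  usable <- b1 - w >= 1 & b2 + w <= n & (b2 - b1) >= 2L * w + 1L
  if (!any(usable)) stop("no usable loops for APA")
  agg <- matrix(0, 2 * w + 1, 2 * w + 1)
  for (i in which(usable)) {
    sub <- map@matrix[(b1[i] - w):(b1[i] + w), (b2[i] - w):(b2[i] + w)]
    if (normed) {
      mu <- mean(sub)
      if (mu > 0) sub <- sub / mu
    }
    agg <- agg + sub
  }
  agg <- agg / sum(usable)
  c0 <- w + 1
  centreVal <- if (center >= 3)
    mean(agg[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)]) else agg[c0, c0]
  cornerBlock <- agg[(2 * w + 2 - corner):(2 * w + 1), 1:corner]
  score <- centreVal / mean(cornerBlock)
  new("APAResult", matrix = agg, p2ll = score,
      nLoopsUsed = sum(usable), nLoopsSkipped = sum(!usable),
      windowBins = w, binSize = map@binSize)
}

#' Compare two loop sets
#'
#' Loops are matched when both anchors fall within \code{slackBins} bins of
#' each other. Returns the loops of \code{loopsA} missing from
#' \code{loopsB} (lost), those present in both (retained), and the loops of
#' \code{loopsB} missing from \code{loopsA} (gained).
#'
#' @param loopsA,loopsB \linkS4class{LoopSet}s on the same bin space.
#' @param binSize bin width in bp.
#' @param slackBins anchor matching slack in bins (default 1).
#' @return list of \code{LoopSet}s: \code{lost}, \code{retained},
#'   \code{gained}.
#' @export
compareLoopSets <- function(loopsA, loopsB, binSize, slackBins = 1) {
  binsOf <- function(l) cbind(binIndexOf(anchorOne(l), binSize),
                              binIndexOf(anchorTwo(l), binSize))
  a <- binsOf(loopsA); b <- binsOf(loopsB)
  chrA <- as.character(seqnames(anchorOne(loopsA)))
  chrB <- as.character(seqnames(anchorOne(loopsB)))
  matchedA <- rep(FALSE, length(loopsA))
  matchedB <- rep(FALSE, length(loopsB))
  if (length(loopsA) && length(loopsB)) {
    for (i in seq_len(length(loopsA))) {
      hit <- chrB == chrA[i] &
        abs(b[, 1] - a[i, 1]) <= slackBins &
        abs(b[, 2] - a[i, 2]) <= slackBins
      if (any(hit)) {
        matchedA[i] <- TRUE
        matchedB[hit] <- TRUE
      }
    }
  }
  list(lost = loopsA[!matchedA], retained = loopsA[matchedA],
       gained = loopsB[!matchedB])
}

#' Classify loop anchors into promoter / enhancer / CTCF
#'
#' P: the anchor overlaps both a TSS window (TSS +/- \code{promoterBp}) and
#' an H3K27ac peak. E: it overlaps an H3K27ac peak that is itself not
#' associated with any TSS window. CTCF: everything else.
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param tss \code{GRanges} of TSS positions (width-1 or gene bodies with
#'   strand; TSS windows are built from \code{tssOf}).
#' @param h3k27ac \code{GRanges} of H3K27ac peaks.
#' @param promoterBp TSS window half-width (default 2000).
#' @return the \code{LoopSet} with anchor categories filled in.
#' @export
classifyAnchors <- function(loops, tss, h3k27ac, promoterBp = 2000) {
  tssPos <- tssOf(tss)
  tssWin <- GRanges(seqnames(tss),
                    IRanges(pmax(1, tssPos - promoterBp),
                            tssPos + promoterBp))
  enhancer <- h3k27ac[GenomicRanges::countOverlaps(
    h3k27ac, tssWin, ignore.strand = TRUE) == 0]
  classify <- function(anchors) {
    hasTss <- GenomicRanges::countOverlaps(anchors, tssWin,
                                           ignore.strand = TRUE) > 0
    hasK27 <- GenomicRanges::countOverlaps(anchors, h3k27ac,
                                           ignore.strand = TRUE) > 0
    hasEnh <- GenomicRanges::countOverlaps(anchors, enhancer,
                                           ignore.strand = TRUE) > 0
    ifelse(hasTss & hasK27, "P", ifelse(hasEnh, "E", "CTCF"))
  }
  loops@category1 <- classify(anchorOne(loops))
  loops@category2 <- classify(anchorTwo(loops))
  methods::validObject(loops)
  loops
}

#' Unordered loop categories
#'
#' @param loops a classified \linkS4class{LoopSet}.
#' @return character vector like \code{"P-E"}; anchor order is ignored
#'   (P-E and E-P coincide).
#' @export
loopCategory <- function(loops) {
  lv <- c("P", "E", "CTCF")
  c1 <- loops@category1; c2 <- loops@category2
  if (anyNA(c1) || anyNA(c2)) stop("anchors are not classified")
  first <- pmin(match(c1, lv), match(c2, lv))
  second <- pmax(match(c1, lv), match(c2, lv))
  paste(lv[first], lv[second], sep = "-")
}

#' Loop-category table with enrichment tests between two loop sets
#'
#' Counts unordered anchor-category combinations in two loop sets (e.g.
#' lost vs retained) and, per category, tests the 2x2 contingency
#' (category vs not, set A vs set B) with Fisher's exact test. The sample
#' odds ratio is the cross-product \code{(a*d)/(b*c)} with
#' \code{a = category count in A}, \code{b = rest of A}, \code{c} and
#' \code{d} likewise in B; degenerate tables (a zero margin) are flagged.
#'
#' @param loopsA,loopsB classified \linkS4class{LoopSet}s.
#' @param labels names of the two sets (default lost/retained).
#' @return data.frame: category, counts in each set, \code{odds_ratio},
#'   \code{p_value}, \code{degenerate}.
#' @export
loopCategoryTable <- function(loopsA, loopsB,
                              labels = c("lost", "retained")) {
  if (!length(loopsA) || !length(loopsB)) stop("empty loop set")
  catA <- loopCategory(loopsA)
  catB <- loopCategory(loopsB)
  cats <- c("P-P", "P-E", "E-E", "P-CTCF", "E-CTCF", "CTCF-CTCF")
  res <- lapply(cats, function(cc) {
    a <- sum(catA == cc); b <- length(catA) - a
    c2 <- sum(catB == cc); d <- length(catB) - c2
    degenerate <- (a + c2 == 0) || (b + d == 0)
    orat <- if (degenerate) NA_real_ else (a * d) / (b * c2)
    p <- if (degenerate) NA_real_ else
      stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE))$p.value
    data.frame(category = cc, nA = a, nB = c2, odds_ratio = orat,
               p_value = p, degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("n_", labels)
  out
}

#' Fraction of loop anchors overlapping peaks
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param peaks \code{GRanges}.
#' @param mode \code{"anchors"} (default; the numerator counts anchors, the
#'   denominator is 2x the loop count), \code{"both"} (loops with both
#'   anchors over a peak) or \code{"either"} (loops with at least one).
#' @return fraction in [0, 1].
#' @export
anchorPeakOverlap <- function(loops, peaks,
                              mode = c("anchors", "both", "either")) {
  mode <- match.arg(mode)
  if (!length(loops)) return(0)
  h1 <- GenomicRanges::countOverlaps(anchorOne(loops), peaks,
                                     ignore.strand = TRUE) > 0
  h2 <- GenomicRanges::countOverlaps(anchorTwo(loops), peaks,
                                     ignore.strand = TRUE) > 0
  switch(mode,
         anchors = mean(c(h1, h2)),
         both = mean(h1 & h2),
         either = mean(h1 | h2))
}
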