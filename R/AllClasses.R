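#' @import methods
#' @importFrom GenomicRanges GRanges start end width strand seqnames mcols mcols<-
#'   findOverlaps reduce resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Feature-by-sample count container with optional spike-in companion
#'
#' Holds a non-negative integer matrix of fragment or read counts (features in
#' rows, samples in columns) together with an optional spike-in count matrix
#' over its own feature set but the same samples. The spike-in matrix carries
#' counts of exogenous chromatin (e.g. Drosophila) used to derive size factors
#' that are insensitive to global binding loss.
#'
#' @slot counts integer matrix, features x samples, with unique row and column
#'   names.
#' @slot spikein integer matrix with the same column names as \code{counts},
#'   or a 0x0 matrix when absent.
#'
#' @export
setClass("CountTable", representation(counts = "matrix", spikein = "matrix"))

setValidity("CountTable", function(object) {
  m <- object@counts
  msg <- character()
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    msg <- c(msg, "counts must have unique row names (feature ids)")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "counts must have unique column names (sample ids)")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  s <- object@spikein
  if (length(s)) {
    if (!identical(colnames(s), colnames(m)))
      msg <- c(msg, "spike-in columns must match count table samples")
    if (any(s < 0) || any(s != round(s)))
      msg <- c(msg, "spike-in counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of non-negative integer counts with feature
#'   row names and sample column names.
#' @param spikein optional matrix of spike-in feature counts for the same
#'   samples.
#' @return A \linkS4class{CountTable}.
#' @examples
#' m <- matrix(rpois(8, 10), 4, 2,
#'             dimnames = list(paste0("p", 1:4), c("s1", "s2")))
#' CountTable(m)
#' @export
CountTable <- function(counts, spikein = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(spikein)) spikein <- matrix(0, 0, 0) else {
    spikein <- as.matrix(spikein)
    storage.mode(spikein) <- "double"
  }
  new("CountTable", counts = counts, spikein = spikein)
}

#' @describeIn CountTable-class the count matrix
#' @param object,x a \code{CountTable}
#' @export
setGeneric("countsOf", function(object) standardGeneric("countsOf"))

#' @rdname CountTable-class
#' @export
setMethod("countsOf", "CountTable", function(object) object@counts)

#' @describeIn CountTable-class the spike-in matrix (or NULL)
#' @export
setGeneric("spikeinCounts", function(object) standardGeneric("spikeinCounts"))

#' @rdname CountTable-class
#' @export
setMethod("spikeinCounts", "CountTable", function(object) {
  if (length(object@spikein)) object@spikein else NULL
})

#' @rdname CountTable-class
#' @export
setMethod("dim", "CountTable", function(x) dim(x@counts))

#' @rdname CountTable-class
#' @export
setMethod("show", "CountTable", function(object) {
  cat("CountTable:", nrow(object@counts), "features x",
      ncol(object@counts), "samples")
  if (length(object@spikein))
    cat(";", nrow(object@spikein), "spike-in features")
  cat("\n")
})

#' Binned symmetric contact map over one chromosome
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp.
#' @slot matrix square symmetric non-negative matrix of contact values; bin b
#'   covers \code{[(b-1)*binSize, b*binSize)}.
#' @export
setClass("ContactMap",
         representation(chrom = "character", binSize = "numeric",
                        matrix = "matrix"))

setValidity("ContactMap", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "contact matrix must be square")
  else if (max(abs(m - t(m))) > 1e-9)
    msg <- c(msg, "contact matrix must be symmetric (tolerance 1e-9)")
  if (any(m < 0)) msg <- c(msg, "contact values must be non-negative")
  if (object@binSize <= 0) msg <- c(msg, "binSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMap
#' @param chrom chromosome name.
#' @param binSize bin width in bp.
#' @param matrix square symmetric matrix of contact values.
#' @return A \linkS4class{ContactMap}.
#' @export
ContactMap <- function(chrom, binSize, matrix) {
  new("ContactMap", chrom = as.character(chrom), binSize = binSize,
      matrix = as.matrix(matrix))
}

#' @rdname ContactMap-class
#' @param object a \code{ContactMap}
#' @export
setMethod("show", "ContactMap", function(object) {
  cat("ContactMap on", object@chrom, "-", nrow(object@matrix), "bins of",
      object@binSize, "bp\n")
})

#' Set of chromatin loops (anchor pairs)
#'
#' Anchors are stored as two parallel \code{GRanges}; within each loop
#' anchor1 starts upstream of (or at) anchor2 and both lie on the same
#' chromosome. Optional anchor categories (P/E/CTCF) are kept per anchor.
#'
#' @slot anchor1,anchor2 parallel \code{GRanges} of loop anchors.
#' @slot category1,category2 character vectors of anchor categories
#'   (\code{NA} when unclassified).
#' @export
setClass("LoopSet",
         representation(anchor1 = "GRanges", anchor2 = "GRanges",
                        category1 = "character", category2 = "character"))

setValidity("LoopSet", function(object) {
  msg <- character()
  if (length(object@anchor1) != length(object@anchor2))
    msg <- c(msg, "anchor1 and anchor2 must be parallel")
  else if (length(object@anchor1)) {
    if (!all(as.character(seqnames(object@anchor1)) ==
             as.character(seqnames(object@anchor2))))
      msg <- c(msg, "loop anchors must be on the same chromosome")
    if (!all(start(object@anchor1) <= start(object@anchor2)))
      msg <- c(msg, "anchor1 must start upstream of anchor2")
  }
  if (length(object@category1) != length(object@anchor1) ||
      length(object@category2) != length(object@anchor1))
    msg <- c(msg, "category vectors must be parallel to anchors")
  ok <- c("P", "E", "CTCF", NA)
  if (!all(object@category1 %in% ok) || !all(object@category2 %in% ok))
    msg <- c(msg, "anchor categories must be P, E, CTCF or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a LoopSet
#'
#' Anchors given in reverse genomic order are swapped so that anchor1 is
#' always the upstream anchor.
#'
#' @param anchor1,anchor2 parallel \code{GRanges} of anchors (same chromosome
#'   within each loop).
#' @return A \linkS4class{LoopSet}.
#' @export
LoopSet <- function(anchor1, anchor2) {
  if (length(anchor1) != length(anchor2))
    stop("anchor1 and anchor2 must have the same length")
  if (length(anchor1) &&
      !all(as.character(seqnames(anchor1)) == as.character(seqnames(anchor2))))
    stop("loop anchors must be on the same chromosome")
  swap <- start(anchor1) > start(anchor2)
  if (any(swap)) {
    a1 <- anchor1
    anchor1[swap] <- anchor2[swap]
    anchor2[swap] <- a1[swap]
  }
  n <- length(anchor1)
  new("LoopSet", anchor1 = anchor1, anchor2 = anchor2,
      category1 = rep(NA_character_, n), category2 = rep(NA_character_, n))
}

#' @rdname LoopSet-class
#' @param x,object a \code{LoopSet}
#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' @rdname LoopSet-class
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
  new("LoopSet", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
      category1 = x@category1[i], category2 = x@category2[i])
})

#' @describeIn LoopSet-class upstream anchors
#' @export
setGeneric("anchorOne", function(object) standardGeneric("anchorOne"))

#' @rdname LoopSet-class
#' @export
setMethod("anchorOne", "LoopSet", function(object) object@anchor1)

#' @describeIn LoopSet-class downstream anchors
#' @export
setGeneric("anchorTwo", function(object) standardGeneric("anchorTwo"))

#' @rdname LoopSet-class
#' @export
setMethod("anchorTwo", "LoopSet", function(object) object@anchor2)

#' @describeIn LoopSet-class per-anchor categories as a 2-column matrix
#' @export
setGeneric("anchorCategories", function(object)
  standardGeneric("anchorCategories"))

#' @rdname LoopSet-class
#' @export
setMethod("anchorCategories", "LoopSet", function(object)
  cbind(object@category1, object@category2))

#' @rdname LoopSet-class
#' @export
setMethod("show", "LoopSet", function(object) {
  cat("LoopSet of", length(object), "loops")
  if (any(!is.na(object@category1))) {
    tab <- table(loopCategory(object))
    cat(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

#' Position weight matrix with background model
#'
#' @slot probs 4 x W probability matrix, rows A, C, G, T; columns sum to 1.
#' @slot background named probabilities over A, C, G, T summing to 1.
#' @slot pseudocount pseudocount weight mixed into each column (proportional
#'   to the background) before log-odds are formed.
#' @export
setClass("PWMotif",
         representation(probs = "matrix", background = "numeric",
                        pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  msg <- character()
  if (!identical(rownames(object@probs), c("A", "C", "G", "T")))
    msg <- c(msg, "probs rows must be A, C, G, T")
  if (ncol(object@probs) < 1) msg <- c(msg, "motif width must be >= 1")
  if (any(abs(colSums(object@probs) - 1) > 1e-9))
    msg <- c(msg, "each PWM column must sum to 1 (tolerance 1e-9)")
  if (any(object@probs < 0)) msg <- c(msg, "PWM probabilities must be >= 0")
  bg <- object@background
  if (!identical(names(bg), c("A", "C", "G", "T")) ||
      abs(sum(bg) - 1) > 1e-9)
    msg <- c(msg, "background must be named A,C,G,T probabilities summing to 1")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PWMotif
#'
#' @param probs 4 x W probability matrix (rows A, C, G, T) or a character
#'   consensus string; a consensus is expanded so the stated base has
#'   probability \code{consensusProb} and the rest is split evenly.
#' @param background named background probabilities (default uniform).
#' @param pseudocount pseudocount used before log-odds (default 0.01).
#' @param consensusProb probability given to the consensus base when
#'   \code{probs} is a string.
#' @return A \linkS4class{PWMotif}.
#' @examples
#' PWMotif("ACGT")
#' @export
PWMotif <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25),
                    pseudocount = 0.01, consensusProb = 0.85) {
  if (is.character(probs)) {
    bases <- strsplit(toupper(probs), "")[[1]]
    if (!all(bases %in% c("A", "C", "G", "T")))
      stop("consensus must be over A, C, G, T")
    m <- matrix((1 - consensusProb) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(bases, rownames(m)), seq_along(bases))] <- consensusProb
    probs <- m
  }
  probs <- as.matrix(probs)
  if (is.null(rownames(probs)) && nrow(probs) == 4)
    rownames(probs) <- c("A", "C", "G", "T")
  probs <- probs[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background[c("A", "C", "G", "T")]
  names(background) <- c("A", "C", "G", "T")
  new("PWMotif", probs = probs, background = background,
      pseudocount = pseudocount)
}

#' @describeIn PWMotif-class motif width in bp
#' @param object a \code{PWMotif}
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))

#' @rdname PWMotif-class
#' @export
setMethod("motifWidth", "PWMotif", function(object) ncol(object@probs))

#' @rdname PWMotif-class
#' @export
setMethod("show", "PWMotif", function(object) {
  cons <- rownames(object@probs)[apply(object@probs, 2, which.max)]
  cat("PWMotif of width", motifWidth(object), "- consensus",
      paste(cons, collapse = ""), "\n")
})

#' Orientation-normalised flank alignment around motif matches
#'
#' Each row is one site: \code{flank} bases upstream, the motif core, and
#' \code{flank} bases downstream, always in motif (plus-strand) orientation.
#' Truncated windows are padded with N.
#'
#' @slot seqs character matrix of single bases (A, C, G, T, N), one row per
#'   site.
#' @slot coreWidth width of the motif core.
#' @slot flank flank width on each side.
#' @slot cluster integer cluster ids (NA before clustering).
#' @export
setClass("FlankAlignment",
         representation(seqs = "matrix", coreWidth = "integer",
                        flank = "integer", cluster = "integer"))

setValidity("FlankAlignment", function(object) {
  msg <- character()
  if (ncol(object@seqs) != object@coreWidth + 2L * object@flank)
    msg <- c(msg, "alignment must have coreWidth + 2*flank columns")
  if (!all(object@seqs %in% c("A", "C", "G", "T", "N")))
    msg <- c(msg, "alignment alphabet is A, C, G, T, N")
  if (length(object@cluster) != nrow(object@seqs))
    msg <- c(msg, "cluster vector must be parallel to rows")
  if (length(msg)) msg else TRUE
})

#' @rdname FlankAlignment-class
#' @param object a \code{FlankAlignment}
#' @export
setMethod("show", "FlankAlignment", function(object) {
  cat("FlankAlignment:", nrow(object@seqs), "sites,",
      object@flank, "bp flanks around a", object@coreWidth, "bp core")
  if (any(!is.na(object@cluster)))
    cat(";", length(unique(object@cluster)), "clusters")
  cat("\n")
})

#' @describeIn FlankAlignment-class the base matrix
#' @export
setGeneric("alignmentMatrix", function(object)
  standardGeneric("alignmentMatrix"))

#' @rdname FlankAlignment-class
#' @export
setMethod("alignmentMatrix", "FlankAlignment", function(object) object@seqs)

#' @describeIn FlankAlignment-class cluster assignments (NA if unclustered)
#' @export
setGeneric("clusterIds", function(object) standardGeneric("clusterIds"))

#' @rdname FlankAlignment-class
#' @export
setMethod("clusterIds", "FlankAlignment", function(object) object@cluster)

#' Aggregate peak analysis result
#'
#' @slot matrix aggregated (2w+1) x (2w+1) submatrix centred on loop pixels.
#' @slot p2ll ratio of the centre pixel(s) to the mean of the lower-left
#'   corner block.
#' @slot nLoopsUsed,nLoopsSkipped loops aggregated / filtered (edge or
#'   short-range).
#' @slot windowBins half-window w in bins.
#' @slot binSize bin width in bp.
#' @export
setClass("APAResult",
         representation(matrix = "matrix", p2ll = "numeric",
                        nLoopsUsed = "integer", nLoopsSkipped = "integer",
                        windowBins = "integer", binSize = "numeric"))

setValidity("APAResult", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m) || nrow(m) %% 2 == 0)
    "APA matrix must be square with odd dimension" else TRUE
})

#' @rdname APAResult-class
#' @param object an \code{APAResult}
#' @export
setMethod("show", "APAResult", function(object) {
  cat("APAResult: P2LL =", signif(object@p2ll, 4), "from",
      object@nLoopsUsed, "loops (", object@nLoopsSkipped, "skipped ),",
      "window +/-", object@windowBins, "bins of", object@binSize, "bp\n")
})

#' @describeIn APAResult-class the P2LL score
#' @export
setGeneric("p2ll", function(object) standardGeneric("p2ll"))

#' @rdname APAResult-class
#' @export
setMethod("p2ll", "APAResult", function(object) object@p2ll)

#' @describeIn APAResult-class the aggregate matrix
#' @export
setGeneric("apaMatrix", function(object) standardGeneric("apaMatrix"))

#' @rdname APAResult-class
#' @export
setMethod("apaMatrix", "APAResult", function(object) object@matrix)

#' Per-sample normalisation factors
#'
#' @slot factors named positive factors, one per sample.
#' @slot method how they were derived: \code{"TMM"} or
#'   \code{"spikein_median_ratio"}.
#' @export
setClass("NormFactors",
         representation(factors = "numeric", method = "character"))

setValidity("NormFactors", function(object) {
  msg <- character()
  if (is.null(names(object@factors)))
    msg <- c(msg, "factors must be named by sample")
  if (any(!is.finite(object@factors)) || any(object@factors <= 0))
    msg <- c(msg, "factors must be finite and > 0")
  if (!object@method %in% c("TMM", "spikein_median_ratio"))
    msg <- c(msg, "method must be TMM or spikein_median_ratio")
  if (length(msg)) msg else TRUE
})

#' @describeIn NormFactors-class the named factor vector
#' @param object a \code{NormFactors}
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))

#' @rdname NormFactors-class
#' @export
setMethod("normFactors", "NormFactors", function(object) object@factors)

#' @rdname NormFactors-class
#' @export
setMethod("show", "NormFactors", function(object) {
  cat("NormFactors (", object@method, "):\n", sep = "")
  print(signif(object@factors, 4))
})
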