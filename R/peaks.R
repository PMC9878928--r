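## Reproducible-peak filtering, scaling factors, fragment counting over peaks
## and priority-based genomic annotation.

#' Reproducible peaks across replicates
#'
#' A peak is reproducible when it was called at high confidence in at least
#' one replicate and overlaps (>= 1 bp) a low-confidence call in the other
#' replicates. High-confidence calls count as low-confidence calls too. The
#' reported interval is the high-tier interval; overlapping high-tier calls
#' from several replicates are merged.
#'
#' @param replicatePeaks list (one element per replicate) of \code{GRanges}
#'   with a \code{tier} metadata column in \code{{"high", "low"}}.
#' @param othersMode \code{"all"} (default): a low-tier overlap is required
#'   in every other replicate; \code{"any"}: in at least one other
#'   replicate.
#' @return \code{GRanges} of merged reproducible peak intervals with fresh
#'   \code{peak_id}s.
#' @examples
#' r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'                              tier = "high")
#' r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250),
#'                              tier = "low")
#' reproduciblePeaks(list(r1, r2))
#' @export
reproduciblePeaks <- function(replicatePeaks, othersMode = c("all", "any")) {
  othersMode <- match.arg(othersMode)
  if (length(replicatePeaks) < 2)
    stop("reproducible-peak filtering needs >= 2 replicates; ",
         "with a single replicate pass peaks through unfiltered")
  for (r in replicatePeaks) {
    tier <- mcols(r)$tier
    if (is.null(tier) || !all(tier %in% c("high", "low")))
      stop("every replicate needs a 'tier' column with values high/low")
  }
  nRep <- length(replicatePeaks)
  kept <- list()
  for (i in seq_len(nRep)) {
    hi <- replicatePeaks[[i]][mcols(replicatePeaks[[i]])$tier == "high"]
    if (!length(hi)) next
    support <- vapply(seq_len(nRep)[-i], function(j) {
      GenomicRanges::countOverlaps(hi, replicatePeaks[[j]]) > 0
    }, logical(length(hi)))
    support <- matrix(support, nrow = length(hi))
    ok <- if (othersMode == "all") rowSums(support) == nRep - 1 else
      rowSums(support) > 0
    kept[[length(kept) + 1]] <- hi[ok]
  }
  if (!length(kept)) return(GRanges())
  merged <- reduce(unstrand(do.call(c, unname(kept))))
  if (length(merged))
    mcols(merged)$peak_id <- sprintf("rp%05d", seq_along(merged))
  merged
}

#' @importFrom GenomicRanges countOverlaps
#' @importFrom BiocGenerics unstrand
NULL

#' Merge reproducible peak sets across conditions
#'
#' Overlapping intervals across conditions become single features; the
#' contributing condition(s) are recorded per merged peak.
#'
#' @param peakSets named list of \code{GRanges}, one per condition.
#' @return \code{GRanges} with \code{peak_id} and \code{conditions} columns.
#' @export
mergeConditionPeaks <- function(peakSets) {
  if (is.null(names(peakSets)))
    names(peakSets) <- paste0("condition", seq_along(peakSets))
  all <- do.call(c, unname(lapply(peakSets, unstrand)))
  merged <- reduce(all)
  prov <- vapply(seq_along(merged), function(i) {
    hit <- vapply(peakSets, function(s)
      GenomicRanges::countOverlaps(merged[i], s) > 0, TRUE)
    paste(names(peakSets)[hit], collapse = ",")
  }, "")
  mcols(merged) <- NULL
  mcols(merged)$peak_id <- sprintf("mp%05d", seq_along(merged))
  mcols(merged)$conditions <- prov
  merged
}

#' Count ChIP fragments over peaks
#'
#' Each read is extended from its 5' end in strand direction to the
#' estimated fragment size, and a peak's count is the number of extended
#' fragments overlapping it by at least 1 bp.
#'
#' @param reads stranded \code{GRanges} of read intervals.
#' @param peaks \code{GRanges} of peaks.
#' @param fragmentSize fragment size in bp (>= 1).
#' @return integer vector of counts, one per peak, named by \code{peak_id}
#'   when present.
#' @export
countFragments <- function(reads, peaks, fragmentSize) {
  if (fragmentSize < 1) stop("fragmentSize must be >= 1")
  if (any(as.character(strand(reads)) == "*"))
    stop("reads must be stranded for fragment extension")
  frags <- resize(reads, fragmentSize, fix = "start")
  n <- GenomicRanges::countOverlaps(peaks, frags, ignore.strand = TRUE)
  if (!is.null(mcols(peaks)$peak_id)) names(n) <- mcols(peaks)$peak_id
  n
}

#' Library-size scaling factor
#'
#' Scales a sample's signal to a standard 15 million reads.
#'
#' @param libSize number of uniquely mapped reads (vectorised).
#' @return data.frame with columns \code{factor} (= 1.5e7 / libSize) and
#'   \code{basis}.
#' @export
scaleFactorLibsize <- function(libSize) {
  if (any(libSize <= 0)) stop("library size must be > 0")
  data.frame(factor = 15e6 / libSize, basis = "libsize")
}

#' Spike-in scaling factor
#'
#' Scales a sample's signal so that spike-in reads count 1 million.
#'
#' @param spikeinReads number of uniquely mapped spike-in reads (vectorised).
#' @return data.frame with columns \code{factor} (= 1e6 / spikeinReads) and
#'   \code{basis}.
#' @export
scaleFactorSpikein <- function(spikeinReads) {
  if (any(spikeinReads <= 0))
    stop("no spike-in reads: spike-in scaling is impossible; ",
         "use scaleFactorLibsize instead")
  data.frame(factor = 1e6 / spikeinReads, basis = "spikein_total")
}

#' Annotate peaks against gene models by fixed category priority
#'
#' Each peak is anchored at its summit (metadata column \code{summit}) or at
#' its midpoint and assigned the first matching category in the priority
#' order Promoter.Up, Promoter.Down, Exonic/Intronic (or Genic when no exon
#' models are supplied), TES, distal5, distal3, intergenic. Promoter and
#' distal windows are strand-aware relative to the gene.
#'
#' @param peaks \code{GRanges} of peaks (optionally with \code{summit}).
#' @param genes stranded \code{GRanges} of gene bodies with \code{gene_id}.
#' @param exons optional \code{GRanges} of exons (any isoform) used to split
#'   genic hits into Exonic/Intronic.
#' @param promoterBp promoter / TES window half-width (default 2000).
#' @param distalBp distal window width (default 50000).
#' @return data.frame with one row per peak: \code{peak_id},
#'   \code{category}, \code{assigned_gene}.
#' @export
annotatePeaks <- function(peaks, genes, exons = NULL, promoterBp = 2000,
                          distalBp = 50000) {
  anchor <- if (!is.null(mcols(peaks)$summit)) mcols(peaks)$summit else
    floor((start(peaks) + end(peaks)) / 2)
  anchorGr <- GRanges(seqnames(peaks), IRanges(anchor, anchor))
  ids <- if (!is.null(mcols(peaks)$peak_id)) mcols(peaks)$peak_id else
    as.character(seq_along(peaks))

  pad <- distalBp + promoterBp
  searchWin <- GRanges(seqnames(genes),
                       IRanges(pmax(1, start(genes) - pad), end(genes) + pad))
  ov <- findOverlaps(anchorGr, searchWin, ignore.strand = TRUE)
  pi <- queryHits(ov); gi <- subjectHits(ov)

  tss <- tssOf(genes)[gi]
  tes <- tesOf(genes)[gi]
  minus <- as.character(strand(genes))[gi] == "-"
  pos <- anchor[pi]
  dTss <- ifelse(minus, tss - pos, pos - tss)
  dTes <- ifelse(minus, tes - pos, pos - tes)
  inBody <- pos >= start(genes)[gi] & pos <= end(genes)[gi]

  genic <- if (is.null(exons)) "Genic" else {
    inExon <- GenomicRanges::countOverlaps(anchorGr,
                                           exons, ignore.strand = TRUE) > 0
    ifelse(inExon[pi], "Exonic", "Intronic")
  }
  priority <- c("Promoter.Up", "Promoter.Down", "Exonic", "Intronic",
                "Genic", "TES", "distal5", "distal3", "intergenic")
  cat <- rep("intergenic", length(pi))
  cat[dTes > promoterBp & dTes <= distalBp] <- "distal3"
  cat[dTss < -promoterBp & dTss >= -distalBp] <- "distal5"
  cat[abs(dTes) <= promoterBp] <- "TES"
  if (length(genic) == 1) {
    cat[inBody] <- genic
  } else {
    cat[inBody] <- genic[inBody]
  }
  cat[dTss >= 0 & dTss <= promoterBp] <- "Promoter.Down"
  cat[dTss < 0 & dTss >= -promoterBp] <- "Promoter.Up"

  rank <- match(cat, priority)
  o <- order(pi, rank, abs(dTss))
  keep <- !duplicated(pi[o])
  sel <- o[keep]
  out <- data.frame(peak_id = ids, category = "intergenic",
                    assigned_gene = NA_character_,
                    stringsAsFactors = FALSE)
  out$category[pi[sel]] <- cat[sel]
  out$assigned_gene[pi[sel]] <- mcols(genes)$gene_id[gi[sel]]
  out$assigned_gene[out$category == "intergenic"] <- NA_character_
  out
}
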