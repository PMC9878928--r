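## Gene-peak combined z-scores and Pareto-level selection of
## correlated / anti-correlated pairs.

#' z-scores of log2 fold changes
#'
#' Each feature's log2 fold change is divided by the standard deviation of
#' all fold changes in the table (sample sd, no centring), so that
#' \code{z * sd} reconstructs the fold change exactly.
#'
#' @param fc data.frame with \code{feature_id} and \code{log2fc} columns.
#' @return list with \code{z} (named numeric) and \code{sd} (the common
#'   denominator).
#' @export
zscoreFoldChanges <- function(fc) {
  x <- fc$log2fc
  if (sum(is.finite(x)) < 2)
    stop("need >= 2 features with finite log2 fold changes")
  s <- stats::sd(x[is.finite(x)])
  if (s == 0) stop("all fold changes identical: sd is zero")
  list(z = stats::setNames(x / s, fc$feature_id), sd = s)
}

#' Associate genes with peaks in their neighbourhood
#'
#' Emits a (gene, peak) pair whenever the peak overlaps the window
#' \code{[min(TSS, TES) - flankBp, max(TSS, TES) + flankBp]} of the gene
#' (strand-independent genomic span). A peak may pair with several genes
#' and vice versa.
#'
#' @param genes stranded \code{GRanges} with \code{gene_id}.
#' @param peaks \code{GRanges} with \code{peak_id}.
#' @param flankBp window half-width beyond the gene span (default 50000).
#' @return data.frame with columns \code{gene_id}, \code{peak_id}.
#' @export
associateGenePeaks <- function(genes, peaks, flankBp = 50000) {
  win <- GRanges(seqnames(genes),
                 IRanges(pmax(1, start(genes) - flankBp),
                         end(genes) + flankBp))
  ov <- findOverlaps(win, peaks, ignore.strand = TRUE)
  data.frame(gene_id = mcols(genes)$gene_id[queryHits(ov)],
             peak_id = mcols(peaks)$peak_id[subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Combined gene-peak z-scores
#'
#' For each pair the combined score is the product \code{z_g * z_p}; a
#' positive product means expression and binding moved in the same
#' direction (correlated), a negative product the opposite
#' (anti-correlated). Zero products get no class.
#'
#' @param pairs data.frame with \code{gene_id}, \code{peak_id}.
#' @param zGenes,zPeaks outputs of \code{\link{zscoreFoldChanges}} (or named
#'   numeric vectors).
#' @return data.frame with columns \code{gene_id}, \code{peak_id},
#'   \code{z_g}, \code{z_p}, \code{z_gp}, \code{correlation_class}.
#' @export
combinedScores <- function(pairs, zGenes, zPeaks) {
  zg <- if (is.list(zGenes)) zGenes$z else zGenes
  zp <- if (is.list(zPeaks)) zPeaks$z else zPeaks
  if (!all(pairs$gene_id %in% names(zg)))
    stop("missing gene z-scores for some pairs")
  if (!all(pairs$peak_id %in% names(zp)))
    stop("missing peak z-scores for some pairs")
  z_g <- unname(zg[pairs$gene_id])
  z_p <- unname(zp[pairs$peak_id])
  z_gp <- z_g * z_p
  cls <- ifelse(z_gp > 0, "correlated",
                ifelse(z_gp < 0, "anti_correlated", NA))
  data.frame(pairs, z_g = z_g, z_p = z_p, z_gp = z_gp,
             correlation_class = cls, stringsAsFactors = FALSE)
}

#' Pareto levels by non-dominated sorting
#'
#' Both objectives are maximised. Level 1 holds the pairs dominated by no
#' other pair (another pair dominates when it is >= in both objectives and
#' > in at least one); level k holds the non-dominated pairs once levels
#' < k are removed. Identical objective vectors share a level.
#'
#' @param x,y numeric objective vectors (e.g. |z_g| and |z_p|).
#' @return integer vector of Pareto levels (empty input gives empty output).
#' @examples
#' paretoLevels(c(3, 2, 1, 1), c(3, 1, 2, 1))  # 1 2 2 3
#' @export
paretoLevels <- function(x, y) {
  n <- length(x)
  if (n == 0) return(integer(0))
  stopifnot(length(y) == n, all(is.finite(x)), all(is.finite(y)))
  ## collapse duplicated objective vectors: ties share a level
  key <- paste(x, y, sep = "\r")
  uk <- !duplicated(key)
  ux <- x[uk]; uy <- y[uk]
  o <- order(-ux, -uy)
  lev <- integer(length(ux))
  ## M[l] = max y among points assigned level l so far; processing in
  ## decreasing x (then y), a point's level is 1 + the deepest level whose
  ## running max y still dominates it. M is non-increasing, so binary search.
  M <- numeric(0)
  for (i in o) {
    yi <- uy[i]
    ## smallest level l with M[l] < yi (no dominator at l or deeper)
    lo <- 1L; hi <- length(M); l <- length(M) + 1L
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (M[mid] < yi) { l <- mid; hi <- mid - 1L } else lo <- mid + 1L
    }
    lev[i] <- l
    if (l > length(M)) M <- c(M, yi) else M[l] <- yi
  }
  lev[match(key, key[uk])]
}

#' Attach Pareto levels to scored pairs
#'
#' Levels are computed separately within each correlation class, maximising
#' \code{(|z_g|, |z_p|)} (default) or, alternatively, \code{|z_gp|} as a
#' single objective.
#'
#' @param scored data.frame from \code{\link{combinedScores}}.
#' @param objective \code{"two_sided"} (|z_g|, |z_p|) or
#'   \code{"abs_product"} (|z_gp|).
#' @return the input with an integer \code{pareto_level} column (NA for
#'   pairs without a correlation class).
#' @export
paretoRank <- function(scored, objective = c("two_sided", "abs_product")) {
  objective <- match.arg(objective)
  scored$pareto_level <- NA_integer_
  for (cls in c("correlated", "anti_correlated")) {
    idx <- which(!is.na(scored$correlation_class) &
                   scored$correlation_class == cls)
    if (!length(idx)) next
    scored$pareto_level[idx] <- if (objective == "two_sided")
      paretoLevels(abs(scored$z_g[idx]), abs(scored$z_p[idx]))
    else
      paretoLevels(abs(scored$z_gp[idx]), abs(scored$z_gp[idx]))
  }
  scored
}

#' Select pairs from the top Pareto levels
#'
#' @param ranked data.frame from \code{\link{paretoRank}}.
#' @param maxLevel keep pairs with level <= this (default 10).
#' @return the selected rows, flagged \code{selected = TRUE}, per
#'   correlation class ("most correlated" / "most anti-correlated").
#' @export
selectTopLevels <- function(ranked, maxLevel = 10) {
  sel <- ranked[!is.na(ranked$pareto_level) &
                  ranked$pareto_level <= maxLevel, , drop = FALSE]
  if (nrow(sel)) sel$selected <- TRUE
  sel
}

#' Recall and precision of planted gene-peak couplings
#'
#' Scores a selection against the generator's ground truth: recall is the
#' fraction of planted (coupled gene, causal peak) pairs present in the
#' selection; precision the fraction of selected pairs that are planted.
#' Also returns the scatter table (expression fold change vs binding fold
#' change) of the selected pairs.
#'
#' @param selected data.frame of selected pairs (\code{gene_id},
#'   \code{peak_id}).
#' @param genes truth \code{GRanges} from \code{\link{simulateGenome}} (with
#'   \code{coupled} and \code{causal_peak}) or a data.frame with columns
#'   \code{gene_id}, \code{causal_peak}.
#' @param geneFc,peakFc optional fold-change tables used to fill the scatter
#'   table.
#' @return list with \code{recall}, \code{precision}, \code{nPlanted},
#'   \code{nSelected} and \code{scatter} (data.frame).
#' @export
recoverPlantedCoupling <- function(selected, genes, geneFc = NULL,
                                   peakFc = NULL) {
  truth <- if (methods::is(genes, "GRanges")) {
    data.frame(gene_id = mcols(genes)$gene_id,
               causal_peak = mcols(genes)$causal_peak,
               stringsAsFactors = FALSE)
  } else genes
  truth <- truth[!is.na(truth$causal_peak), , drop = FALSE]
  if (nrow(truth) &&
      !any(truth$gene_id %in% c(selected$gene_id, truth$gene_id)))
    stop("truth/selection id mismatch")
  plantedKey <- paste(truth$gene_id, truth$causal_peak)
  selKey <- paste(selected$gene_id, selected$peak_id)
  hit <- plantedKey %in% selKey
  recall <- if (length(plantedKey)) mean(hit) else 0
  precision <- if (length(selKey)) mean(selKey %in% plantedKey) else NA_real_
  scatter <- selected[, intersect(c("gene_id", "peak_id", "z_g", "z_p",
                                    "z_gp", "pareto_level",
                                    "correlation_class"),
                                  names(selected)), drop = FALSE]
  if (!is.null(geneFc))
    scatter$gene_log2fc <-
      geneFc$log2fc[match(scatter$gene_id, geneFc$feature_id)]
  if (!is.null(peakFc))
    scatter$peak_log2fc <-
      peakFc$log2fc[match(scatter$peak_id, peakFc$feature_id)]
  list(recall = recall, precision = precision,
       nPlanted = nrow(truth), nSelected = nrow(selected),
       scatter = scatter)
}

#' Gene-peak integration in one call
#'
#' Runs z-scoring of the two fold-change tables, windowed gene-peak
#' association, combined scores, per-class Pareto ranking and top-level
#' selection.
#'
#' @param geneFc,peakFc fold-change data.frames (\code{feature_id},
#'   \code{log2fc}, ...).
#' @param genes,peaks \code{GRanges} with \code{gene_id} / \code{peak_id}.
#' @param flankBp association window half-width (default 50000).
#' @param maxLevel Pareto level cutoff (default 10).
#' @param objective see \code{\link{paretoRank}}.
#' @param deOnly if \code{TRUE}, only genes classified differentially
#'   expressed by \code{\link{classifyDe}} enter the pairing.
#' @return list with \code{pairs} (all ranked pairs) and \code{selected}.
#' @export
integrateGenePeaks <- function(geneFc, peakFc, genes, peaks,
                               flankBp = 50000, maxLevel = 10,
                               objective = "two_sided", deOnly = FALSE) {
  if (deOnly) {
    keep <- classifyDe(geneFc) != "unchanged"
    genes <- genes[mcols(genes)$gene_id %in% geneFc$feature_id[keep]]
  }
  zg <- zscoreFoldChanges(geneFc)
  zp <- zscoreFoldChanges(peakFc)
  pairs <- associateGenePeaks(genes, peaks, flankBp)
  pairs <- pairs[pairs$gene_id %in% names(zg$z) &
                   pairs$peak_id %in% names(zp$z), , drop = FALSE]
  scored <- combinedScores(pairs, zg, zp)
  ranked <- paretoRank(scored, objective)
  list(pairs = ranked, selected = selectTopLevels(ranked, maxLevel))
}
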