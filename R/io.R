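## Readers and writers for the plain-text formats the pipeline touches.
## All interval formats are BED-convention on disk (0-based half-open) and
## GRanges (1-based closed) in memory; the conversion happens here only.

#' Read a BED file of intervals or peaks
#'
#' Accepts 3-6 column tab-separated BED. Columns beyond chrom/start/end are
#' interpreted as name, score and strand when present. Coordinates on disk
#' are 0-based half-open and converted to 1-based closed \code{GRanges}.
#'
#' @param path BED file path.
#' @return \code{GRanges}; a \code{name} metadata column becomes
#'   \code{peak_id} and a numeric \code{score} column is kept when present.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tp1\t5\t+", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end0) | !nzchar(chrom))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start0 < 0 | end0 <= start0)
  if (length(bad))
    stop("malformed BED line ", bad[1],
         ": need 0 <= start < end (empty intervals are invalid)")
  strand <- rep("*", length(lines))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (any(nf >= 4)) {
    nm <- rep(NA_character_, length(lines))
    nm[nf >= 4] <- vapply(fields[nf >= 4], `[`, "", 4L)
    if (any(nm != ".", na.rm = TRUE)) mcols(gr)$peak_id <- nm
  }
  if (any(nf >= 5)) {
    sc <- rep(NA_real_, length(lines))
    sc[nf >= 5] <- suppressWarnings(
      as.numeric(vapply(fields[nf >= 5], `[`, "", 5L)))
    if (any(is.finite(sc))) mcols(gr)$score <- sc
  }
  gr
}

#' Write intervals as BED
#'
#' Rows are sorted deterministically by (chrom, start, end) and written as
#' 0-based half-open coordinates. \code{peak_id} and \code{score} metadata
#' columns are emitted as BED name/score; strand is written whenever any
#' interval is stranded, so that \code{readBed(writeBed(x))} round-trips.
#'
#' @param gr \code{GRanges} to write.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  if (length(gr) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  o <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  chrom <- as.character(seqnames(gr))
  df <- data.frame(chrom = chrom, start = start(gr) - 1, end = end(gr))
  std <- as.character(strand(gr))
  mc <- mcols(gr)
  needStrand <- any(std != "*")
  if (needStrand || !is.null(mc$peak_id) || !is.null(mc$score)) {
    nm <- if (!is.null(mc$peak_id)) as.character(mc$peak_id) else
      rep(".", length(gr))
    nm[is.na(nm)] <- "."
    sc <- if (!is.null(mc$score)) mc$score else rep(0, length(gr))
    sc[is.na(sc)] <- 0
    std[std == "*"] <- "."
    df <- cbind(df, name = nm, score = sc, strand = std)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A \code{Biostrings::DNAStringSet} with unique names, upper-cased.
#'   Duplicate names or characters outside A, C, G, T, N are errors.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1])
  chars <- unique(strsplit(paste(toupper(as.character(seqs)),
                                 collapse = ""), "")[[1]])
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("non-DNA alphabet in ", path, ": ",
         paste(setdiff(chars, c("A", "C", "G", "T", "N")), collapse = ","))
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- names(seqs)
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read loops from BEDPE
#'
#' Expects 6+ tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2). Trans-chromosomal rows are skipped with a warning reporting how
#' many were dropped. Anchors are reordered so anchor1 is upstream.
#'
#' @param path BEDPE file path.
#' @return A \linkS4class{LoopSet}.
#' @export
readBedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    stop("BEDPE needs at least 6 columns, found ", ncol(df))
  trans <- df[[1]] != df[[4]]
  if (any(trans)) {
    warning(sum(trans), " trans-chromosomal loop(s) skipped")
    df <- df[!trans, , drop = FALSE]
  }
  a1 <- GRanges(df[[1]], IRanges(df[[2]] + 1, df[[3]]))
  a2 <- GRanges(df[[4]], IRanges(df[[5]] + 1, df[[6]]))
  LoopSet(a1, a2)
}

#' Write loops as BEDPE
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedpe <- function(loops, path) {
  a1 <- anchorOne(loops); a2 <- anchorTwo(loops)
  df <- data.frame(as.character(seqnames(a1)), start(a1) - 1, end(a1),
                   as.character(seqnames(a2)), start(a2) - 1, end(a2))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count table from TSV
#'
#' First column holds feature ids, the header row sample ids.
#'
#' @param path counts TSV.
#' @param spikeinPath optional TSV of spike-in counts over the same samples.
#' @return A \linkS4class{CountTable}.
#' @export
readCountTable <- function(path, spikeinPath = NULL) {
  readOne <- function(p) {
    df <- utils::read.table(p, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
    as.matrix(df)
  }
  CountTable(readOne(path),
             if (!is.null(spikeinPath)) readOne(spikeinPath) else NULL)
}

#' Write a count table (and its spike-in companion) to TSV
#'
#' @param table a \linkS4class{CountTable}.
#' @param path output TSV for the main counts.
#' @param spikeinPath optional output TSV for spike-in counts.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(table, path, spikeinPath = NULL) {
  writeOne <- function(m, p) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeOne(countsOf(table), path)
  if (!is.null(spikeinPath) && !is.null(spikeinCounts(table)))
    writeOne(spikeinCounts(table), spikeinPath)
  invisible(path)
}

#' Read a contact map from dense or triplet TSV
#'
#' Dense format: a square numeric matrix, no header. Triplet format: three
#' columns (bin_i, bin_j, value) with 1-based bin indices; missing pixels
#' are zero and the matrix is symmetrised from the given triangle.
#'
#' @param path input TSV.
#' @param binSize bin width in bp.
#' @param chrom chromosome name.
#' @param format \code{"dense"} or \code{"triplet"}.
#' @param nBins number of bins (required for triplet input).
#' @return A \linkS4class{ContactMap}.
#' @export
readContactMap <- function(path, binSize, chrom = "chr1",
                           format = c("dense", "triplet"), nBins = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE)
    if (is.null(nBins)) nBins <- max(df[[1]], df[[2]])
    m <- matrix(0, nBins, nBins)
    m[cbind(df[[1]], df[[2]])] <- df[[3]]
    m[cbind(df[[2]], df[[1]])] <- df[[3]]
  }
  ContactMap(chrom, binSize, m)
}

#' Write a contact map as dense TSV
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContactMap <- function(map, path) {
  utils::write.table(map@matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a motif from MEME-minimal text
#'
#' Parses the first MOTIF block of a MEME minimal-format file: the
#' letter-probability matrix plus any background frequencies line.
#'
#' @param path motif file path.
#' @param pseudocount pseudocount stored on the returned motif.
#' @return A \linkS4class{PWMotif}.
#' @export
readMemeMotif <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) && bgi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    if (length(tok) >= 8) {
      vals <- as.numeric(tok[seq(2, 8, by = 2)])
      names(vals) <- tok[seq(1, 7, by = 2)]
      bg <- vals[c("A", "C", "G", "T")]
    }
  }
  mi <- grep("^MOTIF", lines)
  if (!length(mi)) stop("no MOTIF block in ", path)
  li <- grep("^letter-probability matrix", lines)
  li <- li[li > mi[1]][1]
  if (is.na(li)) stop("no letter-probability matrix in ", path)
  rows <- list()
  i <- li + 1
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 4 || anyNA(suppressWarnings(as.numeric(tok)))) break
    rows[[length(rows) + 1]] <- as.numeric(tok)
    i <- i + 1
  }
  if (!length(rows)) stop("empty letter-probability matrix in ", path)
  probs <- t(do.call(rbind, rows))
  rownames(probs) <- c("A", "C", "G", "T")
  probs <- sweep(probs, 2, colSums(probs), "/")
  PWMotif(probs, background = bg, pseudocount = pseudocount)
}

#' Write a motif as MEME-minimal text
#'
#' @param pwm a \linkS4class{PWMotif}.
#' @param path output path.
#' @param name motif name written in the MOTIF line.
#' @return \code{path}, invisibly.
#' @export
writeMemeMotif <- function(pwm, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwm@background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg["A"], bg["C"], bg["G"], bg["T"]),
               "",
               paste("MOTIF", name),
               sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                 motifWidth(pwm))), con)
  writeLines(apply(pwm@probs, 2, function(col)
    sprintf(" %.6f  %.6f  %.6f  %.6f", col[1], col[2], col[3], col[4])), con)
  invisible(path)
}

#' Read a fold-change table from TSV
#'
#' Expects columns \code{feature_id}, \code{log2fc}, \code{p_value},
#' \code{fdr} and optionally \code{mean_cpm}.
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
readFoldChangeTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("feature_id", "log2fc", "p_value", "fdr")
  if (!all(need %in% names(df)))
    stop("fold-change table must have columns ",
         paste(need, collapse = ", "))
  stopifnot(all(df$p_value >= 0 & df$p_value <= 1),
            all(df$fdr >= 0 & df$fdr <= 1))
  df
}

#' Write a fold-change / differential-result table to TSV
#'
#' @param df data.frame as returned by \code{\link{moderatedTest}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFoldChangeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
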