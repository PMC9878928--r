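## Synthetic data with the statistical structure the pipeline assumes:
## NB counts with condition-dependent binding loss at a subset of peaks,
## expression changes coupled to nearby affected peaks, sequences carrying a
## core motif with planted flank signatures, and contact maps with enriched
## loop pixels. Ground truth is retained on every object so downstream
## recovery can be scored without re-deriving it.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults chosen
#' to emulate a CTCF degradation experiment: a minority of peaks lose binding
#' strongly in the treated condition, a subset of genes near affected peaks
#' change expression, spike-in counts carry only per-sample depth, and a
#' fraction of dependent sites carry a planted G at flank position +4.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param nGenes,nPeaks number of genes / peaks.
#' @param chromLength chromosome length in bp.
#' @param nReplicates replicates per condition (two conditions: control,
#'   treated).
#' @param fracDependentPeaks fraction of peaks losing binding on treatment.
#' @param bindingLossLog2fc mean binding log2 fold change at dependent peaks.
#' @param couplingProb probability that a dependent peak inside a gene's
#'   \code{[TSS - flankBp, TES + flankBp]} window couples that gene.
#' @param expressionLog2fc mean expression log2 fold change of coupled genes.
#' @param nbDispersion negative-binomial dispersion (1/size).
#' @param baseMeanLog,baseMeanSdLog log-normal parameters of baseline means.
#' @param spikeinN number of spike-in features.
#' @param spikeinScalePerSample per-sample multiplicative depth factors
#'   (length \code{2 * nReplicates}); default all 1.
#' @param motifCore a \linkS4class{PWMotif} for the core motif (default a
#'   20-bp CTCF-like consensus).
#' @param flankSignature list(offset, base, fraction): position relative to
#'   the core (positive = downstream of the core 3' end in motif
#'   orientation), the planted base, and the fraction of dependent sites
#'   carrying it.
#' @param seqBackground background base probabilities for sequences.
#' @param peakWidth peak width in bp.
#' @param geneSpanRange min/max gene span in bp.
#' @param flankBp gene neighbourhood half-width used for coupling.
#' @param loopN number of loops.
#' @param loopEnrichment fold enrichment of loop pixels over the local
#'   distance-decay background.
#' @param binSize contact-map bin size in bp.
#' @param nBins number of contact-map bins.
#' @param contactScale Poisson intensity scale of the contact background.
#' @param loopGapBins min/max anchor separation in bins.
#' @return A validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 50, nPeaks = 100)
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 2000L,
                             nPeaks = 5000L,
                             chromLength = 1e8,
                             nReplicates = 4L,
                             fracDependentPeaks = 0.2,
                             bindingLossLog2fc = -2,
                             couplingProb = 0.045,
                             expressionLog2fc = -2,
                             nbDispersion = 0.1,
                             baseMeanLog = log(200),
                             baseMeanSdLog = 1,
                             spikeinN = 500L,
                             spikeinScalePerSample = NULL,
                             motifCore = PWMotif("TGGCCACCAGGGGGCGCTAC"),
                             flankSignature = list(offset = 4L, base = "G",
                                                   fraction = 0.82),
                             seqBackground = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                             peakWidth = 400L,
                             geneSpanRange = c(2000L, 20000L),
                             flankBp = 50000L,
                             loopN = 100L,
                             loopEnrichment = 3,
                             binSize = 10000,
                             nBins = 600L,
                             contactScale = 5000,
                             loopGapBins = c(150L, 400L)) {
  if (is.null(spikeinScalePerSample))
    spikeinScalePerSample <- rep(1, 2L * nReplicates)
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              nPeaks = as.integer(nPeaks), chromLength = chromLength,
              nReplicates = as.integer(nReplicates),
              fracDependentPeaks = fracDependentPeaks,
              bindingLossLog2fc = bindingLossLog2fc,
              couplingProb = couplingProb,
              expressionLog2fc = expressionLog2fc,
              nbDispersion = nbDispersion,
              baseMeanLog = baseMeanLog, baseMeanSdLog = baseMeanSdLog,
              spikeinN = as.integer(spikeinN),
              spikeinScalePerSample = spikeinScalePerSample,
              motifCore = motifCore, flankSignature = flankSignature,
              seqBackground = seqBackground,
              peakWidth = as.integer(peakWidth),
              geneSpanRange = as.integer(geneSpanRange),
              flankBp = as.integer(flankBp),
              loopN = as.integer(loopN), loopEnrichment = loopEnrichment,
              binSize = binSize, nBins = as.integer(nBins),
              contactScale = contactScale,
              loopGapBins = as.integer(loopGapBins))
  fr <- c(cfg$fracDependentPeaks, cfg$couplingProb,
          cfg$flankSignature$fraction)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]")
  if (!is.finite(cfg$bindingLossLog2fc) || !is.finite(cfg$expressionLog2fc))
    stop("effect sizes must be finite")
  if (cfg$nbDispersion <= 0) stop("nbDispersion must be > 0")
  if (cfg$nReplicates < 2) stop("need >= 2 replicates per condition")
  if (length(cfg$spikeinScalePerSample) != 2L * cfg$nReplicates)
    stop("spikeinScalePerSample must have one factor per sample")
  if (cfg$flankSignature$offset == 0 || abs(cfg$flankSignature$offset) > 20)
    stop("flank signature offset must lie within +/-20, excluding 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Write a simulation configuration as JSON
#'
#' @param cfg a \code{SimulationConfig}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSimulationConfig <- function(cfg, path) {
  out <- cfg
  out$motifCore <- list(probs = unclass(out$motifCore@probs),
                        background = as.list(out$motifCore@background),
                        pseudocount = out$motifCore@pseudocount)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a gene and peak layout with ground-truth labels
#'
#' Genes are placed without overlap along one chromosome; peaks are placed
#' uniformly. A fraction of peaks is labelled dependent (they will lose
#' binding in the treated condition) and genes whose neighbourhood
#' \code{[TSS - flankBp, TES + flankBp]} contains a dependent peak are
#' coupled with probability \code{couplingProb} per such peak; the causal
#' peak of a coupled gene is the nearest coupling peak.
#'
#' @param cfg a \code{SimulationConfig}.
#' @return list with \code{genes} (GRanges with \code{gene_id},
#'   \code{coupled}, \code{causal_peak}, \code{planted_log2fc}) and
#'   \code{peaks} (GRanges with \code{peak_id}, \code{summit},
#'   \code{dependent}, \code{planted_log2fc}).
#' @export
simulateGenome <- function(cfg) {
  set.seed(cfg$seed)
  slot <- cfg$chromLength / cfg$nGenes
  if (mean(cfg$geneSpanRange) >= slot)
    stop("infeasible packing: nGenes * mean gene span exceeds chromLength")
  span <- round(stats::runif(cfg$nGenes, cfg$geneSpanRange[1],
                             pmin(cfg$geneSpanRange[2], slot * 0.8)))
  offset <- round(stats::runif(cfg$nGenes, 0, slot - span - 1))
  startg <- floor((seq_len(cfg$nGenes) - 1) * slot) + offset + 1
  strand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
  genes <- GRanges("chr1", IRanges(startg, startg + span - 1),
                   strand = strand)
  mcols(genes)$gene_id <- sprintf("g%05d", seq_len(cfg$nGenes))

  pstart <- sort(round(stats::runif(cfg$nPeaks, 1,
                                    cfg$chromLength - cfg$peakWidth)))
  peaks <- GRanges("chr1", IRanges(pstart, pstart + cfg$peakWidth - 1))
  mcols(peaks)$peak_id <- sprintf("p%05d", seq_len(cfg$nPeaks))
  mcols(peaks)$summit <- pstart + cfg$peakWidth %/% 2
  dep <- rep(FALSE, cfg$nPeaks)
  dep[sample.int(cfg$nPeaks, round(cfg$fracDependentPeaks * cfg$nPeaks))] <-
    TRUE
  mcols(peaks)$dependent <- dep
  mcols(peaks)$planted_log2fc <- ifelse(dep, cfg$bindingLossLog2fc, 0)

  win <- GRanges("chr1",
                 IRanges(pmax(1, start(genes) - cfg$flankBp),
                         end(genes) + cfg$flankBp))
  ov <- findOverlaps(win, peaks[dep])
  depIdx <- which(dep)
  couple <- stats::rbinom(length(ov), 1, cfg$couplingProb) == 1
  coupled <- rep(FALSE, cfg$nGenes)
  causal <- rep(NA_character_, cfg$nGenes)
  if (any(couple)) {
    gi <- queryHits(ov)[couple]
    pi <- depIdx[subjectHits(ov)[couple]]
    tssPos <- tssOf(genes)
    d <- abs(mcols(peaks)$summit[pi] - tssPos[gi])
    o <- order(gi, d)
    keep <- !duplicated(gi[o])
    gsel <- gi[o][keep]
    psel <- pi[o][keep]
    coupled[gsel] <- TRUE
    causal[gsel] <- mcols(peaks)$peak_id[psel]
  }
  mcols(genes)$coupled <- coupled
  mcols(genes)$causal_peak <- causal
  mcols(genes)$planted_log2fc <- ifelse(coupled, cfg$expressionLog2fc, 0)
  list(genes = genes, peaks = peaks)
}

#' TSS positions of genes
#'
#' @param genes stranded \code{GRanges} of gene bodies.
#' @return integer vector: \code{start} for plus-strand genes, \code{end}
#'   for minus-strand genes.
#' @export
tssOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' TES positions of genes
#'
#' @param genes stranded \code{GRanges} of gene bodies.
#' @return integer vector of transcription end sites.
#' @export
tesOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
}

#' Simulate peak and gene count tables
#'
#' Counts are negative binomial around log-normal baseline means; in treated
#' samples the mean of dependent peaks / coupled genes is shifted by the
#' planted log2 fold change. Per-sample depth factors multiply all means;
#' spike-in features share the depth factors but never the condition effect.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param genes,peaks output of \code{\link{simulateGenome}}.
#' @return list with \code{peaks} (a \linkS4class{CountTable} carrying the
#'   spike-in companion), \code{genes} (a \code{CountTable}) and
#'   \code{design} (condition labels per sample).
#' @export
simulateCounts <- function(cfg, genes, peaks) {
  set.seed(cfg$seed + 1L)
  n <- cfg$nReplicates
  samples <- c(paste0("ctrl_", seq_len(n)), paste0("treat_", seq_len(n)))
  design <- rep(c("ctrl", "treat"), each = n)
  scale <- cfg$spikeinScalePerSample
  size <- 1 / cfg$nbDispersion

  drawTable <- function(baseMu, log2fc) {
    mu <- outer(baseMu, scale)
    treated <- design == "treat"
    mu[, treated] <- mu[, treated] * 2^log2fc
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                nrow = nrow(mu))
    colnames(m) <- samples
    m
  }
  basePeak <- stats::rlnorm(length(peaks), cfg$baseMeanLog, cfg$baseMeanSdLog)
  peakCounts <- drawTable(basePeak, mcols(peaks)$planted_log2fc)
  rownames(peakCounts) <- mcols(peaks)$peak_id

  baseGene <- stats::rlnorm(length(genes), cfg$baseMeanLog, cfg$baseMeanSdLog)
  geneCounts <- drawTable(baseGene, mcols(genes)$planted_log2fc)
  rownames(geneCounts) <- mcols(genes)$gene_id

  baseSpike <- stats::rlnorm(cfg$spikeinN, log(100), 0.5)
  spikeMu <- outer(baseSpike, scale)
  spike <- matrix(stats::rnbinom(length(spikeMu), mu = spikeMu, size = size),
                  nrow = cfg$spikeinN,
                  dimnames = list(sprintf("spike%04d", seq_len(cfg$spikeinN)),
                                  samples))
  list(peaks = CountTable(peakCounts, spike),
       genes = CountTable(geneCounts),
       design = stats::setNames(design, samples))
}

#' Simulate peak sequences with a planted core motif and flank signature
#'
#' Each peak sequence carries exactly one core-motif instance drawn from the
#' configured PWM at a random offset and strand, on a background of
#' independent draws from \code{seqBackground}. A configured fraction of
#' dependent-peak sequences carries the flank-signature base at the stated
#' offset relative to the core, in motif orientation (minus-strand instances
#' are embedded as the reverse complement).
#'
#' @param cfg a \code{SimulationConfig}.
#' @param peaks peak \code{GRanges} from \code{\link{simulateGenome}}.
#' @param seqLength sequence length per peak (default: core + 2*20 + 60).
#' @return list with \code{seqs} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame: peak_id, offset (0-based core start), strand,
#'   dependent, signature_planted).
#' @export
simulateSequences <- function(cfg, peaks, seqLength = NULL) {
  set.seed(cfg$seed + 2L)
  W <- motifWidth(cfg$motifCore)
  if (W < 8) stop("motif core width must be >= 8")
  sig <- cfg$flankSignature
  if (abs(sig$offset) > 20 || sig$offset == 0)
    stop("flank signature offset must lie within the +/-20 bp window")
  if (is.null(seqLength)) seqLength <- W + 2L * 20L + 60L
  L <- as.integer(seqLength)
  if (L < W + 40L) stop("sequences must be at least core + 40 bp long")
  bases <- c("A", "C", "G", "T")
  bg <- cfg$seqBackground[bases]
  probs <- cfg$motifCore@probs
  nP <- length(peaks)
  dep <- mcols(peaks)$dependent
  orient <- sample(c("+", "-"), nP, replace = TRUE)
  coreStart <- floor(stats::runif(nP, 21, L - W - 20 + 1))  # 1-based, oriented
  planted <- dep & stats::rbinom(nP, 1, sig$fraction) == 1
  ## the planted fraction is controlled: non-planted dependent sites carry a
  ## non-signature base at the offset, so the observed signature fraction
  ## estimates sig$fraction directly
  otherBases <- setdiff(bases, sig$base)
  otherProb <- bg[otherBases] / sum(bg[otherBases])

  seqs <- character(nP)
  offset0 <- integer(nP)
  for (i in seq_len(nP)) {
    s <- sample(bases, L, replace = TRUE, prob = bg)
    o <- coreStart[i]
    core <- vapply(seq_len(W), function(j)
      sample(bases, 1, prob = probs[, j]), "")
    s[o:(o + W - 1)] <- core
    if (dep[i]) {
      pos <- if (sig$offset > 0) o + W - 1 + sig$offset else o + sig$offset
      s[pos] <- if (planted[i]) sig$base else
        sample(otherBases, 1, prob = otherProb)
    }
    if (orient[i] == "-") {
      s <- rev(c(A = "T", C = "G", G = "C", T = "A")[s])
      offset0[i] <- L - (o - 1) - W
    } else {
      offset0[i] <- o - 1
    }
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- mcols(peaks)$peak_id
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  list(seqs = out,
       truth = data.frame(peak_id = ids, offset = offset0, strand = orient,
                          dependent = dep, signature_planted = planted,
                          stringsAsFactors = FALSE))
}

#' Simulate loop calls on the contact-map bin space
#'
#' Anchor pairs are drawn with separations uniform over
#' \code{loopGapBins}, keeping a 10-bin margin from the matrix edges so the
#' default APA window fits.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param chrom chromosome name for the anchors.
#' @return A \linkS4class{LoopSet} of \code{loopN} loops whose anchors span
#'   one bin each.
#' @export
simulateLoops <- function(cfg, chrom = "chr1") {
  set.seed(cfg$seed + 3L)
  w <- 10L
  gap <- sample(seq(cfg$loopGapBins[1], cfg$loopGapBins[2]), cfg$loopN,
                replace = TRUE)
  maxStart <- cfg$nBins - w - gap
  if (any(maxStart <= w + 1))
    stop("loop separations do not fit in the contact map")
  b1 <- vapply(maxStart, function(m) sample(seq(w + 1L, m), 1L), 1L)
  b2 <- b1 + gap
  binRange <- function(b)
    GRanges(chrom, IRanges((b - 1) * cfg$binSize + 1, b * cfg$binSize))
  LoopSet(binRange(b1), binRange(b2))
}

#' Simulate a contact map with distance decay and enriched loop pixels
#'
#' Background intensity decays as \code{contactScale / (1 + |i - j|)}; at
#' each loop pixel the intensity is multiplied by \code{loopEnrichment}.
#' Counts are Poisson draws, symmetrised from the upper triangle.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param loops a \linkS4class{LoopSet} (e.g. \code{\link{simulateLoops}}).
#' @return A \linkS4class{ContactMap}.
#' @export
simulateContactMap <- function(cfg, loops) {
  set.seed(cfg$seed + 4L)
  n <- cfg$nBins
  b1 <- binIndexOf(anchorOne(loops), cfg$binSize)
  b2 <- binIndexOf(anchorTwo(loops), cfg$binSize)
  if (any(b1 < 1 | b2 < 1 | b1 > n | b2 > n))
    stop("loop anchors fall outside the contact map")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lambda <- cfg$contactScale / (1 + d)
  lambda[cbind(b1, b2)] <- lambda[cbind(b1, b2)] * cfg$loopEnrichment
  lambda[cbind(b2, b1)] <- lambda[cbind(b1, b2)]
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- stats::rpois(sum(up), lambda[up])
  m <- m + t(m) - diag(diag(m))
  ContactMap("chr1", cfg$binSize, m)
}

#' Bin index of interval midpoints
#'
#' @param gr \code{GRanges}.
#' @param binSize bin width in bp.
#' @return 1-based bin indices of the interval midpoints.
#' @export
binIndexOf <- function(gr, binSize) {
  mid <- floor((start(gr) - 1 + end(gr)) / 2)
  as.integer(mid %/% binSize + 1)
}

#' Run the full generator
#'
#' Convenience wrapper producing the genome layout, count tables, peak
#' sequences, loops and contact map from one configuration.
#'
#' @param cfg a \code{SimulationConfig}.
#' @return list with elements \code{genes}, \code{peaks}, \code{counts}
#'   (list peaks/genes/design), \code{sequences} (list seqs/truth),
#'   \code{loops}, \code{contactMap}.
#' @export
simulateAll <- function(cfg) {
  geno <- simulateGenome(cfg)
  counts <- simulateCounts(cfg, geno$genes, geno$peaks)
  seqs <- simulateSequences(cfg, geno$peaks)
  loops <- simulateLoops(cfg)
  cm <- simulateContactMap(cfg, loops)
  list(genes = geno$genes, peaks = geno$peaks, counts = counts,
       sequences = seqs, loops = loops, contactMap = cm)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the generator output in the pipeline's interchange formats: BED for
#' genes and peaks, TSV count tables (with spike-in companion), FASTA
#' sequences, a truth-table TSV, BEDPE loops, a dense contact-map TSV and
#' the configuration as JSON.
#'
#' @param sim output of \code{\link{simulateAll}}.
#' @param cfg the \code{SimulationConfig} used.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedData <- function(sim, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  genes <- sim$genes
  mcols(genes)$peak_id <- mcols(genes)$gene_id
  writeBed(genes, p("genes.bed"))
  writeBed(sim$peaks, p("peaks.bed"))
  writeCountTable(sim$counts$peaks, p("peak_counts.tsv"),
                  p("spikein_counts.tsv"))
  writeCountTable(sim$counts$genes, p("gene_counts.tsv"))
  writeFasta(sim$sequences$seqs, p("peak_sequences.fa"))
  utils::write.table(sim$sequences$truth, p("sequence_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(
    feature_id = c(mcols(sim$peaks)$peak_id, mcols(sim$genes)$gene_id),
    label = c(ifelse(mcols(sim$peaks)$dependent, "dependent", "independent"),
              ifelse(mcols(sim$genes)$coupled, "coupled", "uncoupled")),
    planted_effect = c(mcols(sim$peaks)$planted_log2fc,
                       mcols(sim$genes)$planted_log2fc),
    causal_peak = c(rep(NA, length(sim$peaks)),
                    mcols(sim$genes)$causal_peak))
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeBedpe(sim$loops, p("loops.bedpe"))
  writeContactMap(sim$contactMap, p("contact_map.tsv"))
  writeSimulationConfig(cfg, p("config.json"))
  invisible(dir)
}
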