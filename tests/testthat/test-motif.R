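uniformPwm <- function(consensus, p = 0.85)
  PWMotif(consensus, consensusProb = p)

test_that("log-odds scores are zero at background and finite everywhere", {
  flat <- PWMotif(matrix(0.25, 4, 5,
                         dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_true(all(abs(logOdds(flat)) < 1e-12))
  hard <- PWMotif(matrix(c(1, 0, 0, 0), 4, 3,
                         dimnames = list(c("A", "C", "G", "T"), NULL)))
  lo <- logOdds(hard)
  expect_true(all(is.finite(lo)))
  expect_lt(abs(lo["A", 1] - 2), 0.05)  # ~2 bits before pseudocount
})

test_that("exact score p-values equal exhaustive enumeration (W <= 6)", {
  set.seed(71)
  for (W in 2:6) {
    probs <- matrix(rgamma(4 * W, 1), 4,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
    probs <- sweep(probs, 2, colSums(probs), "/")
    pwm <- PWMotif(probs)
    tab <- scorePvalueTable(pwm, resolution = 0.001)
    oracle <- bruteScoreTail(pwm, 0.001)
    for (s in sort(unique(oracle$scores))) {
      expect_equal(zfintegrate:::tailProb(tab, s),
                   sum(oracle$probs[oracle$scores >= s]),
                   tolerance = 1e-12)
    }
    ## maximal score has p = P(best word); p is non-increasing in s
    smax <- max(oracle$scores)
    expect_equal(zfintegrate:::tailProb(tab, smax),
                 sum(oracle$probs[oracle$scores == smax]),
                 tolerance = 1e-12)
    grid <- seq(min(oracle$scores), smax, by = 25)
    expect_true(all(diff(zfintegrate:::tailProb(tab, grid)) <= 1e-15))
  }
  expect_error(scorePvalueTable(uniformPwm("ACGT"), resolution = 0.02),
               "coarse")
})

test_that("scanning finds planted sites on both strands with mirrored offsets", {
  pwm <- uniformPwm("ACGTACGTAC", p = 0.97)
  seq1 <- paste0(strrep("T", 15), "ACGTACGTAC", strrep("T", 15))
  hits <- scanMotif(c(s1 = seq1), pwm, background = "uniform")
  best <- hits[hits$best, ]
  expect_equal(best$offset, 15)
  expect_equal(best$strand, "+")

  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq1), "")[[1]]),
              collapse = "")
  hitsRc <- scanMotif(c(s1 = rc), pwm, background = "uniform")
  bestRc <- hitsRc[hitsRc$best, ]
  expect_equal(bestRc$strand, "-")
  expect_equal(bestRc$offset, 15)
  expect_equal(bestRc$score, best$score)

  ## windows containing N are skipped
  seqN <- paste0(strrep("T", 15), "ACGTNCGTAC", strrep("T", 15))
  hitsN <- scanMotif(c(s1 = seqN), pwm, background = "uniform")
  expect_false(any(hitsN$offset == 15 & hitsN$strand == "+"))
})

test_that("random-sequence hit counts match the p-value threshold rate", {
  set.seed(72)
  pwm <- uniformPwm("ACGTACGTACGT", p = 0.9)
  L <- 100
  nSeq <- 400
  seqs <- vapply(seq_len(nSeq), function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", seq_len(nSeq))
  thr <- 1e-3
  hits <- scanMotif(seqs, pwm, pThreshold = thr, background = "uniform")
  ## the discrete score grid makes the achievable level <= thr; use it
  tab <- scorePvalueTable(PWMotif(pwm@probs), resolution = 0.001)
  alpha <- max(tab$tail[tab$tail <= thr])
  expected <- 2 * (L - 12 + 1) * alpha * nSeq
  ## Poisson-ish tolerance: 4 sd
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected) + 1)
})

test_that("flank extraction is orientation-normalised and pads with N", {
  pwm <- uniformPwm("ACGTACGTAC", p = 0.97)
  core <- "ACGTACGTAC"
  up <- strrep("A", 20); down <- paste0("GGG", strrep("C", 17))
  seqPlus <- paste0(up, core, down)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  seqMinus <- rc(seqPlus)
  hits <- scanMotif(c(pl = seqPlus, mi = seqMinus), pwm,
                    background = "uniform")
  aln <- extractFlanks(hits, c(pl = seqPlus, mi = seqMinus), coreWidth = 10)
  m <- alignmentMatrix(aln)
  expect_equal(ncol(m), 50)
  ## both rows read identically in motif orientation
  expect_identical(m["pl", ], m["mi", ])
  expect_equal(paste(m["pl", 21:30], collapse = ""), core)
  expect_equal(m["pl", 31:33], c("G", "G", "G"))

  ## a hit near the sequence start gets N padding on the upstream side
  shortSeq <- paste0("TT", core, strrep("C", 25))
  hs <- scanMotif(c(s = shortSeq), pwm, background = "uniform")
  expect_warning(alnS <- extractFlanks(hs, c(s = shortSeq), coreWidth = 10),
                 "padded")
  ms <- alignmentMatrix(alnS)
  expect_equal(ncol(ms), 50)
  expect_true(all(ms[1, 1:18] == "N"))
})

test_that("hamming clustering separates planted flank classes exactly", {
  set.seed(73)
  base <- sample(c("A", "C", "G", "T"), 50, TRUE)
  a <- base
  b <- base
  b[c(3, 12, 25, 38, 47)] <- vapply(b[c(3, 12, 25, 38, 47)], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], "")
  rows <- rbind(matrix(rep(a, 12), 12, byrow = TRUE),
                matrix(rep(b, 9), 9, byrow = TRUE))
  ord <- sample(nrow(rows))
  aln <- new("FlankAlignment", seqs = rows[ord, ], coreWidth = 10L,
             flank = 20L, cluster = rep(NA_integer_, 21))
  cl <- hammingCluster(aln, k = 2)
  ids <- clusterIds(cl$alignment)
  trueClass <- c(rep(1, 12), rep(2, 9))[ord]
  expect_equal(length(unique(ids[trueClass == 1])), 1)
  expect_equal(length(unique(ids[trueClass == 2])), 1)
  expect_false(ids[which(trueClass == 1)[1]] == ids[which(trueClass == 2)[1]])

  ## row order invariance of memberships
  perm <- sample(21)
  aln2 <- new("FlankAlignment", seqs = alignmentMatrix(aln)[perm, ],
              coreWidth = 10L, flank = 20L, cluster = rep(NA_integer_, 21))
  cl2 <- hammingCluster(aln2, k = 2)
  expect_equal(table(clusterIds(cl2$alignment), trueClass[perm]),
               table(ids, trueClass), ignore_attr = TRUE)
  expect_equal(length(unique(clusterIds(
    hammingCluster(aln, k = 1)$alignment))), 1)
  expect_error(hammingCluster(aln, k = 50), "exceeds")
})

test_that("column information follows the closed forms", {
  m <- rbind(c("G", "A", "A", "N"),
             c("G", "C", "A", "N"),
             c("G", "G", "T", "N"),
             c("G", "T", "T", "N"))
  info <- columnInformation(m)
  expect_equal(info$ic, c(2, 0, 1, 0), tolerance = 1e-12)
  expect_equal(info$G[1], 2)
  expect_equal(info$A[3], 0.5)
  expect_equal(info$T[3], 0.5)
})

test_that("signature fractions come with Wilson intervals and enrichment", {
  rows <- matrix("A", 10, 50)
  rows[1:8, 34] <- "G"     # +4 downstream of a 10-bp core: column 30 + 4
  aln <- new("FlankAlignment", seqs = rows, coreWidth = 10L, flank = 20L,
             cluster = rep(NA_integer_, 10))
  sf <- signatureFraction(aln, 4, "G")
  expect_equal(sf$fraction, 0.8)
  expect_true(sf$ciLow < 0.8 && sf$ciHigh > 0.8)
  expect_equal(unname(wilsonInterval(8, 10)), c(sf$ciLow, sf$ciHigh))
  ctrl <- new("FlankAlignment", seqs = matrix("A", 10, 50), coreWidth = 10L,
              flank = 20L, cluster = rep(NA_integer_, 10))
  ctrl@seqs[1:2, 34] <- "G"
  sf2 <- signatureFraction(aln, 4, "G", control = ctrl)
  expect_equal(sf2$enrichment, 4)
  expect_error(signatureFraction(aln, 25, "G"), "offset")
  ## upstream offsets address the 5' flank
  rows[, 20] <- "T"        # -1 relative to the core start
  alnU <- new("FlankAlignment", seqs = rows, coreWidth = 10L, flank = 20L,
              cluster = rep(NA_integer_, 10))
  expect_equal(signatureFraction(alnU, -1, "T")$fraction, 1)
})

test_that("planted signatures survive the full scan/extract path", {
  peaks <- GRanges("chr1", IRanges(1:400 * 1000, width = 400))
  mcols(peaks)$peak_id <- sprintf("p%03d", 1:400)
  mcols(peaks)$dependent <- TRUE
  cfg <- simulationConfig(seed = 74, nGenes = 50, nPeaks = 400,
                          chromLength = 5e6,
                          flankSignature = list(offset = 4L, base = "G",
                                                fraction = 0.6))
  sim <- simulateSequences(cfg, peaks)
  hits <- scanMotif(sim$seqs, cfg$motifCore, background = "uniform")
  aln <- extractFlanks(hits, sim$seqs, coreWidth = motifWidth(cfg$motifCore))
  sf <- signatureFraction(aln, 4, "G")
  planted <- mean(sim$truth$signature_planted)
  expect_lt(abs(sf$fraction - planted), 0.03)
  ## scan recovers the recorded offsets/strands (minus strand included)
  best <- hits[hits$best, ]
  tr <- sim$truth[match(best$seq_id, sim$truth$peak_id), ]
  expect_gt(mean(best$offset == tr$offset & best$strand == tr$strand), 0.95)
})
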