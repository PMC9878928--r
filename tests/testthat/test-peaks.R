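gr <- function(start, end, tier = NULL, strand = "*") {
  g <- GRanges("chr1", IRanges(start, end), strand = strand)
  if (!is.null(tier)) mcols(g)$tier <- tier
  g
}

test_that("reproducible peaks require a high call supported by all others", {
  r1 <- gr(c(100, 1000), c(200, 1100), tier = c("high", "high"))
  r2 <- gr(150, 250, tier = "low")
  out <- reproduciblePeaks(list(r1, r2))
  expect_equal(start(out), 100)
  expect_equal(end(out), 200)

  ## three replicates: support missing in one replicate drops the peak
  r3 <- gr(5000, 5100, tier = "low")
  expect_equal(length(reproduciblePeaks(list(r1, r2, r3))), 0L)
  expect_equal(length(reproduciblePeaks(list(r1, r2, r3),
                                        othersMode = "any")), 1L)

  ## high calls in several replicates merge into one interval
  r2b <- gr(c(150, 180), c(250, 260), tier = c("high", "low"))
  out2 <- reproduciblePeaks(list(r1[1], r2b))
  expect_equal(length(out2), 1L)
  expect_equal(c(start(out2), end(out2)), c(100, 250))

  expect_error(reproduciblePeaks(list(r1)), "2 replicates")
})

test_that("reproducible-peak output is monotone under added low-tier calls", {
  set.seed(21)
  r1 <- randomIntervals(40, chroms = "chr1", maxPos = 1e5)
  mcols(r1)$tier <- sample(c("high", "low"), 40, TRUE)
  r2 <- randomIntervals(40, chroms = "chr1", maxPos = 1e5)
  mcols(r2)$tier <- sample(c("high", "low"), 40, TRUE)
  base <- reproduciblePeaks(list(r1, r2))
  extra <- gr(2e4, 9e4, tier = "low")
  grown <- reproduciblePeaks(list(r1, c(r2, extra)))
  ## every base peak is still covered by a grown peak
  expect_true(all(countOverlaps(base, grown) > 0))
  expect_gte(length(grown), 0)
  ## output intervals come from high-tier calls only
  hi <- c(r1[mcols(r1)$tier == "high"], r2[mcols(r2)$tier == "high"])
  expect_true(all(countOverlaps(base, hi) > 0))
})

test_that("condition peak sets merge with provenance and idempotence", {
  a <- gr(c(100, 1000), c(200, 1100))
  b <- gr(150, 250)
  merged <- mergeConditionPeaks(list(ctrl = a, treat = b))
  expect_equal(start(merged), c(100, 1000))
  expect_equal(end(merged), c(250, 1100))
  expect_equal(mcols(merged)$conditions, c("ctrl,treat", "ctrl"))
  again <- mergeConditionPeaks(list(m = merged))
  expect_equal(start(again), start(merged))
  expect_equal(end(again), end(merged))
})

test_that("fragment counting extends reads 5'->3' to the fragment size", {
  peaks <- gr(250, 349)
  plus <- gr(100, 135, strand = "+")
  expect_equal(unname(countFragments(plus, peaks, 200)), 1L)
  expect_equal(unname(countFragments(plus, peaks, 100)), 0L)
  minus <- gr(400, 435, strand = "-")
  ## extends left to [236, 435]
  expect_equal(unname(countFragments(minus, peaks, 200)), 1L)
  expect_equal(unname(countFragments(minus, peaks, 80)), 0L)
  expect_error(countFragments(gr(1, 50), peaks, 100), "strand")
})

test_that("fragment counting matches the all-pairs oracle on random data", {
  set.seed(31)
  reads <- randomIntervals(1000, chroms = "chr1", maxPos = 2e5)
  peaks <- randomIntervals(50, chroms = "chr1", maxPos = 2e5,
                           stranded = FALSE)
  for (fs in c(1, 73, 200)) {
    expect_identical(unname(countFragments(reads, peaks, fs)),
                     bruteCountFragments(reads, peaks, fs))
  }
})

test_that("scaling factors follow the 15e6 and 1e6 conventions", {
  expect_equal(scaleFactorLibsize(c(30e6, 15e6, 7.5e6))$factor,
               c(0.5, 1, 2))
  expect_equal(scaleFactorSpikein(c(2e6, 1e6, 5e5))$factor, c(0.5, 1, 2))
  expect_error(scaleFactorLibsize(0), "> 0")
  expect_error(scaleFactorSpikein(0), "spike-in")
})

test_that("peak annotation follows the fixed category priority", {
  genes <- GRanges("chr1", IRanges(10000, 20000), strand = "+")
  mcols(genes)$gene_id <- "g1"
  mkPeak <- function(summit) {
    p <- GRanges("chr1", IRanges(summit - 50, summit + 50))
    mcols(p)$peak_id <- "p"
    mcols(p)$summit <- summit
    p
  }
  catOf <- function(summit) annotatePeaks(mkPeak(summit), genes)$category
  expect_equal(catOf(9000), "Promoter.Up")       # TSS - 1000
  expect_equal(catOf(11500), "Promoter.Down")    # TSS + 1500, also genic
  expect_equal(catOf(15000), "Genic")
  expect_equal(catOf(19500), "Genic")   # genic outranks TES in the priority
  expect_equal(catOf(21000), "TES")     # within TES + 2 kb, outside the body
  expect_equal(catOf(5000), "distal5")           # 5 kb upstream
  expect_equal(catOf(60000), "distal3")          # 40 kb past TES
  expect_equal(catOf(500000), "intergenic")

  ## minus-strand gene: upstream is to the genomic right
  genesM <- GRanges("chr1", IRanges(10000, 20000), strand = "-")
  mcols(genesM)$gene_id <- "gm"
  expect_equal(annotatePeaks(mkPeak(21000), genesM)$category, "Promoter.Up")
  expect_equal(annotatePeaks(mkPeak(9500), genesM)$category, "TES")

  ## exon models split genic hits
  exons <- GRanges("chr1", IRanges(c(14000, 18000), c(14500, 18500)))
  expect_equal(annotatePeaks(mkPeak(14200), genes, exons)$category, "Exonic")
  expect_equal(annotatePeaks(mkPeak(16000), genes, exons)$category,
               "Intronic")
})

test_that("annotation is total: one category per peak, counts sum to n", {
  set.seed(41)
  genes <- GRanges("chr1", IRanges(seq(1e4, 9e5, by = 1e5), width = 2e4),
                   strand = sample(c("+", "-"), 9, TRUE))
  mcols(genes)$gene_id <- paste0("g", 1:9)
  peaks <- randomIntervals(300, chroms = "chr1", maxPos = 1.2e6,
                           stranded = FALSE)
  mcols(peaks)$peak_id <- paste0("p", seq_along(peaks))
  ann <- annotatePeaks(peaks, genes)
  expect_equal(nrow(ann), 300)
  expect_equal(sum(table(ann$category)), 300)
  expect_true(all(ann$category %in% c("Promoter.Up", "Promoter.Down",
                                      "Genic", "TES", "distal5", "distal3",
                                      "intergenic")))
  expect_true(all(is.na(ann$assigned_gene[ann$category == "intergenic"])))
  expect_true(all(!is.na(ann$assigned_gene[ann$category != "intergenic"])))
})
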