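mkTable <- function(m, spike = NULL) {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(paste0("f", seq_len(nrow(m))),
                        paste0("s", seq_len(ncol(m))))
  CountTable(m, spike)
}

test_that("CPM filtering keeps features above threshold in >= 1 sample", {
  m <- rbind(a = c(0, 0), b = c(1000, 0), c = c(1, 1))
  colnames(m) <- c("s1", "s2")
  ## library sizes 1001 and 1: feature c has CPM ~999/1e6... compute directly
  kept <- rownames(countsOf(cpmFilter(CountTable(m))))
  expect_false("a" %in% kept)
  expect_true("b" %in% kept)

  ## boundary: CPM exactly equal to the threshold in all samples is removed
  m2 <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("s1", "s2")))
  ## libsize 2 => cpm = 5e5; threshold 5e5 exact
  expect_equal(nrow(countsOf(cpmFilter(CountTable(m2), minCpm = 5e5))), 0)
  expect_equal(nrow(countsOf(cpmFilter(CountTable(m2), minCpm = 5e5 - 1))),
               2)
})

test_that("TMM factors are 1 for identical columns and geometric-mean 1", {
  m <- matrix(rpois(2000, 50), 500, 4)
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]; m[, 4] <- m[, 1]
  f <- normFactors(tmmFactors(mkTable(m)))
  expect_true(all(abs(f - 1) < 1e-6))
  set.seed(51)
  m2 <- matrix(rnbinom(4000, mu = 100, size = 5), 1000, 4)
  f2 <- normFactors(tmmFactors(mkTable(m2)))
  expect_lt(abs(exp(mean(log(f2))) - 1), 1e-12)
  ## pure scaling of a column is absorbed by the library size, factor ~ 1
  m3 <- m2; m3[, 2] <- m3[, 2] * 2
  f3 <- normFactors(tmmFactors(mkTable(m3)))
  expect_lt(abs(f3[2] - 1), 0.05)
})

test_that("spike-in size factors match the median-of-ratios hand computation", {
  sp <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2,
               dimnames = list(paste0("r", 1:3), c("s1", "s2")))
  f <- normFactors(spikeinSizeFactors(sp))
  ## geometric means: sqrt(200), sqrt(1800), sqrt(5000); all ratios 1/sqrt(2)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ## identical samples give equal factors
  spI <- cbind(s1 = c(10, 30), s2 = c(10, 30))
  expect_equal(unname(normFactors(spikeinSizeFactors(spI))), c(1, 1))

  ## rows with zeros are excluded from the reference set
  spZ <- rbind(sp, z = c(0, 5))
  expect_equal(normFactors(spikeinSizeFactors(spZ)), f)
  expect_error(spikeinSizeFactors(matrix(c(0, 1, 1, 0), 2,
                                         dimnames = list(c("a", "b"),
                                                         c("s1", "s2")))),
               "no usable")
})

test_that("spike-in factors are scale-equivariant in ratio and match DESeq2", {
  set.seed(52)
  ## odd feature count: the sample median is an observed ratio, so the
  ## log-space median used by DESeq2 coincides exactly
  sp <- matrix(rpois(404, 80) + 1, 101, 4,
               dimnames = list(paste0("r", 1:101), paste0("s", 1:4)))
  f <- normFactors(spikeinSizeFactors(sp))
  sp2 <- sp
  sp2[, 3] <- sp2[, 3] * 7
  f2 <- normFactors(spikeinSizeFactors(sp2))
  for (j in 1:4) {
    expected <- if (j == 3) 7 else 1
    expect_equal(f2[j] / f2[1] / (f[j] / f[1]),
                 if (j == 3) 7 else 1, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  skip_if_not_installed("DESeq2")
  expect_equal(unname(f),
               unname(DESeq2::estimateSizeFactorsForMatrix(sp)),
               tolerance = 1e-10)
})

test_that("the moderated test reduces to the ordinary t when d0 = 0", {
  set.seed(53)
  m <- matrix(rnbinom(300 * 8, mu = 100, size = 10), 300, 8)
  ct <- mkTable(m)
  design <- rep(c("a", "b"), each = 4)
  res <- moderatedTest(ct, design, priorDf = 0)
  y <- log2(t(t(m + 0.5) / (colSums(m) + 1)) * 1e6)
  for (i in c(1, 57, 300)) {
    tt <- t.test(y[i, 5:8], y[i, 1:4], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("the moderated test agrees with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(54)
  m <- matrix(rnbinom(2000 * 8, mu = rlnorm(2000, log(100), 1), size = 8),
              2000, 8)
  ct <- mkTable(m)
  design <- rep(c("a", "b"), each = 4)
  res <- moderatedTest(ct, design)
  y <- log2(t(t(m + 0.5) / (colSums(m) + 1)) * 1e6)
  fit <- limma::eBayes(limma::lmFit(y, cbind(1, rep(c(0, 1), each = 4))))
  expect_equal(attr(res, "d0"), unname(fit$df.prior), tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("planted effects rank above null features (AUC >= 0.95)", {
  set.seed(55)
  n <- 2000
  mu <- rlnorm(n, log(200), 1)
  planted <- seq_len(200)
  muMat <- outer(mu, rep(1, 8))
  muMat[planted, 5:8] <- muMat[planted, 5:8] / 4    # log2FC = -2
  m <- matrix(rnbinom(n * 8, mu = muMat, size = 10), n)
  res <- moderatedTest(mkTable(m), rep(c("a", "b"), each = 4))
  stat <- abs(res$t)
  r <- rank(stat)
  auc <- (sum(r[planted]) - length(planted) * (length(planted) + 1) / 2) /
    (length(planted) * (n - length(planted)))
  expect_gte(auc, 0.95)
})

test_that("BH q-values match the step-up definition and are monotone", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  set.seed(56)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bhFdr(p)
    expect_equal(q, bruteBH(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bhFdr(c(0.1, NaN)), "NaN")
})

test_that("DB/DE classification respects inclusive thresholds", {
  res <- data.frame(log2fc = c(1.2, 0.9, -1.0, 1.5, 1.5),
                    fdr = c(0.01, 0.001, 0.05, 0.01, 0.06),
                    mean_cpm = c(10, 10, 10, 0.5, 10))
  expect_equal(classifyDb(res),
               c("up", "unchanged", "down", "up", "unchanged"))
  expect_equal(classifyDe(res),
               c("up", "unchanged", "down", "unchanged", "unchanged"))
  ## thresholds are configurable
  expect_equal(classifyDb(res, minAbsLog2fc = 0.5, maxFdr = 0.1)[5], "up")
})
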