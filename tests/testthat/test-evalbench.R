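test_that("editDistance matches an independent Levenshtein oracle", {
  expect_equal(editDistance("ACGT", "ACG"), 1L)
  expect_equal(editDistance("ACGT", "ACGT"), 0L)
  expect_equal(editDistance("", "ACGT"), 4L)
  set.seed(41)
  for (rep in 1:15) {
    a <- randomDNA(sample(0:12, 1))
    b <- randomDNA(sample(0:12, 1))
    expect_equal(editDistance(a, b), oracleLevenshtein(a, b))
  }
  # vectorized elementwise
  expect_equal(editDistance(c("AAA", "CCC"), c("AAT", "CCC")), c(1L, 0L))
})

test_that("avgEditDistance averages the top-n candidates", {
  cands <- c("ACGT", "ACGA", "TTTT")
  expect_equal(avgEditDistance(cands, "ACGT"), mean(c(0, 1, 3)))
  expect_equal(avgEditDistance(cands, "ACGT", n = 2), 0.5)
  expect_error(avgEditDistance(character(0), "ACGT"), "empty")
})

test_that("pca2d matches an eigen-decomposition oracle", {
  set.seed(42)
  X <- matrix(rnorm(30 * 5), 30, 5)
  coords <- pca2d(X)
  expect_equal(dim(coords), c(30L, 2L))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  for (j in 1:2) {
    v <- eg$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(unname(coords[, j]), as.numeric(Xc %*% v), tolerance = 1e-8)
  }
  # projected variance equals the top eigenvalues / (n - 1)
  expect_equal(unname(apply(coords, 2, var)),
               eg$values[1:2] / (nrow(X) - 1), tolerance = 1e-8)
  expect_false(attr(coords, "rankDeficient"))
})

test_that("pca2d flags rank-deficient input", {
  X <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  coords <- pca2d(X)
  expect_true(attr(coords, "rankDeficient"))
  expect_equal(unname(coords[, 2]), rep(0, 10))
  expect_error(pca2d(matrix(0, 2, 3)), "3 rows")
})

test_that("sequenceFeatures and centroidDistance behave geometrically", {
  f <- sequenceFeatures(c("ACGT", "ACGA", "TTTT"), maxLen = 6L)
  expect_equal(dim(f), c(3L, 42L))
  # identical sequences get identical feature rows
  f2 <- sequenceFeatures(c("ACGT", "ACGT"), maxLen = 6L)
  expect_equal(f2[1, ], f2[2, ])
  A <- matrix(c(0, 0, 2, 0), 2, byrow = TRUE)
  B <- matrix(c(4, 3), 1)
  expect_equal(centroidDistance(A, B), sqrt(9 + 9))
  expect_equal(centroidDistance(A, A), 0)
  expect_error(centroidDistance(A[0, , drop = FALSE], B), "empty")
})

test_that("rankingMetrics reproduces hand-computed AUROC/AUPRC/Top-1", {
  # perfect separation
  m <- rankingMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$top1, 1)
  # fully tied scores: AUROC 0.5, AUPRC = prevalence
  t2 <- rankingMetrics(rep(0.5, 4), c(1, 0, 1, 0))
  expect_equal(t2$auroc, 0.5)
  expect_equal(t2$auprc, 0.5)
  # reversed ranking
  expect_equal(rankingMetrics(c(0.1, 0.9), c(1, 0))$auroc, 0)
  # hand case: scores 4,3,2,1 labels 1,0,1,0
  m3 <- rankingMetrics(4:1, c(1, 0, 1, 0))
  expect_equal(m3$auroc, 0.75)                       # 3 of 4 pairs correct
  expect_equal(m3$auprc, 0.5 * 1 + 0.5 * (2 / 3))    # step PR curve
  expect_equal(m3$top1, 1)
  expect_error(rankingMetrics(1:3, c(1, 1, 1)), "negative")
})

test_that("baselineFrequency ranks by count with lexicographic ties", {
  pool <- new("PoolRound", sequences = c("TTTT", "AAAA", "CCCC"),
              counts = c(5L, 9L, 5L), roundId = 3L)
  bf <- baselineFrequency(pool)
  expect_equal(bf$sequence, c("AAAA", "CCCC", "TTTT"))
  expect_equal(bf$score, c(9, 5, 5))
  expect_equal(nrow(baselineFrequency(pool, 2L)), 2L)
})

test_that("baselineEnrichment computes smoothed frequency ratios", {
  early <- new("PoolRound", sequences = c("AAAA", "CCCC"),
               counts = c(9L, 1L), roundId = 1L)
  late <- new("PoolRound", sequences = c("AAAA", "CCCC", "GGGG"),
              counts = c(5L, 10L, 5L), roundId = 3L)
  be <- baselineEnrichment(early, late)
  # manual: depths 10 and 20, pseudocount 1
  man <- c(AAAA = (6 / 20) / (10 / 10), CCCC = (11 / 20) / (2 / 10),
           GGGG = (6 / 20) / (1 / 10))
  man <- sort(man, decreasing = TRUE)
  expect_equal(be$sequence, names(man))
  expect_equal(be$score, unname(man))
})

test_that("baselineClusterConsensus finds the dominant cluster", {
  seqs <- c("ACGTACGTAC", "ACGTACGTAT", "ACGTACGAAC",  # one tight cluster
            "TTTTGGGGCC")                              # a singleton
  pool <- new("PoolRound", sequences = seqs,
              counts = c(10L, 8L, 6L, 3L), roundId = 5L)
  res <- baselineClusterConsensus(pool, radius = 2L)
  expect_equal(res$largestCluster, "ACGTACGTAC")
  expect_equal(length(unique(res$labels)), 2L)
  expect_true(grepl("^[ACGT]+$", res$wholePool))
})
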