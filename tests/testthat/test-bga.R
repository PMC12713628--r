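test_that("bgaConfig validates its arguments", {
  cfg <- bgaConfig()
  expect_equal(cfg$threshold, 0.9)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$convergence_tolerance, 0.01)
  expect_equal(cfg$convergence_window, 5L)
  expect_error(bgaConfig(threshold = 0), "threshold")
  expect_error(bgaConfig(threshold = 1), "threshold")
  expect_error(bgaConfig(batch_size = 0L), "batch_size")
})

test_that("bgaSample draws, decodes and accumulates batch statistics", {
  m <- fxVaeModel()
  cfg <- bgaConfig(batch_size = 16L, n_batches = 6L, threshold = 0.5,
                   seed = 11L)
  res <- bgaSample(m, cfg)
  expect_named(res, c("retained", "stats", "status", "scores"))
  expect_equal(nrow(res$stats), 6L)
  expect_equal(length(res$scores), 6L * 16L)
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  # cumulative columns really are cumulative over all scores so far
  for (b in seq_len(6L)) {
    sofar <- res$scores[seq_len(b * 16L)]
    expect_equal(res$stats$cum_mean[b], mean(sofar))
    expect_equal(res$stats$cum_sd[b], sd(sofar))
    expect_equal(res$stats$cum_prop[b], mean(sofar > cfg$threshold))
  }
  # retained sequences all exceed the threshold and carry a class
  if (nrow(res$retained)) {
    expect_true(all(res$retained$score > cfg$threshold))
    expect_true(all(res$retained$class %in% 1:8))
    expect_true(all(grepl("^[ACGT]+$", res$retained$sequence)))
  }
  expect_equal(res$status, if (nrow(res$retained)) "ok" else "empty")
})

test_that("bgaSample is deterministic under a fixed seed", {
  m <- fxVaeModel()
  cfg <- bgaConfig(batch_size = 8L, n_batches = 3L, seed = 5L)
  expect_identical(bgaSample(m, cfg), bgaSample(m, cfg))
  cfg2 <- bgaConfig(batch_size = 8L, n_batches = 3L, seed = 6L)
  expect_false(identical(bgaSample(m, cfg)$scores, bgaSample(m, cfg2)$scores))
})

test_that("an unattainable threshold yields the explicit empty status", {
  m <- fxVaeModel()
  cfg <- bgaConfig(batch_size = 8L, n_batches = 2L,
                   threshold = 1 - 1e-12, seed = 1L)
  res <- bgaSample(m, cfg)
  expect_equal(res$status, "empty")
  expect_equal(nrow(res$retained), 0L)
  expect_equal(nrow(res$stats), 2L)
})

test_that("bgaConverged detects flat and moving cumulative statistics", {
  flat <- data.frame(batch = 1:10, mean = 0.5, sd = 0.1, prop = 0.2,
                     cum_mean = 0.5, cum_sd = 0.1, cum_prop = 0.2)
  expect_true(bgaConverged(flat, bgaConfig()))
  moving <- flat
  moving$cum_mean <- seq(0.5, 1.5, length.out = 10)
  expect_false(bgaConverged(moving, bgaConfig()))
  # fewer rows than the window cannot be converged
  expect_false(bgaConverged(flat[1:3, ], bgaConfig()))
  # a spike inside the trailing window breaks convergence
  spiked <- flat
  spiked$cum_prop[9] <- 0.4
  expect_false(bgaConverged(spiked, bgaConfig()))
})

test_that("groupAndSort groups by class with stable descending order", {
  seqs <- c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT")
  cls <- c(1L, 2L, 1L, 2L, 1L)
  sco <- c(0.5, 0.9, 0.8, 0.9, 0.8)
  g <- groupAndSort(seqs, cls, sco, nClasses = 3L)
  expect_named(g, c("1", "2", "3"))
  expect_equal(g[["1"]]$sequence, c("ACGT", "GGGG", "AAAA"))
  expect_equal(g[["1"]]$score, c(0.8, 0.8, 0.5))
  # score tie in class 2 breaks lexicographically
  expect_equal(g[["2"]]$sequence, c("CCCC", "TTTT"))
  expect_equal(nrow(g[["3"]]), 0L)
  expect_error(groupAndSort("AA", 4L, 0.1, nClasses = 3L), "unknown class")
  expect_error(groupAndSort(seqs, cls, sco[1:3]), "length")
})

test_that("assignClassByNeighbors recovers labels of near-training sequences", {
  gp <- fxPairs()
  tr <- aptSequences(gp$pairs)
  cls <- classLabels(gp$pairs)
  # exact training sequences map back to their own class (k = 1)
  idx <- c(1L, 10L, 25L, 40L)
  expect_identical(assignClassByNeighbors(tr[idx], gp$pairs, k = 1L),
                   cls[idx])
  # one substitution away still maps back
  mut <- vapply(tr[idx], function(s) {
    substr(s, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, 3, 3))[1]
    s
  }, "", USE.NAMES = FALSE)
  expect_identical(assignClassByNeighbors(mut, gp$pairs, k = 1L), cls[idx])
  # empty input, validation
  expect_identical(assignClassByNeighbors(character(0), gp$pairs), integer(0))
  expect_error(assignClassByNeighbors("ACGX", gp$pairs))
  # k larger than the training set is clamped, not an error
  expect_length(assignClassByNeighbors(tr[1], gp$pairs, k = 10000L), 1L)
})

test_that("filterByTrainingAnchors keeps members near top-scoring binders", {
  gp <- fxPairs()
  tr <- aptSequences(gp$pairs)
  cls <- classLabels(gp$pairs)
  cl <- cls[1]
  sco <- aptScores(gp$pairs)
  own <- tr[cls == cl]
  # the class's top-scoring sequence is its own anchor (distance 0);
  # homopolymers are maximally far from any training sequence
  near <- own[which.max(sco[cls == cl])]
  far <- c(strrep("A", 40L), strrep("C", 40L), strrep("G", 40L))
  pool <- c(far[1], near, far[2], far[3])
  expect_identical(filterByTrainingAnchors(pool, gp$pairs, cl, keep = 0.25),
                   near)
  # keep = 1 retains everything, input order preserved
  expect_identical(filterByTrainingAnchors(pool, gp$pairs, cl, keep = 1),
                   pool)
  # empty input and validation
  expect_identical(filterByTrainingAnchors(character(0), gp$pairs, cl),
                   character(0))
  expect_error(filterByTrainingAnchors("ACGX", gp$pairs, cl))
  expect_error(filterByTrainingAnchors(own[1], gp$pairs, 999L),
               "no training pairs")
  # nAnchors beyond the class size is clamped, not an error
  expect_length(filterByTrainingAnchors(own[1], gp$pairs, cl,
                                        nAnchors = 10000L), 1L)
})
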