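test_that("syntheticFamilySpec and syntheticSelexSpec validate arguments", {
  sp <- syntheticFamilySpec()
  expect_equal(sp$n_classes, 8L)
  expect_equal(sp$n_pairs, 195L)
  expect_equal(sp$motif_length, 10L)
  expect_error(syntheticFamilySpec(motif_length = 5L), "motif_length")
  expect_error(syntheticFamilySpec(n_pairs = 3L, n_classes = 8L), "n_pairs")
  ss <- syntheticSelexSpec()
  expect_equal(ss$pool_size, 2000L)
  expect_equal(ss$rounds, c(3L, 5L, 7L))
  expect_error(syntheticSelexSpec(pool_size = 10L), "pool_size")
  expect_error(syntheticSelexSpec(mutation_rate = 0.5), "mutation_rate")
})

test_that("genTargets shares one scaffold across classes", {
  tg <- genTargets(syntheticFamilySpec(n_classes = 4L, n_pairs = 40L))
  expect_equal(nrow(tg), 4L)
  expect_equal(tg$class_id, 1:4)
  expect_equal(length(unique(tg$smiles)), 4L)
  # every SMILES parses and the descriptions are attached
  tl <- attr(tg, "targets")
  expect_equal(length(tl), 4L)
  for (t in tl) expect_true(all(c("smiles", "fingerprint") %in% names(t)))
  expect_error(genTargets(syntheticFamilySpec(n_classes = 9L,
                                              n_pairs = 90L)), "at most")
})

test_that("genPairs plants class motifs in proportion to the score", {
  gp <- genPairs(syntheticFamilySpec(n_pairs = 120L, seed = 5L))
  ats <- gp$pairs
  expect_s4_class(ats, "AptamerTargetSet")
  expect_equal(length(ats), 120L)
  expect_equal(length(gp$motifs), 8L)
  expect_false(anyDuplicated(gp$motifs) > 0)
  expect_equal(gp$motifStarts, (((1:8 - 1) * 4) %% 31) + 1)
  expect_true(all(aptScores(ats) >= 0 & aptScores(ats) <= 1))
  expect_true(all(nchar(aptSequences(ats)) == 40L))
  # motif presence at the planted site should track the score:
  # mean score of motif carriers > mean score of non-carriers
  has <- vapply(seq_len(120L), function(i) {
    cl <- classLabels(ats)[i]
    st <- gp$motifStarts[cl]
    substr(aptSequences(ats)[i], st, st + 9L) == gp$motifs[cl]
  }, logical(1))
  expect_gt(mean(has), 0.2)  # a substantial fraction carries the motif
  expect_gt(mean(aptScores(ats)[has]), mean(aptScores(ats)[!has]))
  # structures are valid folds of the sequences
  expect_true(all(nchar(aptStructures(ats)) == 40L))
})

test_that("genPairs is reproducible and seed-sensitive", {
  sp <- syntheticFamilySpec(n_pairs = 30L, seed = 9L)
  expect_identical(genPairs(sp)$pairs, genPairs(sp)$pairs)
  sp2 <- syntheticFamilySpec(n_pairs = 30L, seed = 10L)
  expect_false(identical(genPairs(sp)$motifs, genPairs(sp2)$motifs))
})

test_that("simulateSelex enriches the pool toward the planted binder", {
  sim <- fxSelex()
  expect_named(sim$rounds, c("R3", "R5", "R7"))
  expect_equal(nchar(sim$binder), 40L)
  depths <- vapply(sim$rounds, function(p) sum(p@counts), 0)
  expect_true(all(depths == 1200))
  # mean (count-weighted) edit distance to the binder shrinks over rounds
  wdist <- vapply(sim$rounds, function(p)
    sum(editDistance(p@sequences, rep(sim$binder, length(p@sequences))) *
          p@counts) / sum(p@counts), 0)
  expect_true(wdist["R5"] < wdist["R3"])
  expect_true(wdist["R7"] < wdist["R5"])
  # diversity collapses as selection proceeds
  expect_lt(length(sim$rounds$R7), length(sim$rounds$R3))
})

test_that("simulateSelex is reproducible under a fixed seed", {
  sp <- syntheticSelexSpec(pool_size = 1000L, rounds = 2L, seed = 3L)
  expect_identical(simulateSelex(sp), simulateSelex(sp))
})

test_that("writeSyntheticBundle writes every pipeline artifact", {
  d <- tempfile("bundle")
  fam <- syntheticFamilySpec(n_classes = 3L, n_pairs = 24L, seed = 2L)
  sel <- syntheticSelexSpec(pool_size = 1000L, rounds = c(2L, 3L), seed = 2L)
  man <- writeSyntheticBundle(d, fam, sel)
  expect_true(all(file.exists(file.path(
    d, c("training_pairs.tsv", "targets.tsv", "pool_R2.tsv", "pool_R3.tsv",
         "truth.fasta", "manifest.json")))))
  expect_equal(man$rounds, c("R2", "R3"))
  expect_equal(length(man$motifs), 3L)
  # round-trip: pairs reload identically (sequence, class, score)
  ats <- readTrainingPairs(file.path(d, "training_pairs.tsv"))
  gp <- genPairs(fam)
  expect_equal(aptSequences(ats), aptSequences(gp$pairs))
  expect_equal(classLabels(ats), classLabels(gp$pairs))
  expect_equal(aptScores(ats), aptScores(gp$pairs))
  # truth FASTA holds the planted binder
  expect_equal(unname(readFastaSeqs(file.path(d, "truth.fasta"))),
               simulateSelex(sel)$binder)
  unlink(d, recursive = TRUE)
})
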