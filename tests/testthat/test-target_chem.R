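test_that("parseSmiles handles chains, branches, rings and bond orders", {
  g <- parseSmiles("CCO")
  expect_equal(g$atoms, c("C", "C", "O"))
  expect_equal(nrow(g$bonds), 2L)
  # branch
  g <- parseSmiles("CC(C)C")
  expect_equal(length(g$atoms), 4L)
  expect_true(all(g$bonds[g$bonds[, 1] == 2L | g$bonds[, 2] == 2L, ] != 0))
  deg <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), 4L)
  expect_equal(deg, c(1L, 3L, 1L, 1L))
  # ring closure: benzene (aromatic, order 1.5)
  g <- parseSmiles("c1ccccc1")
  expect_equal(length(g$atoms), 6L)
  expect_equal(nrow(g$bonds), 6L)
  expect_true(all(g$bonds[, "order"] == 1.5))
  expect_true(all(g$aromatic))
  # double bond
  g <- parseSmiles("C=O")
  expect_equal(unname(g$bonds[1, "order"]), 2)
  # two-character halogen
  g <- parseSmiles("CCl")
  expect_equal(g$atoms, c("C", "Cl"))
})

test_that("parseSmiles rejects malformed input naming the position", {
  expect_error(parseSmiles("C(C"), "branch")
  expect_error(parseSmiles("CC)"), "position 3")
  expect_error(parseSmiles("C1CC"), "ring")
  expect_error(parseSmiles("C=%"), ".")
  err <- tryCatch(parseSmiles("CXO"), error = conditionMessage)
  expect_match(err, "2")           # offending position reported
})

test_that("adjacency and distance matrices are consistent", {
  g <- parseSmiles("CCO")
  A <- adjacencyMatrix(g)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, 3))
  D <- distanceMatrix(g)
  expect_equal(D, t(D))
  expect_equal(D[1, 3], 2)
  expect_equal(D[1, 2], 1)
  # distance 1 exactly where adjacent
  expect_equal((D == 1) * 1, (A > 0) * 1)
  # triangle inequality on a ring
  D <- distanceMatrix(parseSmiles("C1CCCCC1"))
  expect_equal(max(D), 3)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j])
})

test_that("morganFingerprint is deterministic, seed- and structure-sensitive", {
  g1 <- parseSmiles("CCO")
  f1 <- morganFingerprint(g1)
  expect_equal(length(f1), 2048L)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_identical(f1, morganFingerprint(parseSmiles("CCO")))
  # different molecule -> different bits; different seed -> different bits
  expect_false(identical(f1, morganFingerprint(parseSmiles("CCN"))))
  expect_false(identical(f1, morganFingerprint(g1, seed = 43L)))
  # radius 0 is a subset of radius 2 bit positions
  f0 <- morganFingerprint(g1, radius = 0L)
  expect_true(all(which(f0 == 1L) %in% which(morganFingerprint(g1) == 1L)))
})

test_that("buildSandwich embeds the three target slabs top-left", {
  tgt <- describeTarget("CCO")
  enc <- encodeSequence("ACGT", "....", maxLen = 6L)
  S <- 6L
  sw <- buildSandwich(enc, tgt$adjacency, tgt$distance, S)
  expect_equal(dim(sw), c(3L, S, S))
  n <- nrow(tgt$adjacency)
  expect_equal(sw[3, seq_len(n), seq_len(n)], unname(tgt$adjacency))
  expect_true(all(sw[3, (n + 1):S, ] == 0))
  # structure slab carries the one-hot in its first 3 columns
  expect_equal(sw[2, seq_len(4), seq_len(3)],
               unname(enc@structOneHot[1:4, ]))
})

test_that("describeTarget bundles graph, matrices and fingerprint", {
  tgt <- describeTarget("CC(C)O")
  expect_named(tgt, c("smiles", "graph", "adjacency", "distance",
                      "fingerprint", "nAtoms"))
  expect_equal(tgt$nAtoms, 4L)
  expect_equal(dim(tgt$adjacency), c(4L, 4L))
})

test_that("disconnected molecular graphs are rejected", {
  g <- parseSmiles("CCO")
  g$bonds <- g$bonds[0, , drop = FALSE]
  expect_error(distanceMatrix(g), "disconnected")
})

test_that("targets table round-trips through TSV", {
  tg <- genTargets()
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  rt <- readTargetsTable(path)
  expect_equal(rt$smiles, tg$smiles)
  expect_equal(rt$class_id, tg$class_id)
})
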