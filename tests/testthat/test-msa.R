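test_that("pairwise progressiveMSA attains the optimal end-free score", {
  set.seed(31)
  for (rep in 1:10) {
    a <- randomDNA(sample(6:14, 1))
    b <- randomDNA(sample(6:14, 1))
    rows <- progressiveMSA(c(a, b))
    expect_equal(gsub("-", "", rows[1]), a)
    expect_equal(gsub("-", "", rows[2]), b)
    expect_equal(nchar(rows[1]), nchar(rows[2]))
    # score of the produced alignment equals the DP optimum from the oracle
    ca <- strsplit(rows[1], "")[[1]]
    cb <- strsplit(rows[2], "")[[1]]
    inner <- which(ca != "-" & cb != "-")
    span <- if (length(inner)) seq(min(inner), max(inner)) else integer(0)
    sc <- sum(vapply(span, function(k) {
      if (ca[k] == "-" || cb[k] == "-") -2
      else if (ca[k] == cb[k]) 1 else -1
    }, 0))
    expect_equal(sc, oracleNW(a, b))
  }
})

test_that("progressiveMSA preserves inputs and handles edge cases", {
  seqs <- c("ACGTACGT", "ACGTTCGT", "ACGACGT", "TTTTACGT")
  rows <- progressiveMSA(seqs)
  expect_equal(length(rows), 4L)
  expect_equal(length(unique(nchar(rows))), 1L)
  expect_equal(gsub("-", "", rows), seqs)
  expect_equal(progressiveMSA("ACGT"), "ACGT")
  expect_error(progressiveMSA(character(0)), "no sequences")
  expect_error(progressiveMSA("ACGX"))
  # identical inputs align without gaps
  same <- progressiveMSA(rep("ACGTAC", 3))
  expect_equal(same, rep("ACGTAC", 3))
})

test_that("consensusTemplate confines conserved columns and drops gaps", {
  aln <- c("ACGT-A",
           "ACGA-A",
           "ACGT-A",
           "ACTACA",
           "ACGTCA")
  tpl <- consensusTemplate(aln, conservationThreshold = 0.8,
                           maxGapFraction = 0.5)
  expect_s4_class(tpl, "LibraryTemplate")
  # column 5 has 3/5 gaps -> dropped; col 1,2 fully conserved; col 3 G is
  # 4/5 = 0.8 -> confined; col 4 T is 3/5 -> N; col 6 conserved
  expect_equal(paste(tpl@symbols, collapse = ""), "ACGNA")
  expect_equal(tpl@confined, c(1L, 2L, 3L, 5L))
  expect_error(consensusTemplate(character(0)), "empty")
  expect_error(consensusTemplate(c("--", "--")), "gappy")
})

test_that("renderLibrary and emitLibrary format primers and positions", {
  tpl <- consensusTemplate(c("ACGT", "ACTT", "ACAT"), forward = "GGG",
                           reverse = "TTC")
  expect_equal(renderLibrary(tpl), "gggACNTttc")
  rec <- withCallingHandlers(emitLibrary(tpl, id = "lib1"),
                             warning = function(w) invokeRestart("muffleWarning"))
  expect_equal(rec[1], ">lib1 confined=1,2,4")
  expect_equal(rec[2], "gggACNTttc")
  # fully confined templates warn about missing diversity
  expect_warning(emitLibrary(consensusTemplate(rep("ACGT", 3))),
                 "no N positions")
  f <- tempfile(fileext = ".fasta")
  withCallingHandlers(emitLibrary(tpl, id = "lib1", path = f),
                      warning = function(w) invokeRestart("muffleWarning"))
  expect_equal(readLines(f), c(">lib1 confined=1,2,4", "gggACNTttc"))
})

test_that("candidateConsensus takes the plurality base per column", {
  expect_equal(candidateConsensus(c("ACGT", "ACGT", "ACTT")), "ACGT")
  expect_equal(candidateConsensus("AC-GT"), "ACGT")
  # already-gapped rows are respected as an alignment
  expect_equal(candidateConsensus(c("AC-T", "ACGT", "ACGT")), "ACGT")
  expect_error(candidateConsensus(character(0)), "no sequences")
})

test_that("sequenceLogoCounts counts bases by position", {
  counts <- sequenceLogoCounts(c("ACGT", "ACGA", "ACGT"))
  expect_equal(dim(counts), c(4L, 4L))
  expect_equal(colnames(counts), c("A", "C", "G", "T"))
  expect_equal(unname(rowSums(counts)), rep(3L, 4L))
  expect_equal(unname(counts[1, "A"]), 3L)
  expect_equal(unname(counts[4, "T"]), 2L)
  expect_equal(unname(counts[4, "A"]), 1L)
})

test_that("refineAlignment drops rows disagreeing with the plurality", {
  rows <- c("ACGTAC", "ACGTAC", "ACGTAC", "ACGTAT", "TTTTTT")
  out <- refineAlignment(rows)
  expect_false("TTTTTT" %in% out)
  expect_true(all(c("ACGTAC") %in% out))
  # homogeneous input is untouched
  same <- rep("ACGT", 4)
  expect_identical(refineAlignment(same), same)
  # never trims below minRows
  div <- c("AAAA", "CCCC", "GGGG", "TTTT")
  expect_gte(length(refineAlignment(div, minRows = 3L)), 3L)
  # input order preserved
  out2 <- refineAlignment(c("ACGTAT", "ACGTAC", "ACGTAC", "ACGTAC", "TTTTTT"),
                          maxPasses = 1L)
  expect_identical(out2, c("ACGTAT", "ACGTAC", "ACGTAC", "ACGTAC"))
  expect_error(refineAlignment(character(0)), "empty")
  expect_error(refineAlignment(c("ACG", "ACGT")), "equal length")
})

test_that("candidateConsensus uses positional columns for equal-length sets", {
  # a diverse equal-length set must not error through MSA degeneracy
  set.seed(44)
  seqs <- vapply(1:12, function(i) randomDNA(30), "")
  expect_equal(nchar(candidateConsensus(seqs)), 30L)
})
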