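test_that("trainAptaVAE validates its inputs", {
  gp <- fxPairs()
  expect_error(trainAptaVAE(gp$pairs[1:10], fxVaeConfig()), "20")
  one <- genPairs(syntheticFamilySpec(n_classes = 1L, n_pairs = 25L,
                                      seed = 2L))$pairs
  expect_error(trainAptaVAE(one, fxVaeConfig()), "class")
})

test_that("training produces a full history with the Eq-style identity", {
  m <- fxVaeModel()
  h <- m@history
  expect_s4_class(m, "AptaVAEModel")
  expect_true(all(c("epoch", "sequence", "target", "class", "score",
                    "attention", "matrix", "kl", "total", "val_total",
                    "kl_weight") %in% names(h)))
  # logged total always equals the full composite combination of the
  # logged components (KL un-annealed in the log)
  expect_equal(h$total,
               h$sequence + h$target + h$class + 2 * h$score +
                 h$attention + h$matrix + h$kl,
               tolerance = 1e-12)
  expect_true(all(is.finite(h$val_total)))
  expect_true(all(h$kl >= 0))
  expect_true(all(h$kl_weight > 0 & h$kl_weight <= 1))
})

test_that("training reduces the validation loss on the small fixture", {
  h <- fxVaeModel()@history
  expect_lt(min(h$val_total), h$val_total[1])
})

test_that("encodePair yields a finite latent of the configured size", {
  m <- fxVaeModel()
  ld <- encodePair(m, fxPairs()$pairs, 1L)
  expect_s4_class(ld, "LatentDistribution")
  expect_equal(length(ld@mu), m@config$latent_dim)
  expect_true(all(is.finite(ld@mu)))
  expect_true(all(abs(ld@logvar) <= 8))
  # deterministic
  expect_identical(ld, encodePair(m, fxPairs()$pairs, 1L))
})

test_that("decodeLatent returns sequences, scores, classes of right shape", {
  m <- fxVaeModel()
  set.seed(1)
  Z <- matrix(rnorm(3 * m@config$latent_dim), 3)
  dec <- decodeLatent(m, Z)
  expect_equal(length(dec$sequences), 3L)
  expect_true(all(grepl("^[ACGT]+$", dec$sequences)))
  expect_true(all(dec$scores >= 0 & dec$scores <= 1))
  expect_true(all(dec$classes %in% seq_len(8L)))
  expect_equal(dim(dec$classProbs), c(3L, 8L))
  expect_equal(unname(rowSums(dec$classProbs > 0)), rep(8, 3))
  det <- decodeLatent(m, Z, detail = TRUE)
  expect_true(all(c("fingerprint", "attention", "distance",
                    "structureSlab", "adjacency") %in% names(det)))
})

test_that("ablation toggles train and drop the corresponding facets", {
  gp <- fxPairs()
  m1 <- trainAptaVAE(gp$pairs, fxVaeConfig(use3d = FALSE, epochs = 2L,
                                           patience = 2L))
  expect_true(all(m1@history$matrix == 0))
  m2 <- trainAptaVAE(gp$pairs, fxVaeConfig(useAttention = FALSE,
                                           epochs = 2L, patience = 2L))
  expect_true(all(m2@history$attention == 0))
  m3 <- trainAptaVAE(gp$pairs, fxVaeConfig(useSkip = FALSE, epochs = 2L,
                                           patience = 2L))
  expect_s4_class(m3, "AptaVAEModel")
})

test_that("training is bit-reproducible under a fixed seed", {
  gp <- fxPairs()
  cfg <- fxVaeConfig(epochs = 3L, patience = 3L, seed = 23L)
  m1 <- trainAptaVAE(gp$pairs, cfg)
  m2 <- trainAptaVAE(gp$pairs, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
  # a different seed changes the trajectory
  m3 <- trainAptaVAE(gp$pairs, fxVaeConfig(epochs = 3L, patience = 3L,
                                           seed = 24L))
  expect_false(identical(m1@params, m3@params))
})

test_that("reconstruction from the posterior mean yields a plausible length", {
  m <- fxVaeModel()
  gp <- fxPairs()
  ld <- encodePair(m, gp$pairs, 5L)
  dec <- decodeLatent(m, matrix(ld@mu, 1))
  # the occupancy read-out cannot exceed the training length and, even for
  # this under-trained fixture, should keep most of the 40 positions
  L <- nchar(aptSequences(gp$pairs)[5])
  expect_lte(nchar(dec$sequences), L)
  expect_gte(nchar(dec$sequences), L - 5L)
})
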