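test_that("trainAptaClux validates input and records a full history", {
  tiny <- new("PoolRound", sequences = c("ACGT", "GGTT"),
              counts = c(1L, 1L), roundId = 1L)
  expect_error(trainAptaClux(tiny, fxCluxConfig()), "50 unique")
  m <- fxCluxModel()
  expect_s4_class(m, "AptaCluxModel")
  h <- m@history
  expect_true(all(c("epoch", "sequence", "structure", "kl", "total",
                    "val_total", "kl_weight") %in% names(h)))
  expect_equal(h$total, h$sequence + h$structure + h$kl, tolerance = 1e-12)
  expect_true(all(is.finite(h$val_total)))
})

test_that("trainAptaClux is bit-reproducible under a fixed seed", {
  sim <- fxSelex()
  cfg <- fxCluxConfig(epochs = 3L, patience = 3L, seed = 8L)
  m1 <- trainAptaClux(sim$rounds$R3, cfg)
  m2 <- trainAptaClux(sim$rounds$R3, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
})

test_that("latentMeans is deterministic with sequence row names", {
  m <- fxCluxModel()
  pool <- fxSelex()$rounds$R3
  lat <- latentMeans(m, pool)
  expect_equal(nrow(lat), length(pool))
  expect_equal(ncol(lat), m@config$latent_dim)
  expect_equal(rownames(lat), pool@sequences)
  expect_identical(lat, latentMeans(m, pool))
  # duplicated sequences give identical rows
  two <- latentMeans(m, c(pool@sequences[1], pool@sequences[1]))
  expect_equal(two[1, ], two[2, ])
  expect_true(is.character(attr(lat, "provenance")))
})

test_that("kdeDensity matches a brute-force kernel sum", {
  set.seed(13)
  X <- matrix(rnorm(20 * 3), 20, 3)
  h <- 0.7
  dens <- kdeDensity(X, bandwidth = h, pcaDims = 0L)
  ref <- vapply(1:20, function(i)
    mean(vapply(1:20, function(j)
      exp(-sum((X[i, ] - X[j, ])^2) / (2 * h^2)) /
        ((2 * pi)^(3 / 2) * h^3), 0)), 0)
  expect_equal(unname(as.numeric(dens)), ref, tolerance = 1e-10)
  expect_false(attr(dens, "degenerate"))
  # PCA reduction: density computed in the projected space
  Xw <- matrix(rnorm(20 * 12), 20, 12)
  d8 <- kdeDensity(Xw, bandwidth = h, pcaDims = 8L)
  P <- stats::prcomp(Xw)$x[, 1:8]
  ref8 <- vapply(1:20, function(i)
    mean(vapply(1:20, function(j)
      exp(-sum((P[i, ] - P[j, ])^2) / (2 * h^2)) /
        ((2 * pi)^4 * h^8), 0)), 0)
  expect_equal(unname(as.numeric(d8)), ref8, tolerance = 1e-10)
  expect_error(kdeDensity(X[1, , drop = FALSE]), "2 points")
  # identical points are flagged degenerate
  expect_true(attr(kdeDensity(matrix(1, 5, 2)), "degenerate"))
})

test_that("topDensityFraction picks the ceiling-count top block", {
  d <- c(0.1, 0.9, 0.5, 0.9, 0.2)
  expect_equal(topDensityFraction(d, 0.2), 2L)       # tie -> lower index
  expect_equal(topDensityFraction(d, 0.5), c(2L, 4L, 3L))
  expect_equal(sort(topDensityFraction(d, 1)), 1:5)
  expect_error(topDensityFraction(d, 0), "fraction")
})

test_that("kmeansLatent with k = n gives zero inertia", {
  m <- fxCluxModel()
  pool <- fxSelex()$rounds$R3
  lat <- latentMeans(m, pool@sequences[1:20])
  lat <- lat[!duplicated(unname(as.matrix(lat))), , drop = FALSE][1:6, ]
  cfg <- fxCluxConfig(k_clusters = 6L)
  km <- kmeansLatent(m, lat, cfg)
  expect_equal(sort(km$labels), 1:6)
  expect_equal(km$sizes, rep(1L, 6))
  # every point IS its center: within-cluster sum of squares is zero
  wss <- sum(vapply(1:6, function(cl)
    sum((lat[km$labels == cl, ] - km$centers[cl, ])^2), 0))
  expect_equal(wss, 0, tolerance = 1e-20)
  expect_error(kmeansLatent(m, lat[1:3, ], cfg), "at least k")
  # duplicated points do not count toward k
  latDup <- rbind(lat[1:3, ], lat[1:3, ])
  expect_error(kmeansLatent(m, latDup, cfg), "distinct")
  expect_equal(length(km$centerSequences), 6L)
  expect_true(all(grepl("^[ACGT]+$", km$centerSequences)))
})

test_that("decodeCluxLatent returns sequences and structures", {
  m <- fxCluxModel()
  set.seed(3)
  z <- matrix(rnorm(2 * m@config$latent_dim), 2)
  dec <- decodeCluxLatent(m, z)
  expect_equal(length(dec$sequences), 2L)
  expect_true(all(grepl("^[ACGT]+$", dec$sequences)))
  expect_equal(nchar(dec$structures), nchar(dec$sequences))
  # vector input is treated as one sample
  one <- decodeCluxLatent(m, z[1, ])
  expect_equal(one$sequences, dec$sequences[1])
})

test_that("summarizePool returns both routes with round-coded names", {
  m <- fxCluxModel()
  pool <- fxSelex()$rounds$R5
  cfg <- fxCluxConfig()
  s <- summarizePool(m, pool, cfg)
  expect_named(s$candidates, c("R5HD", "R5CC"))
  expect_equal(unname(s$candidates), c(s$highDensity, s$clusterConsensus))
  expect_true(all(grepl("^[ACGT]+$", s$candidates)))
  expect_equal(length(s$densities), length(pool))
  expect_equal(length(s$logos), cfg$k_clusters)
  expect_equal(names(s$logos), paste0("cluster", seq_len(cfg$k_clusters)))
  # the high-density members really are the top-density sequences
  expect_equal(s$highDensityMembers,
               pool@sequences[topDensityFraction(s$densities,
                                                 cfg$density_fraction)])
  # deterministic under the same config seed
  s2 <- summarizePool(m, pool, cfg)
  expect_identical(s$candidates, s2$candidates)
  expect_identical(s$kmeans$labels, s2$kmeans$labels)
})
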