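## The pool-summarization VAE: a plain encoder/decoder over the
## concatenated sequence + structure one-hot of the unique sequences in an
## enriched SELEX pool, with loss = sequence + structure + KL, and the two
## latent summarization routes: kernel-density peaks and k-means cluster
## centers.

#' Configuration for the pool-summarization VAE
#'
#' @param latent_dim latent dimensionality (default 256).
#' @param hidden encoder/decoder hidden width.
#' @param bandwidth Gaussian KDE bandwidth in latent (PCA-reduced) space
#'   (default 0.5).
#' @param density_fraction fraction of highest-density sequences kept for
#'   the high-density consensus (default 0.01, i.e. the top 1 percent).
#' @param k_clusters number of k-means clusters (default 10).
#' @param kde_pca_dims PCA dimensionality for the KDE evaluation space
#'   (default 8; 0 evaluates in the raw latent space).
#' @param lr,batch_size,epochs,patience,val_fraction,seed,klWarmup,klFreeBits
#'   training controls, as in [aptaVAEConfig()].
#' @param useStructure include the structure branch (ablation toggle).
#' @param minLoop,wobble folding parameters for predicting structures of
#'   pool sequences.
#' @return named configuration list.
#' @export
cluxConfig <- function(latent_dim = 256L, hidden = 64L, bandwidth = 0.5,
                       density_fraction = 0.01, k_clusters = 10L,
                       kde_pca_dims = 8L, lr = 1e-3, batch_size = 64L,
                       epochs = 300L, patience = 30L, val_fraction = 0.1,
                       seed = 1L, klWarmup = 20L, klFreeBits = 0.05,
                       useStructure = TRUE, minLoop = 3L, wobble = FALSE) {
  stopifnot(bandwidth > 0, density_fraction > 0, density_fraction <= 1,
            k_clusters >= 1L)
  list(latent_dim = as.integer(latent_dim), hidden = as.integer(hidden),
       bandwidth = bandwidth, density_fraction = density_fraction,
       k_clusters = as.integer(k_clusters),
       kde_pca_dims = as.integer(kde_pca_dims), lr = lr,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       patience = as.integer(patience), val_fraction = val_fraction,
       seed = as.integer(seed), klWarmup = as.integer(klWarmup),
       klFreeBits = klFreeBits,
       useStructure = isTRUE(useStructure), minLoop = as.integer(minLoop),
       wobble = isTRUE(wobble))
}

## one-hot features of unique pool sequences (+ predicted structures)
.cluxFeatures <- function(seqs, cfg, dims = NULL, structures = NULL) {
  maxLen <- if (is.null(dims)) max(nchar(seqs)) else dims$maxLen
  if (any(nchar(seqs) > maxLen))
    stop("sequence longer than the model's maxLen", call. = FALSE)
  if (is.null(structures))
    structures <- vapply(seqs, foldStructure, "", minLoop = cfg$minLoop,
                         wobble = cfg$wobble, USE.NAMES = FALSE)
  n <- length(seqs)
  Xs <- matrix(0, n, maxLen * 4L)
  Xd <- matrix(0, n, maxLen * 3L)
  for (i in seq_len(n)) {
    enc <- encodeSequence(seqs[i], structures[i], maxLen)
    Xs[i, ] <- as.vector(enc@seqOneHot)
    Xd[i, ] <- as.vector(enc@structOneHot)
  }
  list(Xs = Xs, Xd = Xd, structures = structures,
       dims = list(maxLen = maxLen,
                   decodeLen = as.integer(round(stats::median(nchar(seqs))))))
}

.cluxForward <- function(params, cfg, X, eps = NULL) {
  H <- .relu(.affine(X, params$W1, params$b1))
  Mu <- .affine(H, params$Wm, params$bm)
  Lv <- .affine(H, params$Wv, params$bv)
  LvC <- pmin(pmax(Lv, -8), 8)
  Z <- if (is.null(eps)) Mu else Mu + exp(LvC / 2) * eps
  Hd <- .relu(.affine(Z, params$Wd, params$bd))
  Ps <- .sigmoid(.affine(Hd, params$W_seq, params$b_seq))
  Pd <- if (cfg$useStructure)
    .sigmoid(.affine(Hd, params$W_str, params$b_str)) else NULL
  list(H = H, Mu = Mu, Lv = Lv, LvC = LvC, Z = Z, Hd = Hd, Ps = Ps, Pd = Pd)
}

.cluxLosses <- function(cfg, fw, Xs, Xd) {
  # reconstruction summed over each sample's elements, averaged over the
  # batch, matching the KL convention (per-element means instead let the
  # KL term dominate and collapse the latent)
  B <- nrow(Xs)
  comp <- c(sequence = bceLoss(fw$Ps, Xs) * length(Xs) / B,
            structure = if (cfg$useStructure)
              bceLoss(fw$Pd, Xd) * length(Xd) / B else 0,
            kl = sum(-0.5 * (1 + fw$LvC - fw$Mu^2 - exp(fw$LvC))) / nrow(Xs))
  list(components = comp, total = sum(comp))
}

.cluxStep <- function(params, cfg, Xs, Xd, eps, klw) {
  X <- cbind(Xs, Xd)
  fw <- .cluxForward(params, cfg, X, eps)
  losses <- .cluxLosses(cfg, fw, Xs, Xd)
  B <- nrow(Xs)
  grads <- list()
  dOs <- (fw$Ps - Xs) / B
  grads$W_seq <- crossprod(fw$Hd, dOs); grads$b_seq <- colSums(dOs)
  dHd <- tcrossprod(dOs, params$W_seq)
  if (cfg$useStructure) {
    dOd <- (fw$Pd - Xd) / B
    grads$W_str <- crossprod(fw$Hd, dOd); grads$b_str <- colSums(dOd)
    dHd <- dHd + tcrossprod(dOd, params$W_str)
  }
  dHd <- dHd * (fw$Hd > 0)
  grads$Wd <- crossprod(fw$Z, dHd); grads$bd <- colSums(dHd)
  dZ <- tcrossprod(dHd, params$Wd)
  klDim <- colMeans(0.5 * (fw$Mu^2 + exp(fw$LvC) - 1 - fw$LvC))
  fb <- rep(as.numeric(klDim >= cfg$klFreeBits), each = B)
  dMu <- dZ + klw * fb * fw$Mu / B
  dLv <- dZ * eps * 0.5 * exp(fw$LvC / 2) +
    klw * fb * (exp(fw$LvC) - 1) / 2 / B
  dLv <- dLv * (fw$Lv > -8 & fw$Lv < 8)
  grads$Wm <- crossprod(fw$H, dMu); grads$bm <- colSums(dMu)
  grads$Wv <- crossprod(fw$H, dLv); grads$bv <- colSums(dLv)
  dH <- (tcrossprod(dMu, params$Wm) + tcrossprod(dLv, params$Wv)) * (fw$H > 0)
  grads$W1 <- crossprod(X, dH); grads$b1 <- colSums(dH)
  list(grads = grads, losses = losses)
}

#' Train the pool-summarization VAE on a SELEX pool
#'
#' Deduplicated pool sequences (and their predicted dot-bracket structures)
#' are one-hot encoded and autoencoded through a diagonal-Gaussian latent
#' space with loss = sequence + structure + KL. The checkpoint with the
#' lowest validation loss is returned. Multiple rounds may be passed; their
#' unique sequences are pooled (union mode).
#'
#' @param pool a [PoolRound-class], or a list of them.
#' @param config a [cluxConfig()] list.
#' @param quiet suppress progress messages.
#' @return an [AptaCluxModel-class].
#' @export
trainAptaClux <- function(pool, config = cluxConfig(), quiet = TRUE) {
  if (is(pool, "PoolRound")) pool <- list(pool)
  seqs <- unique(unlist(lapply(pool, function(p) p@sequences)))
  if (length(seqs) < 50L)
    stop("at least 50 unique sequences are required", call. = FALSE)
  cfg <- config
  set.seed(cfg$seed)
  feat <- .cluxFeatures(seqs, cfg)
  din <- ncol(feat$Xs) + ncol(feat$Xd)
  params <- list(W1 = .initW(din, cfg$hidden), b1 = numeric(cfg$hidden),
                 Wm = .initW(cfg$hidden, cfg$latent_dim),
                 bm = numeric(cfg$latent_dim),
                 Wv = .initW(cfg$hidden, cfg$latent_dim),
                 bv = numeric(cfg$latent_dim),
                 Wd = .initW(cfg$latent_dim, cfg$hidden),
                 bd = numeric(cfg$hidden),
                 W_seq = .initW(cfg$hidden, ncol(feat$Xs)),
                 b_seq = numeric(ncol(feat$Xs)))
  if (cfg$useStructure) {
    params$W_str <- .initW(cfg$hidden, ncol(feat$Xd))
    params$b_str <- numeric(ncol(feat$Xd))
  }
  opt <- .adamInit(params)
  n <- length(seqs)
  val <- sort(sample(n, max(1L, round(cfg$val_fraction * n))))
  train <- setdiff(seq_len(n), val)
  best <- list(loss = Inf, params = .deepCopy(params))
  hist <- vector("list", cfg$epochs)
  wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    klw <- if (cfg$klWarmup > 0L) min(1, ep / cfg$klWarmup) else 1
    ord <- sample(train)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    acc <- NULL
    for (bt in batches) {
      eps <- matrix(rnorm(length(bt) * cfg$latent_dim), length(bt))
      st <- .cluxStep(params, cfg, feat$Xs[bt, , drop = FALSE],
                      feat$Xd[bt, , drop = FALSE], eps, klw)
      if (!is.finite(st$losses$total))
        stop("non-finite training loss at epoch ", ep, call. = FALSE)
      upd <- .adamStep(params, st$grads, opt, lr = cfg$lr)
      params <- upd$params; opt <- upd$state
      acc <- if (is.null(acc)) st$losses$components else
        acc + st$losses$components
    }
    comp <- acc / length(batches)
    fwv <- .cluxForward(params, cfg,
                        cbind(feat$Xs[val, , drop = FALSE],
                              feat$Xd[val, , drop = FALSE]))
    valLoss <- .cluxLosses(cfg, fwv, feat$Xs[val, , drop = FALSE],
                           feat$Xd[val, , drop = FALSE])$total
    hist[[ep]] <- c(epoch = ep, comp, total = sum(comp),
                    val_total = valLoss, kl_weight = klw)
    if (valLoss < best$loss) { best <- list(loss = valLoss, params = .deepCopy(params))
      wait <- 0L } else wait <- wait + 1L
    if (!quiet && ep %% 25L == 0L)
      message(sprintf("epoch %d: train %.4f, val %.4f", ep, sum(comp), valLoss))
    if (wait >= cfg$patience) break
  }
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  new("AptaCluxModel", params = best$params, config = cfg,
      dims = feat$dims, history = hist)
}

#' Latent posterior means of pool sequences
#'
#' Deterministic: each unique sequence is encoded to its posterior mean (no
#' sampling). Duplicated input sequences give identical rows.
#'
#' @param model a trained [AptaCluxModel-class].
#' @param pool a [PoolRound-class], list of them, or a character vector of
#'   sequences.
#' @return numeric matrix, one row per sequence, with the sequences as row
#'   names and a \code{provenance} attribute (hash of the latent matrix)
#'   shared by downstream summarization routes.
#' @export
latentMeans <- function(model, pool) {
  seqs <- if (is.character(pool)) pool else {
    if (is(pool, "PoolRound")) pool <- list(pool)
    unlist(lapply(pool, function(p) p@sequences))
  }
  cfg <- model@config
  feat <- .cluxFeatures(seqs, cfg, dims = model@dims)
  fw <- .cluxForward(model@params, cfg, cbind(feat$Xs, feat$Xd))
  M <- fw$Mu
  rownames(M) <- seqs
  attr(M, "provenance") <- sprintf("%.0f", .hash32(paste(
    dim(M)[1], dim(M)[2], sum(M), sep = "|")))
  M
}

#' Gaussian kernel density at each latent point
#'
#' \code{density(i) = mean_j K_h(x_i - x_j)} with an isotropic Gaussian
#' kernel (self-term included). By default the latent matrix is first
#' reduced by PCA to \code{kde_pca_dims} dimensions: a bandwidth of 0.5 in
#' the raw high-dimensional space would make all cross terms vanish
#' numerically. Set \code{pcaDims = 0} to evaluate in the raw space.
#'
#' @param latents numeric matrix (rows = points).
#' @param bandwidth kernel bandwidth h (default 0.5).
#' @param pcaDims PCA reduction before evaluation (default 8; 0 = none).
#' @return numeric density vector, one value per row; a \code{degenerate}
#'   attribute flags the all-identical-points case.
#' @export
kdeDensity <- function(latents, bandwidth = 0.5, pcaDims = 8L) {
  X <- as.matrix(latents)
  if (nrow(X) < 2L) stop("need at least 2 points", call. = FALSE)
  degenerate <- all(apply(X, 2L, stats::sd) == 0)
  if (!degenerate && pcaDims > 0L && ncol(X) > pcaDims) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    X <- pc$x[, seq_len(min(pcaDims, ncol(pc$x))), drop = FALSE]
  }
  d <- ncol(X); n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  Kmat <- exp(-D2 / (2 * bandwidth^2)) / ((2 * pi)^(d / 2) * bandwidth^d)
  dens <- rowMeans(Kmat)
  attr(dens, "degenerate") <- degenerate
  dens
}

#' Indices of the highest-density fraction
#'
#' Selects \code{ceiling(fraction * n)} points of highest density; ties
#' break toward the lower index.
#'
#' @param densities numeric vector.
#' @param fraction fraction in (0, 1] (default 0.01).
#' @return integer indices, in decreasing density order.
#' @export
topDensityFraction <- function(densities, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(densities))
  order(-densities, seq_along(densities))[seq_len(k)]
}

#' K-means over latent means, with decoded cluster centers
#'
#' Seeded k-means++ initialization followed by Lloyd iterations
#' (\code{stats::kmeans}, up to 300 iterations); the cluster centers are
#' pushed through the decoder and read off as sequences.
#'
#' @param model a trained [AptaCluxModel-class].
#' @param latents latent matrix from [latentMeans()].
#' @param config a [cluxConfig()] list (uses \code{k_clusters} and
#'   \code{seed}).
#' @return list with \code{labels}, \code{centers} (k x dim matrix),
#'   \code{centerSequences} (decoded strings) and \code{sizes}.
#' @export
kmeansLatent <- function(model, latents, config = cluxConfig()) {
  # force arguments before seeding: lazily evaluated expressions could
  # otherwise consume the stream after set.seed
  force(model)
  X <- as.matrix(latents)
  k <- config$k_clusters
  if (nrow(X) < k)
    stop("need at least k = ", k, " points, got ", nrow(X), call. = FALSE)
  if (nrow(unique(X)) < k)
    stop("need at least k = ", k, " distinct points, got ",
         nrow(unique(X)), " (collapsed latents)", call. = FALSE)
  set.seed(config$seed)
  # k-means++ seeding; duplicate points have squared distance 0 to an
  # already-chosen center and so are never re-drawn
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample(nrow(X), 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(X, 1L, function(x)
      min(colSums((t(centers[seq_len(j - 1L), , drop = FALSE]) - x)^2)))
    centers[j, ] <- X[sample(nrow(X), 1L, prob = d2 / sum(d2)), ]
  }
  km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 300L,
                                       algorithm = "Lloyd"))
  list(labels = unname(km$cluster), centers = km$centers,
       centerSequences = decodeCluxLatent(model, km$centers)$sequences,
       sizes = unname(km$size))
}

#' Decode pool-model latent vectors to sequences (and structures)
#'
#' @param model a trained [AptaCluxModel-class].
#' @param z latent vector or matrix (rows = samples).
#' @return list with \code{sequences} and \code{structures} (argmax
#'   dot-bracket read-out of the structure head, possibly unbalanced).
#' @export
decodeCluxLatent <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  p <- model@params; cfg <- model@config
  Hd <- .relu(.affine(z, p$Wd, p$bd))
  Ps <- .sigmoid(.affine(Hd, p$W_seq, p$b_seq))
  maxLen <- model@dims$maxLen; Lfall <- model@dims$decodeLen
  n <- nrow(z)
  seqs <- character(n); strs <- character(n)
  Pd <- if (cfg$useStructure) .sigmoid(.affine(Hd, p$W_str, p$b_str)) else NULL
  for (i in seq_len(n)) {
    Pm <- matrix(Ps[i, ], maxLen, 4)
    L <- .occupiedLength(Pm, Lfall)
    seqs[i] <- decodeOneHot(Pm[seq_len(L), , drop = FALSE])
    strs[i] <- if (!is.null(Pd))
      decodeOneHotStructure(matrix(Pd[i, ], maxLen, 3)[seq_len(L), ,
                                                       drop = FALSE])
      else NA_character_
  }
  list(sequences = seqs, structures = strs)
}

#' Summarize an enriched pool into consensus aptamer candidates
#'
#' Runs both latent summarization routes on one latent matrix: (i) the
#' high-density route (Gaussian KDE, top \code{density_fraction}, multiple
#' alignment, consensus) and (ii) the cluster route (k-means, decoded
#' centers, alignment, consensus). Candidate names encode round and route,
#' e.g. \code{R3HD} and \code{R3CC}.
#'
#' @param model a trained [AptaCluxModel-class].
#' @param pool the [PoolRound-class] (or list) to summarize.
#' @param config a [cluxConfig()] list.
#' @return list with \code{highDensity} and \code{clusterConsensus}
#'   candidate sequences, \code{names}, \code{densities}, \code{kmeans},
#'   \code{latents} and per-cluster \code{logos} (count matrices).
#' @export
summarizePool <- function(model, pool, config = cluxConfig()) {
  lat <- latentMeans(model, pool)
  rid <- if (is(pool, "PoolRound")) pool@roundId else
    if (is.list(pool) && all(vapply(pool, is, TRUE, "PoolRound")))
      paste(vapply(pool, function(p) p@roundId, integer(1)), collapse = "")
    else NA
  dens <- kdeDensity(lat, bandwidth = config$bandwidth,
                     pcaDims = config$kde_pca_dims)
  hdIdx <- topDensityFraction(dens, config$density_fraction)
  hdSeqs <- rownames(lat)[hdIdx]
  hd <- candidateConsensus(hdSeqs)
  km <- kmeansLatent(model, lat, config)
  cc <- candidateConsensus(km$centerSequences)
  logos <- lapply(seq_len(config$k_clusters), function(cl) {
    members <- rownames(lat)[km$labels == cl]
    if (length(members)) sequenceLogoCounts(members) else NULL
  })
  names(logos) <- paste0("cluster", seq_len(config$k_clusters))
  list(highDensity = hd, clusterConsensus = cc,
       candidates = stats::setNames(c(hd, cc),
                                    paste0("R", rid, c("HD", "CC"))),
       densities = dens, highDensityMembers = hdSeqs, kmeans = km,
       latents = lat, logos = logos,
       provenance = attr(lat, "provenance"))
}
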