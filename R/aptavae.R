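## The guided-library VAE: separate 1D and 3D encoder branches plus a
## co-attention context, a diagonal-Gaussian latent space, and a decoder
## with skip connections reconstructing every input facet (sequence one-hot,
## target fingerprint, class, score, attention context and the three
## sandwich slabs). Trained by Adam on the composite loss; the checkpoint
## with the lowest validation loss is returned.

#' Training configuration for the guided-library VAE
#'
#' @param latent_dim latent dimensionality (default 256).
#' @param hidden1d,hidden3d encoder branch widths for the 1D stream and the
#'   flattened sandwich tensor.
#' @param hiddenDec decoder hidden width.
#' @param attentionDim co-attention projection dimension.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs; training stops early after \code{patience}
#'   epochs without validation improvement.
#' @param patience early-stopping patience.
#' @param val_fraction stratified validation fraction (by class).
#' @param seed master seed for initialization, shuffling, reparameterization
#'   noise and the split.
#' @param klWarmup epochs over which the KL weight ramps linearly from 0 to
#'   1 (posterior-collapse guard; the logged breakdown always reports the
#'   full KL).
#' @param klFreeBits free-bits floor in nats per latent dimension: the KL
#'   gradient is switched off for dimensions whose batch-mean KL is below
#'   this floor, so the latent can store information "for free" instead of
#'   collapsing to the prior (the mean-normalized reconstruction terms are
#'   otherwise orders of magnitude weaker than a 256-dimensional summed
#'   KL). The logged KL component is always the full closed form.
#' @param skipDropout probability of zeroing the skip input per sample
#'   during training, so the decoder also learns to work from the latent
#'   alone (as it must when sampling from the prior).
#' @param use3d,useSkip,useAttention ablation toggles: the sandwich branch
#'   (with its matrix heads), the encoder-to-decoder skip connection, and
#'   the co-attention context.
#' @param weights a [lossWeights()] list.
#' @param minLoop,wobble folding parameters used when structures must be
#'   predicted.
#' @return named configuration list.
#' @export
aptaVAEConfig <- function(latent_dim = 256L, hidden1d = 64L, hidden3d = 32L,
                          hiddenDec = 128L, attentionDim = 64L, lr = 1e-3,
                          batch_size = 16L, epochs = 500L, patience = 50L,
                          val_fraction = 0.2, seed = 1L, klWarmup = 30L,
                          klFreeBits = 0.05, skipDropout = 0.5, use3d = TRUE,
                          useSkip = TRUE, useAttention = TRUE,
                          weights = lossWeights(), minLoop = 3L,
                          wobble = FALSE) {
  stopifnot(latent_dim >= 1L, batch_size >= 1L, epochs >= 1L,
            val_fraction > 0, val_fraction < 1, klFreeBits >= 0)
  list(latent_dim = as.integer(latent_dim), hidden1d = as.integer(hidden1d),
       hidden3d = as.integer(hidden3d), hiddenDec = as.integer(hiddenDec),
       attentionDim = as.integer(attentionDim), lr = lr,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       patience = as.integer(patience), val_fraction = val_fraction,
       seed = as.integer(seed), klWarmup = as.integer(klWarmup),
       klFreeBits = klFreeBits,
       skipDropout = skipDropout, use3d = isTRUE(use3d),
       useSkip = isTRUE(useSkip), useAttention = isTRUE(useAttention),
       weights = weights, minLoop = as.integer(minLoop),
       wobble = isTRUE(wobble))
}

## ---- feature construction ----

## Build the per-pair input matrices. Returns X1 (1D stream), the three
## slab matrices, XA (pooled co-attention context), plus layout metadata.
.aptavaeFeatures <- function(ats, cfg, dims = NULL) {
  n <- length(ats)
  seqs <- ats@sequences; dbs <- ats@structures
  K <- length(ats@targets)
  nBits <- length(ats@targets[[1]]$fingerprint)
  if (is.null(dims)) {
    maxLen <- max(nchar(seqs))
    nAtoms <- max(vapply(ats@targets, function(t) t$nAtoms, integer(1)))
    S <- max(maxLen, nAtoms, 3L)
    dmax <- max(vapply(ats@targets, function(t) max(t$distance), numeric(1)), 1)
  } else {
    maxLen <- dims$maxLen; S <- dims$S; dmax <- dims$dmax
    if (any(nchar(seqs) > maxLen))
      stop("sequence longer than the model's maxLen", call. = FALSE)
  }
  d1 <- maxLen * 4L + nBits + K + 1L
  X1 <- matrix(0, n, d1)
  Xdist <- matrix(0, n, S * S); Xstr <- matrix(0, n, S * S)
  Xadj <- matrix(0, n, S * S)
  XA <- matrix(0, n, cfg$attentionDim)
  tgtEmb <- lapply(ats@targets, function(t)
    hashEmbed(smilesTokenize(t$smiles), d = cfg$attentionDim, seed = cfg$seed))
  for (i in seq_len(n)) {
    enc <- encodeSequence(seqs[i], dbs[i], maxLen)
    tgt <- ats@targets[[ats@classLabels[i]]]
    clsOH <- numeric(K); clsOH[ats@classLabels[i]] <- 1
    X1[i, ] <- c(as.vector(enc@seqOneHot), tgt$fingerprint, clsOH,
                 ats@scores[i])
    sw <- buildSandwich(enc, tgt$adjacency, tgt$distance / dmax, S)
    Xdist[i, ] <- as.vector(sw[1, , ])
    Xstr[i, ] <- as.vector(sw[2, , ])
    Xadj[i, ] <- as.vector(sw[3, , ])
    if (cfg$useAttention) {
      sEmb <- hashEmbed(kmerTokenize(seqs[i], min(6L, nchar(seqs[i]))),
                        d = cfg$attentionDim, seed = cfg$seed)
      XA[i, ] <- coAttend(tgtEmb[[ats@classLabels[i]]], sEmb,
                          d = cfg$attentionDim, seed = cfg$seed)$pooled
    }
  }
  cols <- list(seq = seq_len(maxLen * 4L),
               fp = maxLen * 4L + seq_len(nBits),
               cls = maxLen * 4L + nBits + seq_len(K),
               score = d1)
  list(X1 = X1, Xdist = Xdist, Xstr = Xstr, Xadj = Xadj, XA = XA,
       cols = cols,
       dims = list(maxLen = maxLen, S = S, dmax = dmax, d1 = d1,
                   d3 = 3L * S * S, nBits = nBits, K = K,
                   decodeLen = as.integer(round(stats::median(nchar(seqs))))))
}

## head table for the current configuration
.aptavaeHeads <- function(cfg, cols, S) {
  w <- cfg$weights
  heads <- list(
    list(name = "seq", act = "sig", loss = "bce", wt = 1, comp = "sequence"),
    list(name = "fp", act = "sig", loss = "bce", wt = 1, comp = "target"),
    list(name = "cls", act = "sig", loss = "bce", wt = 1, comp = "class"),
    # the score head is linear (MSE on the raw output, clipped to [0, 1]
    # only at decode time): a sigmoid head shrinks high scores toward the
    # middle because its gradient vanishes near saturation, which starves
    # prior-sample retention above high thresholds
    list(name = "score", act = "lin", loss = "mse", wt = w$scoreMultiplier,
         comp = "score"))
  if (cfg$useAttention)
    heads <- c(heads, list(list(name = "att", act = "lin", loss = "mse",
                                wt = 1, comp = "attention")))
  if (cfg$use3d)
    heads <- c(heads, list(
      list(name = "dist", act = "lin", loss = "mse", wt = w$alpha,
           comp = "mat_distance"),
      list(name = "str", act = "sig", loss = "bce", wt = w$beta,
           comp = "mat_structure"),
      list(name = "adj", act = "sig", loss = "bce",
           wt = 1 - w$alpha - w$beta, comp = "mat_adjacency")))
  heads
}

.aptavaeHeadDims <- function(cfg, feat) {
  d <- list(seq = length(feat$cols$seq), fp = length(feat$cols$fp),
            cls = length(feat$cols$cls), score = 1L)
  if (cfg$useAttention) d$att <- cfg$attentionDim
  if (cfg$use3d) {
    ss <- ncol(feat$Xdist)
    d$dist <- ss; d$str <- ss; d$adj <- ss
  }
  d
}

.aptavaeInitParams <- function(cfg, feat) {
  d1 <- ncol(feat$X1); d3 <- 3L * ncol(feat$Xdist)
  He <- cfg$hidden1d + if (cfg$use3d) cfg$hidden3d else 0L
  He <- He + if (cfg$useAttention) cfg$attentionDim else 0L
  Di <- cfg$latent_dim + if (cfg$useSkip) He else 0L
  p <- list(W1 = .initW(d1, cfg$hidden1d), b1 = numeric(cfg$hidden1d),
            Wm = .initW(He, cfg$latent_dim), bm = numeric(cfg$latent_dim),
            Wv = .initW(He, cfg$latent_dim), bv = numeric(cfg$latent_dim),
            Wd = .initW(Di, cfg$hiddenDec), bd = numeric(cfg$hiddenDec))
  if (cfg$use3d) {
    p$W3 <- .initW(d3, cfg$hidden3d); p$b3 <- numeric(cfg$hidden3d)
  }
  for (h in .aptavaeHeads(cfg, feat$cols, NA)) {
    hd <- .aptavaeHeadDims(cfg, feat)[[h$name]]
    p[[paste0("W_", h$name)]] <- .initW(cfg$hiddenDec, hd)
    p[[paste0("b_", h$name)]] <- numeric(hd)
  }
  p
}

## encoder forward for a row subset
.aptavaeEncode <- function(params, cfg, feat, idx) {
  X1 <- feat$X1[idx, , drop = FALSE]
  H1 <- .relu(.affine(X1, params$W1, params$b1))
  He <- H1
  if (cfg$use3d) {
    X3 <- cbind(feat$Xdist[idx, , drop = FALSE], feat$Xstr[idx, , drop = FALSE],
                feat$Xadj[idx, , drop = FALSE])
    H3 <- .relu(.affine(X3, params$W3, params$b3))
    He <- cbind(He, H3)
  } else { X3 <- NULL; H3 <- NULL }
  if (cfg$useAttention) He <- cbind(He, feat$XA[idx, , drop = FALSE])
  Mu <- .affine(He, params$Wm, params$bm)
  Lv <- .affine(He, params$Wv, params$bv)
  LvC <- pmin(pmax(Lv, -8), 8)
  list(X1 = X1, X3 = X3, H1 = H1, H3 = H3, He = He, Mu = Mu, Lv = Lv,
       LvC = LvC)
}

## decoder forward from latent Z (+ optional skip features)
.aptavaeDecode <- function(params, cfg, Z, skip = NULL, headNames = NULL) {
  Din <- Z
  if (cfg$useSkip) {
    if (is.null(skip)) skip <- matrix(0, nrow(Z), nrow(params$Wd) - ncol(Z))
    Din <- cbind(Z, skip)
  }
  Hd <- .relu(.affine(Din, params$Wd, params$bd))
  allNames <- sub("^W_", "", grep("^W_", names(params), value = TRUE))
  if (is.null(headNames)) headNames <- allNames
  O <- list(); P <- list()
  for (nm in headNames) {
    O[[nm]] <- .affine(Hd, params[[paste0("W_", nm)]], params[[paste0("b_", nm)]])
    P[[nm]] <- if (nm %in% c("att", "dist", "score")) O[[nm]] else
      .sigmoid(O[[nm]])
  }
  list(Din = Din, Hd = Hd, O = O, P = P)
}

## per-head reconstruction targets for a row subset
.aptavaeTargets <- function(cfg, feat, idx) {
  y <- list(seq = feat$X1[idx, feat$cols$seq, drop = FALSE],
            fp = feat$X1[idx, feat$cols$fp, drop = FALSE],
            cls = feat$X1[idx, feat$cols$cls, drop = FALSE],
            score = feat$X1[idx, feat$cols$score, drop = FALSE])
  if (cfg$useAttention) y$att <- feat$XA[idx, , drop = FALSE]
  if (cfg$use3d) {
    y$dist <- feat$Xdist[idx, , drop = FALSE]
    y$str <- feat$Xstr[idx, , drop = FALSE]
    y$adj <- feat$Xadj[idx, , drop = FALSE]
  }
  y
}

## loss breakdown (full Eq-style arithmetic) from head outputs + latent
.aptavaeLosses <- function(cfg, P, Y, Mu, LvC) {
  w <- cfg$weights
  B <- nrow(Mu)
  # reconstruction terms are summed over each sample's elements and averaged
  # over the batch, matching the KL convention (summed over latent
  # dimensions, averaged over the batch); with per-element means instead,
  # the KL term dominates by orders of magnitude and the latent collapses
  ps <- function(loss, x) loss * length(x) / B
  comp <- c(sequence = ps(bceLoss(P$seq, Y$seq), P$seq),
            target = ps(bceLoss(P$fp, Y$fp), P$fp),
            class = ps(bceLoss(P$cls, Y$cls), P$cls),
            score = ps(mseLoss(P$score, Y$score), P$score),
            attention = if (cfg$useAttention)
              ps(mseLoss(P$att, Y$att), P$att) else 0,
            matrix = if (cfg$use3d)
              matrixLoss(ps(mseLoss(P$dist, Y$dist), P$dist),
                         ps(bceLoss(P$str, Y$str), P$str),
                         ps(bceLoss(P$adj, Y$adj), P$adj), w) else 0,
            kl = sum(-0.5 * (1 + LvC - Mu^2 - exp(LvC))) / nrow(Mu))
  total <- compositeLoss(comp[["sequence"]], comp[["target"]], comp[["class"]],
                         comp[["score"]], comp[["attention"]], comp[["matrix"]],
                         comp[["kl"]], w)
  list(components = comp, total = as.numeric(total))
}

## one training step: forward, analytic backward, returns grads + breakdown
.aptavaeStep <- function(params, cfg, feat, idx, eps, skipmask, klw) {
  enc <- .aptavaeEncode(params, cfg, feat, idx)
  B <- length(idx)
  Z <- enc$Mu + exp(enc$LvC / 2) * eps
  skip <- if (cfg$useSkip) enc$He * skipmask else NULL
  dec <- .aptavaeDecode(params, cfg, Z, skip)
  Y <- .aptavaeTargets(cfg, feat, idx)
  losses <- .aptavaeLosses(cfg, dec$P, Y, enc$Mu, enc$LvC)

  heads <- .aptavaeHeads(cfg, feat$cols, NA)
  grads <- list()
  dHd <- matrix(0, B, cfg$hiddenDec)
  for (h in heads) {
    nm <- h$name
    P <- dec$P[[nm]]; Yk <- Y[[nm]]
    N <- length(P)
    dO <- if (h$loss == "bce") (P - Yk) * h$wt / B
          else if (h$act == "sig") 2 * (P - Yk) * P * (1 - P) * h$wt / B
          else 2 * (P - Yk) * h$wt / B
    grads[[paste0("W_", nm)]] <- crossprod(dec$Hd, dO)
    grads[[paste0("b_", nm)]] <- colSums(dO)
    dHd <- dHd + tcrossprod(dO, params[[paste0("W_", nm)]])
  }
  dHd <- dHd * (dec$Hd > 0)
  grads$Wd <- crossprod(dec$Din, dHd)
  grads$bd <- colSums(dHd)
  dDin <- tcrossprod(dHd, params$Wd)
  z <- cfg$latent_dim
  dZ <- dDin[, seq_len(z), drop = FALSE]
  dHe_skip <- if (cfg$useSkip)
    dDin[, -seq_len(z), drop = FALSE] * skipmask else 0
  # KL gradients (annealed by klw; free-bits floor masks the KL pull on
  # dimensions whose batch-mean KL is under cfg$klFreeBits)
  klDim <- colMeans(0.5 * (enc$Mu^2 + exp(enc$LvC) - 1 - enc$LvC))
  fb <- rep(as.numeric(klDim >= cfg$klFreeBits), each = B)
  dMu <- dZ + klw * fb * enc$Mu / B
  dLv <- dZ * eps * 0.5 * exp(enc$LvC / 2) +
    klw * fb * (exp(enc$LvC) - 1) / 2 / B
  dLv <- dLv * (enc$Lv > -8 & enc$Lv < 8)
  grads$Wm <- crossprod(enc$He, dMu); grads$bm <- colSums(dMu)
  grads$Wv <- crossprod(enc$He, dLv); grads$bv <- colSums(dLv)
  dHe <- tcrossprod(dMu, params$Wm) + tcrossprod(dLv, params$Wv) + dHe_skip
  h1 <- cfg$hidden1d
  dH1 <- dHe[, seq_len(h1), drop = FALSE] * (enc$H1 > 0)
  grads$W1 <- crossprod(enc$X1, dH1); grads$b1 <- colSums(dH1)
  if (cfg$use3d) {
    dH3 <- dHe[, h1 + seq_len(cfg$hidden3d), drop = FALSE] * (enc$H3 > 0)
    grads$W3 <- crossprod(enc$X3, dH3); grads$b3 <- colSums(dH3)
  }
  list(grads = grads, losses = losses)
}

## deterministic evaluation pass (eps = 0, skip fully on)
.aptavaeEval <- function(params, cfg, feat, idx) {
  enc <- .aptavaeEncode(params, cfg, feat, idx)
  skip <- if (cfg$useSkip) enc$He else NULL
  dec <- .aptavaeDecode(params, cfg, enc$Mu, skip)
  .aptavaeLosses(cfg, dec$P, .aptavaeTargets(cfg, feat, idx), enc$Mu, enc$LvC)
}

#' Train the guided-library VAE on aptamer-target pairs
#'
#' Encodes every pair into the 1D stream (sequence one-hot, target
#' fingerprint, class one-hot, score), the flattened sandwich tensor and the
#' pooled co-attention context; trains encoder/decoder by Adam on the
#' composite loss; and returns the parameters from the epoch with the lowest
#' validation loss, together with the full per-epoch loss breakdown.
#'
#' @param pairs an [AptamerTargetSet-class] with at least 20 pairs spanning
#'   at least 2 classes.
#' @param config an [aptaVAEConfig()] list.
#' @param quiet suppress progress messages.
#' @return an [AptaVAEModel-class].
#' @export
trainAptaVAE <- function(pairs, config = aptaVAEConfig(), quiet = TRUE) {
  stopifnot(is(pairs, "AptamerTargetSet"))
  if (length(pairs) < 20L)
    stop("at least 20 training pairs are required", call. = FALSE)
  if (length(unique(pairs@classLabels)) < 2L)
    stop("at least 2 classes are required", call. = FALSE)
  cfg <- config
  set.seed(cfg$seed)
  feat <- .aptavaeFeatures(pairs, cfg)
  params <- .aptavaeInitParams(cfg, feat)
  opt <- .adamInit(params)
  n <- length(pairs)
  val <- .stratifiedVal(pairs@classLabels, cfg$val_fraction)
  train <- setdiff(seq_len(n), val)
  best <- list(loss = Inf, params = .deepCopy(params), epoch = 0L)
  hist <- vector("list", cfg$epochs)
  wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    klw <- if (cfg$klWarmup > 0L) min(1, ep / cfg$klWarmup) else 1
    ord <- sample(train)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    acc <- NULL
    heWidth <- cfg$hidden1d + (if (cfg$use3d) cfg$hidden3d else 0L) +
      (if (cfg$useAttention) cfg$attentionDim else 0L)
    for (bt in batches) {
      eps <- matrix(rnorm(length(bt) * cfg$latent_dim), length(bt))
      skipmask <- matrix(stats::rbinom(length(bt), 1L, 1 - cfg$skipDropout),
                         length(bt), heWidth)
      st <- .aptavaeStep(params, cfg, feat, bt, eps, skipmask, klw)
      if (!is.finite(st$losses$total))
        stop("non-finite training loss at epoch ", ep,
             "; components: ",
             paste(sprintf("%s=%.3g", names(st$losses$components),
                           st$losses$components), collapse = ", "),
             call. = FALSE)
      upd <- .adamStep(params, st$grads, opt, lr = cfg$lr)
      params <- upd$params; opt <- upd$state
      acc <- if (is.null(acc)) st$losses$components else
        acc + st$losses$components
    }
    comp <- acc / length(batches)
    valLoss <- .aptavaeEval(params, cfg, feat, val)$total
    hist[[ep]] <- c(epoch = ep, comp,
                    total = as.numeric(compositeLoss(
                      comp[["sequence"]], comp[["target"]], comp[["class"]],
                      comp[["score"]], comp[["attention"]], comp[["matrix"]],
                      comp[["kl"]], cfg$weights)),
                    val_total = valLoss, kl_weight = klw)
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, params = .deepCopy(params), epoch = ep)
      wait <- 0L
    } else wait <- wait + 1L
    if (!quiet && ep %% 25L == 0L)
      message(sprintf("epoch %d: train %.4f, val %.4f", ep,
                      hist[[ep]][["total"]], valLoss))
    if (wait >= cfg$patience) break
  }
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  new("AptaVAEModel", params = best$params, config = cfg, dims = feat$dims,
      history = hist, targets = pairs@targets)
}

#' Encode one training pair into its latent posterior
#'
#' Deterministic: returns the posterior mean and log-variance (no sampling).
#'
#' @param model a trained [AptaVAEModel-class].
#' @param pairs the [AptamerTargetSet-class] the pair lives in.
#' @param i pair index (default 1).
#' @return a [LatentDistribution-class].
#' @export
encodePair <- function(model, pairs, i = 1L) {
  feat <- .aptavaeFeatures(pairs, model@config, dims = model@dims)
  enc <- .aptavaeEncode(model@params, model@config, feat, i)
  new("LatentDistribution", mu = as.numeric(enc$Mu[1, ]),
      logvar = as.numeric(enc$LvC[1, ]))
}

## internal batch encoder: returns mu / logvar matrices for all pairs
.encodePairs <- function(model, pairs) {
  feat <- .aptavaeFeatures(pairs, model@config, dims = model@dims)
  enc <- .aptavaeEncode(model@params, model@config, feat, seq_len(length(pairs)))
  list(mu = enc$Mu, logvar = enc$LvC)
}

#' Decode latent vectors into a reconstruction bundle
#'
#' Deterministic given z: the decoder runs with the skip input zeroed (no
#' encoder features exist for a free latent sample). Sequences are read off
#' the sequence head by per-position argmax over the occupied positions:
#' a position counts as padding only when its maximum base probability
#' falls clearly below the sequence's own signal level (an absolute 0.5
#' cut would truncate out-of-distribution prior samples, whose
#' probabilities are globally damped, at arbitrary lengths). Decoding
#' falls back to the training median length if nothing is occupied.
#'
#' @param model a trained [AptaVAEModel-class].
#' @param z numeric vector (one latent) or matrix (one row per latent).
#' @param detail also return fingerprint, attention and matrix heads.
#' @return list with \code{sequences}, \code{scores} (in [0,1]),
#'   \code{classes}, \code{classProbs}; plus head matrices when
#'   \code{detail = TRUE}.
#' @export
decodeLatent <- function(model, z, detail = FALSE) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  cfg <- model@config
  stopifnot(ncol(z) == cfg$latent_dim)
  want <- c("seq", "score", "cls")
  if (detail) want <- NULL
  dec <- .aptavaeDecode(model@params, cfg, z, skip = NULL, headNames = want)
  n <- nrow(z)
  maxLen <- model@dims$maxLen
  seqs <- character(n); Lfall <- model@dims$decodeLen
  for (i in seq_len(n)) {
    Pm <- matrix(dec$P$seq[i, ], maxLen, 4)
    seqs[i] <- decodeOneHot(Pm[seq_len(.occupiedLength(Pm, Lfall)), ,
                               drop = FALSE])
  }
  clsP <- dec$P$cls
  out <- list(sequences = seqs,
              scores = pmin(pmax(as.numeric(dec$P$score), 0), 1),
              classes = apply(clsP, 1L, which.max), classProbs = clsP)
  if (detail) {
    out$fingerprint <- dec$P$fp
    if (cfg$useAttention) out$attention <- dec$P$att
    if (cfg$use3d) {
      S <- model@dims$S
      out$distance <- lapply(seq_len(n), function(i)
        matrix(dec$P$dist[i, ], S, S) * model@dims$dmax)
      out$structureSlab <- lapply(seq_len(n), function(i)
        matrix(dec$P$str[i, ], S, S))
      out$adjacency <- lapply(seq_len(n), function(i)
        matrix(dec$P$adj[i, ], S, S))
    }
  }
  out
}
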