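## Batch-generated analysis: repeated latent sampling from the prior with
## running statistics (mean score, SD, fraction above the score threshold)
## to decide when generation has stabilized, plus class-wise grouping of the
## retained high-scoring sequences.

#' Configuration for batch-generated analysis
#'
#' @param batch_size latent samples per batch.
#' @param n_batches number of batches.
#' @param threshold score threshold (default 0.9); sequences whose decoded
#'   score exceeds it are retained for library design.
#' @param convergence_tolerance relative-change tolerance for the running
#'   statistics (default 0.01).
#' @param convergence_window number of trailing batches over which the
#'   relative changes are examined (default 5).
#' @param seed RNG seed for the prior draws.
#' @return named configuration list.
#' @export
bgaConfig <- function(batch_size = 128L, n_batches = 50L, threshold = 0.9,
                      convergence_tolerance = 0.01, convergence_window = 5L,
                      seed = 1L) {
  stopifnot(batch_size >= 1L, n_batches >= 1L,
            threshold > 0, threshold < 1)
  list(batch_size = as.integer(batch_size), n_batches = as.integer(n_batches),
       threshold = threshold, convergence_tolerance = convergence_tolerance,
       convergence_window = as.integer(convergence_window),
       seed = as.integer(seed))
}

#' Sample the latent prior in batches and accumulate generation statistics
#'
#' Draws \code{n_batches x batch_size} latent vectors from the standard
#' normal prior, decodes each batch, and records per-batch and cumulative
#' running statistics of the decoded scores. Sequences whose score exceeds
#' the threshold are retained (with their predicted class) as the
#' high-scoring set for guided-library design.
#'
#' @param model a trained [AptaVAEModel-class].
#' @param config a [bgaConfig()] list.
#' @return list with \code{retained} (data.frame: sequence, score, class,
#'   batch), \code{stats} (data.frame per batch: mean, sd, prop and their
#'   cumulative versions), \code{status} (\code{"ok"} or \code{"empty"} when
#'   nothing exceeded the threshold), and \code{scores} (all decoded
#'   scores, for auditing).
#' @export
bgaSample <- function(model, config = bgaConfig()) {
  # force arguments before seeding: a lazily evaluated model expression
  # could otherwise consume the stream after set.seed
  z <- model@config$latent_dim
  cfg <- config
  set.seed(cfg$seed)
  allScores <- numeric(0)
  keep <- list()
  stats <- matrix(NA_real_, cfg$n_batches, 6,
                  dimnames = list(NULL, c("mean", "sd", "prop",
                                          "cum_mean", "cum_sd", "cum_prop")))
  for (b in seq_len(cfg$n_batches)) {
    Z <- matrix(rnorm(cfg$batch_size * z), cfg$batch_size, z)
    dec <- decodeLatent(model, Z)
    sc <- dec$scores
    allScores <- c(allScores, sc)
    hit <- sc > cfg$threshold
    if (any(hit))
      keep[[length(keep) + 1L]] <- data.frame(
        sequence = dec$sequences[hit], score = sc[hit],
        class = dec$classes[hit], batch = b, stringsAsFactors = FALSE)
    stats[b, ] <- c(mean(sc), stats::sd(sc), mean(hit),
                    mean(allScores), stats::sd(allScores),
                    mean(allScores > cfg$threshold))
  }
  retained <- if (length(keep)) do.call(rbind, keep) else
    data.frame(sequence = character(0), score = numeric(0),
               class = integer(0), batch = integer(0))
  list(retained = retained,
       stats = data.frame(batch = seq_len(cfg$n_batches), stats),
       status = if (nrow(retained)) "ok" else "empty",
       scores = allScores)
}

#' Has batch-generated analysis reached a steady state?
#'
#' TRUE iff, over the trailing \code{convergence_window} batches, the
#' batch-to-batch relative change of each cumulative statistic (running
#' mean, SD and above-threshold proportion) stays below
#' \code{convergence_tolerance}.
#'
#' @param stats the \code{stats} data.frame from [bgaSample()].
#' @param config a [bgaConfig()] list.
#' @return logical.
#' @export
bgaConverged <- function(stats, config = bgaConfig()) {
  w <- config$convergence_window
  if (nrow(stats) < w) return(FALSE)
  tailRows <- stats[seq(nrow(stats) - w + 1L, nrow(stats)), , drop = FALSE]
  ok <- vapply(c("cum_mean", "cum_sd", "cum_prop"), function(cn) {
    v <- tailRows[[cn]]
    rel <- abs(diff(v)) / pmax(abs(v[-length(v)]), 1e-12)
    all(rel < config$convergence_tolerance)
  }, logical(1))
  all(ok)
}

#' Group sequences by class and sort by descending score
#'
#' Stable sort; score ties break by sequence lexicographic order.
#'
#' @param sequences character vector.
#' @param classes integer class labels, values in \code{1..nClasses}.
#' @param scores numeric scores.
#' @param nClasses total number of classes (default \code{max(classes)}).
#' @return named list (one element per class \code{"1".."nClasses"}) of
#'   data.frames with columns \code{sequence}, \code{score}, descending.
#' @export
groupAndSort <- function(sequences, classes, scores,
                         nClasses = max(classes)) {
  stopifnot(length(sequences) == length(classes),
            length(sequences) == length(scores))
  if (length(classes) && (any(classes < 1L) || any(classes > nClasses)))
    stop("unknown class id: ",
         paste(unique(classes[classes < 1L | classes > nClasses]),
               collapse = ", "), call. = FALSE)
  out <- setNames(vector("list", nClasses), as.character(seq_len(nClasses)))
  for (cl in seq_len(nClasses)) {
    idx <- which(classes == cl)
    idx <- idx[order(-scores[idx], sequences[idx])]
    out[[cl]] <- data.frame(sequence = sequences[idx], score = scores[idx],
                            stringsAsFactors = FALSE)
  }
  out
}

#' Assign generated sequences to classes by nearest training neighbors
#'
#' Majority vote over the \code{k} training sequences closest in edit
#' distance. The decoder's class head scores a latent, not the emitted
#' sequence, and on prior samples the two can disagree; anchoring the
#' assignment to the training set keeps the per-class groups pure enough
#' for consensus templating. Vote ties break toward the class holding the
#' single nearest neighbor among the tied classes.
#'
#' @param sequences character vector of A/C/G/T strings.
#' @param pairs the [AptamerTargetSet-class] the model was trained on.
#' @param k neighborhood size (default 7).
#' @return integer class labels, one per sequence.
#' @export
assignClassByNeighbors <- function(sequences, pairs, k = 7L) {
  stopifnot(is(pairs, "AptamerTargetSet"), k >= 1L)
  if (length(sequences) == 0L) return(integer(0))
  for (s in sequences) .checkDNA(s)
  tr <- aptSequences(pairs)
  cls <- classLabels(pairs)
  k <- min(as.integer(k), length(tr))
  D <- utils::adist(sequences, tr)
  vapply(seq_along(sequences), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    votes <- table(cls[nb])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) return(top)
    # tie: the tied class with the nearest single neighbor
    top[which.min(vapply(top, function(cl) min(D[i, cls == cl]), 0))]
  }, 0L)
}

#' Filter generated sequences toward a class's strongest training binders
#'
#' Keeps the sequences closest (minimum edit distance) to the class's
#' top-scoring training sequences, its "anchors". Generated pools contain
#' a tail of divergent members whose presence dilutes column conservation
#' during consensus templating; anchoring the filter to the
#' highest-affinity training examples retains the members that carry the
#' class signal without referencing the consensus being built.
#'
#' @param sequences character vector of A/C/G/T strings (one class's
#'   members).
#' @param pairs the [AptamerTargetSet-class] the model was trained on.
#' @param class the class id the members belong to.
#' @param nAnchors how many top-score training sequences form the anchor
#'   set (default 5).
#' @param keep quantile of the distance distribution to retain
#'   (default 0.5: members within the median distance).
#' @return the retained sequences, input order preserved.
#' @export
filterByTrainingAnchors <- function(sequences, pairs, class, nAnchors = 5L,
                                    keep = 0.5) {
  stopifnot(is(pairs, "AptamerTargetSet"), nAnchors >= 1L,
            keep > 0, keep <= 1)
  if (length(sequences) == 0L) return(character(0))
  for (s in sequences) .checkDNA(s)
  idx <- which(classLabels(pairs) == class)
  if (length(idx) == 0L)
    stop("no training pairs in class ", class, call. = FALSE)
  anchors <- aptSequences(pairs)[idx[order(-aptScores(pairs)[idx])]]
  anchors <- anchors[seq_len(min(nAnchors, length(anchors)))]
  d <- apply(utils::adist(sequences, anchors), 1L, min)
  sequences[d <= stats::quantile(d, keep)]
}
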