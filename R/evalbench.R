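## Evaluation harness and conventional NGS baselines: edit distance to a
## ground-truth binder, PCA feature-space centroid distances, ranking
## metrics (AUROC / AUPRC / Top-1), and frequency / enrichment / greedy
## cluster-consensus candidate selection.

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance (via the generalized
#' distance in \code{utils::adist}).
#'
#' @param a,b DNA strings (vectorized; recycled).
#' @return non-negative integer vector.
#' @examples
#' editDistance("ACGT", "ACG")  # 1
#' @export
editDistance <- function(a, b) {
  as.integer(diag(utils::adist(a, b)))
}

#' Mean edit distance of candidates to a ground-truth sequence
#'
#' @param candidates character vector (e.g. a top-N view of a ranked list).
#' @param truth single ground-truth sequence.
#' @param n optional top-N truncation (candidates assumed ranked).
#' @return scalar mean Levenshtein distance.
#' @export
avgEditDistance <- function(candidates, truth, n = NULL) {
  if (!is.null(n)) candidates <- utils::head(candidates, n)
  if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  mean(as.numeric(utils::adist(candidates, truth)))
}

#' Two-component PCA projection
#'
#' Column-centered top-2 eigenvector projection with a fixed sign
#' convention (the largest-magnitude loading of each component is made
#' positive). Rank-deficient inputs get a zero second column and a
#' \code{rankDeficient} attribute.
#'
#' @param features numeric matrix (n x p, n >= 3).
#' @return n x 2 coordinate matrix.
#' @export
pca2d <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 0, nv = 2)
  rankDef <- sum(sv$d > max(sv$d) * 1e-10) < 2L
  V <- sv$v
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- Xc %*% V
  if (rankDef) coords[, 2] <- 0
  colnames(coords) <- c("PC1", "PC2")
  attr(coords, "rankDeficient") <- rankDef
  attr(coords, "rotation") <- V
  attr(coords, "center") <- attr(Xc, "scaled:center")
  coords
}

#' Flattened sequence + structure one-hot feature matrix
#'
#' The default feature space for PCA comparisons: each sequence's padded
#' sequence and structure one-hots, flattened and concatenated.
#'
#' @param sequences character vector.
#' @param maxLen common padded length (default: longest input).
#' @param minLoop,wobble folding parameters.
#' @return numeric matrix, n x (maxLen * 7).
#' @export
sequenceFeatures <- function(sequences, maxLen = max(nchar(sequences)),
                             minLoop = 3L, wobble = FALSE) {
  t(vapply(sequences, function(s) {
    enc <- encodeSequence(s, foldStructure(s, minLoop, wobble), maxLen)
    c(as.vector(enc@seqOneHot), as.vector(enc@structOneHot))
  }, numeric(maxLen * 7L), USE.NAMES = FALSE))
}

#' Euclidean distance between the centroids of two projected sets
#'
#' Both sets must live in a shared PCA basis (fit the projection on their
#' union).
#'
#' @param coordsA,coordsB coordinate matrices (rows = points).
#' @return scalar distance between the column means.
#' @export
centroidDistance <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty set", call. = FALSE)
  sqrt(sum((colMeans(A) - colMeans(B))^2))
}

#' Ranking metrics: AUROC, AUPRC and Top-1
#'
#' AUROC by the rank-sum (Mann-Whitney) statistic with midrank tie
#' correction; AUPRC by step interpolation of the precision-recall curve
#' (tied scores grouped); Top-1 = 1 iff the best-scored item is positive
#' (score ties break toward the lower index).
#'
#' @param scores numeric scores (higher = ranked better).
#' @param labels binary labels (1 = positive); at least one of each class.
#' @return named list with \code{auroc}, \code{auprc}, \code{top1}.
#' @export
rankingMetrics <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("need at least one positive and one negative label", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  # PR curve over decreasing score thresholds, tied scores as one block
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)  # block ends
  tpb <- tp[last]; fpb <- fp[last]
  rec <- tpb / npos
  prec <- tpb / (tpb + fpb)
  auprc <- sum(diff(c(0, rec)) * prec)
  top1 <- as.numeric(y[1L] == 1L)
  list(auroc = auroc, auprc = auprc, top1 = top1)
}

#' Frequency baseline: top sequences by read count
#'
#' @param pool a [PoolRound-class].
#' @param n how many candidates to return (default all).
#' @return data.frame \code{sequence}, \code{score} (count), sorted by
#'   count descending, count ties lexicographic.
#' @export
baselineFrequency <- function(pool, n = length(pool)) {
  ord <- order(-pool@counts, pool@sequences)
  utils::head(data.frame(sequence = pool@sequences[ord],
                         score = pool@counts[ord],
                         stringsAsFactors = FALSE), n)
}

#' Enrichment baseline: round-over-round frequency ratio
#'
#' score = ((count_late + pc) / depth_late) / ((count_early + pc) /
#' depth_early); the pseudocount keeps sequences appearing only late
#' finite and ranked high.
#'
#' @param early,late [PoolRound-class] objects from two rounds.
#' @param n candidates to return.
#' @param pseudocount additive smoothing (default 1).
#' @return data.frame \code{sequence}, \code{score}, descending (ties
#'   lexicographic).
#' @export
baselineEnrichment <- function(early, late, n = length(late),
                               pseudocount = 1) {
  depthE <- sum(early@counts); depthL <- sum(late@counts)
  ce <- early@counts[match(late@sequences, early@sequences)]
  ce[is.na(ce)] <- 0
  score <- ((late@counts + pseudocount) / depthL) /
    ((ce + pseudocount) / depthE)
  ord <- order(-score, late@sequences)
  utils::head(data.frame(sequence = late@sequences[ord], score = score[ord],
                         stringsAsFactors = FALSE), n)
}

#' Greedy cluster-consensus baseline
#'
#' Greedy single-linkage clustering at edit distance <= \code{radius},
#' seeding clusters in descending count order; returns the consensus of the
#' largest cluster (by total reads) and the consensus of the whole pool.
#'
#' @param pool a [PoolRound-class].
#' @param radius edit-distance linkage radius (default 3).
#' @param maxSeqs cap on pool sequences entered into clustering / consensus
#'   (top by count; keeps the quadratic distance step bounded).
#' @return list with \code{largestCluster} and \code{wholePool} consensus
#'   sequences, plus \code{labels} for the clustered subset.
#' @export
baselineClusterConsensus <- function(pool, radius = 3L, maxSeqs = 300L) {
  top <- baselineFrequency(pool, min(length(pool), maxSeqs))
  seqs <- top$sequence; cnt <- top$score
  n <- length(seqs)
  labels <- integer(n)
  D <- utils::adist(seqs)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    members <- i
    repeat {
      near <- which(labels == 0L &
                      apply(D[members, , drop = FALSE], 2L, min) <= radius)
      near <- setdiff(near, members)
      if (!length(near)) break
      members <- c(members, near)
    }
    labels[members] <- cl
  }
  sizes <- tapply(cnt, labels, sum)
  bigCl <- as.integer(names(sizes)[which.max(sizes)])
  list(largestCluster = candidateConsensus(seqs[labels == bigCl]),
       wholePool = candidateConsensus(seqs),
       labels = labels)
}
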