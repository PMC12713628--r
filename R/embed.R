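## Token embeddings and the modified target-sequence co-attention.
## Pretrained language-model providers are pluggable; the built-in provider
## is a deterministic seeded-hash embedding so the pipeline is
## self-contained and bit-reproducible.

#' Overlapping k-mer tokenization of a DNA sequence
#'
#' @param seq A/C/G/T string of length >= k.
#' @param k k-mer size (default 6).
#' @return character vector of the L-k+1 overlapping k-mers (stride 1).
#' @examples
#' kmerTokenize("ACGTACG", 6)
#' @export
kmerTokenize <- function(seq, k = 6L) {
  .checkDNA(seq)
  L <- nchar(seq)
  if (L < k)
    stop("sequence length ", L, " is shorter than k = ", k, call. = FALSE)
  vapply(seq_len(L - k + 1L), function(i) substr(seq, i, i + k - 1L), "")
}

#' Character tokenization of a SMILES string
#'
#' The deterministic fallback scheme for chemical embeddings: one token per
#' character (two-character halogens kept whole).
#'
#' @param smiles SMILES string.
#' @return character vector of tokens.
#' @export
smilesTokenize <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  out <- character(0); p <- 1L
  while (p <= length(chars)) {
    two <- if (p < length(chars)) paste0(chars[p], chars[p + 1L]) else ""
    if (two %in% c("Cl", "Br")) { out <- c(out, two); p <- p + 2L }
    else { out <- c(out, chars[p]); p <- p + 1L }
  }
  out
}

## deterministic standard normals from a hashed counter (Box-Muller)
.hashNormals <- function(key, n, seed) .hash_normals_cpp(key, n, seed)

#' Deterministic hash embedding of a token list
#'
#' Each distinct token maps to a fixed unit-norm d-vector derived from a
#' seeded hash, so identical tokens give identical rows and the whole
#' embedding is bit-reproducible across runs. Stands behind the provider
#' interface that a pretrained DNA/chemistry language model would otherwise
#' fill.
#'
#' @param tokens character vector.
#' @param d embedding dimension (>= 8).
#' @param seed integer provider seed.
#' @return list with \code{vectors} (T x d matrix, unit-norm rows) and
#'   \code{mask} (all-ones integer vector of length T).
#' @export
hashEmbed <- function(tokens, d = 64L, seed = 1L) {
  if (d < 8L) stop("embedding dimension must be >= 8", call. = FALSE)
  if (length(tokens) == 0L) stop("no tokens to embed", call. = FALSE)
  uniq <- unique(tokens)
  tab <- t(vapply(uniq, function(tk) {
    v <- .hashNormals(paste0("tok|", tk), d, seed)
    v / sqrt(sum(v^2))
  }, numeric(d)))
  V <- tab[match(tokens, uniq), , drop = FALSE]
  rownames(V) <- NULL
  list(vectors = V, mask = rep(1L, length(tokens)))
}

#' Modified scaled dot-product attention with query passthrough
#'
#' Computes \code{softmax(Q K' / sqrt(d_K)) V + Q / sqrt(d_Q)}: standard
#' scaled dot-product attention plus the query reiterated independently and
#' scaled back by the square root of its own dimension, which strengthens
#' target-specific information in the context. Masked key positions receive
#' \code{-Inf} logits before the softmax.
#'
#' @param Q query matrix (T_q x d).
#' @param K,V key and value matrices (T_k x d); \code{ncol(K)} must equal
#'   \code{ncol(Q)} and \code{ncol(V)} must equal \code{ncol(Q)} so the
#'   passthrough sum is well defined.
#' @param keyMask binary vector of length T_k (1 = real key); default all 1.
#' @return list with \code{context} (T_q x d) and \code{weights}
#'   (row-stochastic T_q x T_k).
#' @export
modifiedAttention <- function(Q, K, V, keyMask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  dK <- ncol(K); dQ <- ncol(Q)
  if (dQ != dK) stop("ncol(Q) must equal ncol(K)", call. = FALSE)
  if (ncol(V) != dQ)
    stop("ncol(V) must equal ncol(Q) for the query passthrough", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have equal rows", call. = FALSE)
  if (is.null(keyMask)) keyMask <- rep(1L, nrow(K))
  if (all(keyMask == 0L))
    stop("all key positions are masked", call. = FALSE)
  logits <- Q %*% t(K) / sqrt(dK)
  logits[, keyMask == 0L] <- -Inf
  mx <- apply(logits, 1L, max)
  W <- exp(logits - mx)
  W <- W / rowSums(W)
  list(context = W %*% V + Q / sqrt(dQ), weights = W)
}

#' Target-sequence co-attention
#'
#' The target embedding serves as the query; the aptamer sequence embedding
#' acts as key and value -- asking which sequence positions interact most
#' with the given target. Provider embeddings of different widths are
#' aligned to a common dimension by fixed seeded linear projections before
#' [modifiedAttention()] is applied.
#'
#' @param targetEmb,seqEmb embeddings as returned by [hashEmbed()] (lists
#'   with \code{vectors} and \code{mask}).
#' @param d common projection dimension (default 64).
#' @param seed seed for the projection matrices.
#' @return list with \code{context} (T_target x d), \code{weights}, and
#'   \code{pooled} (mask-weighted mean context row, length d).
#' @export
coAttend <- function(targetEmb, seqEmb, d = 64L, seed = 1L) {
  if (is.null(seqEmb$vectors) || nrow(seqEmb$vectors) == 0L)
    stop("empty sequence embedding", call. = FALSE)
  if (is.null(targetEmb$vectors) || nrow(targetEmb$vectors) == 0L)
    stop("empty target embedding", call. = FALSE)
  proj <- function(tag, din) {
    matrix(.hashNormals(paste0("proj|", tag, "|", din, "x", d), din * d, seed),
           nrow = din, ncol = d) / sqrt(din)
  }
  Qm <- targetEmb$vectors %*% proj("Q", ncol(targetEmb$vectors))
  Km <- seqEmb$vectors %*% proj("K", ncol(seqEmb$vectors))
  Vm <- seqEmb$vectors %*% proj("V", ncol(seqEmb$vectors))
  qMask <- if (is.null(targetEmb$mask)) rep(1L, nrow(Qm)) else targetEmb$mask
  Qm[qMask == 0L, ] <- 0
  att <- modifiedAttention(Qm, Km, Vm, keyMask = seqEmb$mask)
  keep <- qMask == 1L
  pooled <- colMeans(att$context[keep, , drop = FALSE])
  list(context = att$context, weights = att$weights, pooled = pooled)
}
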