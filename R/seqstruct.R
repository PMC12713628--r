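## Sequence/structure primitives: validation, one-hot encodings, the
## built-in base-pair-maximization folder, and primer-refinement truncation.

.checkDNA <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) && nchar(bad))
    stop("illegal character '", bad, "' in ", what,
         " (alphabet is A,C,G,T)", call. = FALSE)
  invisible(seq)
}

.checkDotBracket <- function(db, len = NULL) {
  if (!is.character(db) || length(db) != 1L || is.na(db) || nchar(db) == 0L)
    stop("dot-bracket must be a single non-empty string", call. = FALSE)
  if (grepl("[^().]", db))
    stop("dot-bracket may only contain '(', ')' and '.'", call. = FALSE)
  ch <- strsplit(db, "")[[1]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    stop("unbalanced dot-bracket string", call. = FALSE)
  if (!is.null(len) && nchar(db) != len)
    stop("dot-bracket length does not match sequence length", call. = FALSE)
  invisible(db)
}

#' Base-pair table of a dot-bracket string
#'
#' Parses matched parentheses into a two-column matrix of 1-based paired
#' positions (i < j). With a single bracket type the pairing is necessarily
#' non-crossing.
#'
#' @param db dot-bracket string over \code{(}, \code{)}, \code{.}.
#' @return integer matrix with columns \code{i}, \code{j}; zero rows when
#'   unpaired.
#' @examples
#' dotBracketPairs("((..))")
#' @export
dotBracketPairs <- function(db) {
  .checkDotBracket(db)
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  pairs <- list()
  for (p in seq_along(ch)) {
    if (ch[p] == "(") stack <- c(stack, p)
    else if (ch[p] == ")") {
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], p)
      stack <- stack[-length(stack)]
    }
  }
  if (length(pairs)) {
    out <- do.call(rbind, pairs)
    out <- out[order(out[, 1]), , drop = FALSE]
    dimnames(out) <- list(NULL, c("i", "j"))
  }
  out
}

#' One-hot encode a nucleotide sequence
#'
#' Row i carries a single 1 in the column of base i (column order A,C,G,T);
#' rows beyond the sequence length are zero.
#'
#' @param seq A/C/G/T string, 1-based from the 5' end.
#' @param maxLen padded length; the sequence must fit.
#' @return numeric matrix \code{maxLen x 4} with a \code{mask} attribute
#'   (integer 0/1 vector of length \code{maxLen}).
#' @examples
#' oneHotSequence("ACGT", 4)
#' @seealso [decodeOneHot()], [encodeSequence()]
#' @export
oneHotSequence <- function(seq, maxLen = 100L) {
  .checkDNA(seq)
  L <- nchar(seq)
  if (L > maxLen)
    stop("sequence length ", L, " exceeds maxLen ", maxLen, call. = FALSE)
  M <- matrix(0, nrow = maxLen, ncol = 4, dimnames = list(NULL, DNA_BASES))
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  M[cbind(seq_len(L), idx)] <- 1
  attr(M, "mask") <- c(rep(1L, L), rep(0L, maxLen - L))
  M
}

#' One-hot encode a dot-bracket structure
#'
#' Mirrors [oneHotSequence()] with column order \code{(}, \code{)}, \code{.}.
#'
#' @param db dot-bracket string.
#' @inheritParams oneHotSequence
#' @return numeric matrix \code{maxLen x 3} with a \code{mask} attribute.
#' @export
oneHotStructure <- function(db, maxLen = 100L) {
  .checkDotBracket(db)
  L <- nchar(db)
  if (L > maxLen)
    stop("structure length ", L, " exceeds maxLen ", maxLen, call. = FALSE)
  M <- matrix(0, nrow = maxLen, ncol = 3, dimnames = list(NULL, STRUCT_MARKS))
  idx <- match(strsplit(db, "")[[1]], STRUCT_MARKS)
  M[cbind(seq_len(L), idx)] <- 1
  attr(M, "mask") <- c(rep(1L, L), rep(0L, maxLen - L))
  M
}

#' Build an [EncodedSequence-class] from a sequence and optional structure
#'
#' @inheritParams oneHotSequence
#' @param db optional dot-bracket string of the same length; when omitted the
#'   structure slab is left all-zero.
#' @return an \code{EncodedSequence}.
#' @export
encodeSequence <- function(seq, db = NULL, maxLen = 100L) {
  S <- oneHotSequence(seq, maxLen)
  mask <- attr(S, "mask")
  attr(S, "mask") <- NULL
  if (is.null(db)) {
    D <- matrix(0, nrow = maxLen, ncol = 3, dimnames = list(NULL, STRUCT_MARKS))
  } else {
    .checkDotBracket(db, len = nchar(seq))
    D <- oneHotStructure(db, maxLen)
    attr(D, "mask") <- NULL
  }
  new("EncodedSequence", seqOneHot = S, structOneHot = D, mask = mask)
}

#' Decode a one-hot (or real-valued) matrix back to a sequence
#'
#' Per unmasked row the argmax base is emitted; ties break to the
#' lexicographically first base (column order A < C < G < T).
#'
#' @param matrix numeric matrix with 4 columns (A,C,G,T) and finite rows.
#' @param mask binary vector; defaults to the matrix's \code{mask} attribute
#'   or all-ones.
#' @return the decoded A/C/G/T string.
#' @examples
#' decodeOneHot(diag(4))
#' @export
decodeOneHot <- function(matrix, mask = NULL) {
  if (is.null(mask)) mask <- attr(matrix, "mask")
  if (is.null(mask)) mask <- rep(1L, nrow(matrix))
  if (!all(is.finite(matrix[mask == 1L, ])))
    stop("matrix rows must be finite", call. = FALSE)
  keep <- which(mask == 1L)
  if (length(keep) == 0L)
    stop("empty mask: nothing to decode", call. = FALSE)
  idx <- apply(matrix[keep, , drop = FALSE], 1L, which.max) # ties -> first
  paste(DNA_BASES[idx], collapse = "")
}

## occupied length of a decoded probability matrix: the last row whose
## peak probability is within half of the sequence's own signal level.
## A relative cut is used because out-of-distribution latents (prior
## samples) damp all probabilities globally; an absolute cut would then
## truncate decodes at arbitrary lengths.
.occupiedLength <- function(Pm, fallback) {
  peaks <- apply(Pm, 1L, max)
  occ <- peaks > 0.5 * max(peaks)
  if (any(occ)) max(which(occ)) else fallback
}

#' Decode a 3-column matrix to a dot-bracket string (argmax per row)
#' @inheritParams decodeOneHot
#' @return dot-bracket string (may be unbalanced for raw model output).
#' @export
decodeOneHotStructure <- function(matrix, mask = NULL) {
  if (is.null(mask)) mask <- attr(matrix, "mask")
  if (is.null(mask)) mask <- rep(1L, nrow(matrix))
  keep <- which(mask == 1L)
  if (length(keep) == 0L)
    stop("empty mask: nothing to decode", call. = FALSE)
  idx <- apply(matrix[keep, , drop = FALSE], 1L, which.max)
  paste(STRUCT_MARKS[idx], collapse = "")
}

#' Predict a secondary structure by base-pair maximization
#'
#' Returns the non-crossing pairing maximizing the number of Watson-Crick
#' (optionally plus G-T wobble) pairs with hairpin loops of at least
#' \code{minLoop} unpaired bases, via the classic cubic-time recursion. The
#' traceback is deterministic: the 5'-most base pairs whenever an optimal
#' structure allows it, with its smallest admissible partner. An externally
#' predicted structure can be substituted anywhere a folder is accepted (see
#' \code{folder} arguments and the dot-bracket sidecar I/O).
#'
#' @param seq A/C/G/T string.
#' @param minLoop minimum unpaired bases inside a hairpin loop (default 3).
#' @param wobble allow G-T pairs (default \code{FALSE}, Watson-Crick only).
#' @return dot-bracket string of the same length.
#' @examples
#' foldStructure("GGGAAACCC")
#' @export
foldStructure <- function(seq, minLoop = 3L, wobble = FALSE) {
  .checkDNA(seq)
  .nussinov_fold(seq, as.integer(minLoop), isTRUE(wobble))
}

#' Truncate primer flanks while preserving the core fold
#'
#' Removes the longest 5'/3' flanks such that the retained core, refolded in
#' isolation, reproduces exactly the core-internal base pairs of the
#' full-length fold -- i.e. the shortest subsequence that maintains the
#' global secondary structure. Both primers must match the sequence ends
#' exactly; otherwise the input is returned unchanged with a warning
#' attribute. Trim lengths are searched outside-in (largest total trim
#' first, 5' preferred on ties).
#'
#' @param seq full-length A/C/G/T string.
#' @param forward,reverse primer sequences expected at the 5'/3' ends.
#' @param folder folding function \code{seq -> dot-bracket}; defaults to
#'   [foldStructure()].
#' @param ... passed to \code{folder}.
#' @return the truncated sequence, with attributes \code{trim} (integer
#'   c(left, right)) and \code{warning} (character or NULL).
#' @export
primerRefine <- function(seq, forward, reverse, folder = foldStructure, ...) {
  .checkDNA(seq)
  .checkDNA(forward, "forward primer"); .checkDNA(reverse, "reverse primer")
  L <- nchar(seq)
  fail <- function(msg) {
    out <- seq; attr(out, "trim") <- c(0L, 0L); attr(out, "warning") <- msg
    warning(msg, call. = FALSE); out
  }
  if (!startsWith(seq, forward) || !endsWith(seq, reverse))
    return(fail("primers not found at sequence ends; returned unchanged"))
  full <- folder(seq, ...)
  fullPairs <- dotBracketPairs(full)
  samePairs <- function(p, q) {
    nrow(p) == nrow(q) && all(p == q)
  }
  # admissible trims keep every pair of the full-length fold inside the core;
  # the trimmed flanks are therefore unpaired regions of the global structure
  maxLeft <- if (nrow(fullPairs)) min(fullPairs[, 1]) - 1L else L - 1L
  maxRight <- if (nrow(fullPairs)) L - max(fullPairs[, 2]) else L - 1L
  for (t in seq(maxLeft + maxRight, 0L)) {
    for (a in seq(min(t, maxLeft), max(0L, t - maxRight))) {
      b <- t - a
      if (a + b >= L) next
      core <- substr(seq, a + 1L, L - b)
      refolded <- dotBracketPairs(folder(core, ...))
      if (samePairs(refolded, fullPairs - a)) {
        attr(core, "trim") <- c(left = a, right = b)
        attr(core, "warning") <- NULL
        return(core)
      }
    }
  }
  fail("no admissible core found; returned unchanged") # unreachable: t = 0 matches
}
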