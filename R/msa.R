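## Progressive multiple alignment with an average-linkage guide tree and
## profile-profile dynamic programming (match +1, mismatch -1, gap -2,
## terminal gaps free), plus alignment consensus: degenerate library
## templates, single consensus candidates, and sequence-logo counts. An
## external aligner can be substituted by supplying pre-gapped rows to the
## consensus functions.

.seqToProfile <- function(gapped) {
  ch <- strsplit(gapped, "")[[1]]
  P <- matrix(0, 4, length(ch), dimnames = list(DNA_BASES, NULL))
  hit <- ch %in% DNA_BASES
  P[cbind(match(ch[hit], DNA_BASES), which(hit))] <- 1
  P
}

.rowsToProfile <- function(rows) {
  mats <- lapply(rows, .seqToProfile)
  Reduce("+", mats) / length(rows)
}

.applyPath <- function(rows, path, consume) {
  # consume: move codes that advance this alignment (1 plus 2 for A, 3 for B)
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    out <- character(length(path)); p <- 0L
    for (k in seq_along(path)) {
      if (path[k] %in% consume) { p <- p + 1L; out[k] <- ch[p] }
      else out[k] <- "-"
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Progressive multiple sequence alignment
#'
#' Aligns DNA sequences with a guide tree (average-linkage clustering of
#' pairwise alignment scores) and profile-profile global dynamic
#' programming: match +1, mismatch -1, gap -2, terminal gaps free.
#' Deterministic given the input order and the fixed tie rules (diagonal
#' preferred, then a gap in the second profile). For two sequences the
#' result attains the optimal global pairwise score.
#'
#' @param sequences character vector of A/C/G/T strings.
#' @param match,mismatch,gap scoring parameters.
#' @param endFree are terminal gaps free?
#' @return character vector of gapped rows (equal length, same order as the
#'   input); de-gapping row i recovers input i. A single sequence is
#'   returned as-is.
#' @export
progressiveMSA <- function(sequences, match = 1, mismatch = -1, gap = -2,
                           endFree = TRUE) {
  n <- length(sequences)
  if (n == 0L) stop("no sequences to align", call. = FALSE)
  for (s in sequences) .checkDNA(s)
  if (n == 1L) return(sequences)
  profiles <- lapply(sequences, .seqToProfile)
  if (n == 2L) {
    al <- .profile_align(profiles[[1]], profiles[[2]], match, mismatch, gap,
                         endFree)
    return(c(.applyPath(sequences[1], al$path, c(1L, 2L)),
             .applyPath(sequences[2], al$path, c(1L, 3L))))
  }
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    S[i, j] <- S[j, i] <-
      .profile_align(profiles[[i]], profiles[[j]], match, mismatch, gap,
                     endFree)$score
  }
  D <- max(S) + 1 - S; diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  nodes <- lapply(seq_len(n), function(i)
    list(rows = sequences[i], ids = i))
  merged <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0) nodes[[-k]] else merged[[k]]
    A <- pick(tree$merge[m, 1]); B <- pick(tree$merge[m, 2])
    al <- .profile_align(.rowsToProfile(A$rows), .rowsToProfile(B$rows),
                         match, mismatch, gap, endFree)
    merged[[m]] <- list(
      rows = c(.applyPath(A$rows, al$path, c(1L, 2L)),
               .applyPath(B$rows, al$path, c(1L, 3L))),
      ids = c(A$ids, B$ids))
  }
  final <- merged[[n - 1L]]
  final$rows[order(final$ids)]
}

.columnMatrix <- function(alignment) {
  do.call(rbind, strsplit(alignment, ""))
}

#' Derive a guided-library template from an alignment
#'
#' Per column: columns with gap fraction >= \code{maxGapFraction} are
#' dropped; otherwise, if the modal base frequency among non-gap entries
#' reaches \code{conservationThreshold} the position is confined to that
#' base, else it stays N (any base). Base ties break alphabetically.
#'
#' @param alignment character vector of equal-length gapped rows (e.g. from
#'   [progressiveMSA()]).
#' @param conservationThreshold modal-base frequency needed to confine a
#'   position (default 0.8).
#' @param maxGapFraction gap fraction at which a column is dropped
#'   (default 0.5).
#' @param forward,reverse primers stored with the template ("" = none).
#' @return a [LibraryTemplate-class].
#' @export
consensusTemplate <- function(alignment, conservationThreshold = 0.8,
                              maxGapFraction = 0.5,
                              forward = "", reverse = "") {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  M <- .columnMatrix(alignment)
  symbols <- character(0)
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    gapFrac <- mean(col == "-")
    if (gapFrac >= maxGapFraction) next
    bases <- col[col != "-"]
    counts <- table(factor(bases, levels = DNA_BASES))
    top <- which.max(counts)  # ties -> alphabetical
    symbols <- c(symbols,
                 if (counts[top] / length(bases) >= conservationThreshold)
                   DNA_BASES[top] else "N")
  }
  if (length(symbols) == 0L)
    stop("all columns dropped: alignment too gappy", call. = FALSE)
  new("LibraryTemplate", symbols = symbols,
      confined = which(symbols != "N"),
      forwardPrimer = toupper(forward), reversePrimer = toupper(reverse))
}

#' Render a library template as a single string
#'
#' Lowercase primers flank the uppercase template (confined bases and N).
#'
#' @param template a [LibraryTemplate-class].
#' @return character string.
#' @export
renderLibrary <- function(template) {
  paste0(tolower(template@forwardPrimer),
         paste(template@symbols, collapse = ""),
         tolower(template@reversePrimer))
}

#' Emit a library record (and optionally a FASTA file)
#'
#' The FASTA header lists the confined (fixed-base) positions, 1-based
#' within the template (primers excluded).
#'
#' @param template a [LibraryTemplate-class].
#' @param id record identifier.
#' @param path optional FASTA file to append to.
#' @return invisibly, the two FASTA lines (header, record).
#' @export
emitLibrary <- function(template, id = "library", path = NULL) {
  if (!any(template@symbols == "N"))
    warning("template has no N positions: the library carries no diversity",
            call. = FALSE)
  header <- sprintf(">%s confined=%s", id,
                    paste(template@confined, collapse = ","))
  rec <- c(header, renderLibrary(template))
  if (!is.null(path)) {
    con <- file(path, "a")
    writeLines(rec, con)
    close(con)
  }
  invisible(rec)
}

#' Positional alignment of decoder-derived sequences
#'
#' Sequences decoded from one generative model are positionally aligned by
#' construction (position i of every decode comes from the same output
#' unit), so re-aligning them is both unnecessary and unstable: with free
#' terminal gaps, dissimilar sequences score better concatenated than
#' overlapped, and the progressive alignment degenerates. This helper
#' right-pads every sequence with gaps to the common width instead,
#' yielding rows directly usable by [consensusTemplate()].
#'
#' @param sequences character vector of A/C/G/T strings.
#' @param width common width (default: longest input).
#' @return character vector of equal-length gapped rows, input order.
#' @export
positionalAlignment <- function(sequences, width = max(nchar(sequences))) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  for (s in sequences) .checkDNA(s)
  if (any(nchar(sequences) > width))
    stop("sequence longer than width", call. = FALSE)
  vapply(sequences, function(s)
    paste0(s, strrep("-", width - nchar(s))), "", USE.NAMES = FALSE)
}

#' Trim alignment rows that disagree with the column plurality
#'
#' Iteratively removes divergent rows before consensus building: per pass,
#' the per-column plurality base (gaps excluded, ties alphabetical) is
#' computed, each row is scored by the fraction of its columns matching the
#' plurality, and rows scoring below the mean agreement are dropped. The
#' cutoff is the mean itself, so the step is parameter-free; passes stop
#' early when no row falls below it. Divergent rows otherwise dilute
#' column conservation and wash out genuinely conserved positions.
#'
#' @param alignment character vector of equal-length gapped rows.
#' @param maxPasses maximum trimming passes (default 2).
#' @param minRows never trim below this many rows (default 3).
#' @return the retained rows, original order preserved.
#' @export
refineAlignment <- function(alignment, maxPasses = 2L, minRows = 3L) {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  rows <- alignment
  for (p in seq_len(maxPasses)) {
    if (length(rows) <= minRows) break
    M <- .columnMatrix(rows)
    plur <- apply(M, 2L, function(col) {
      b <- col[col != "-"]
      if (!length(b)) return("-")
      counts <- table(factor(b, levels = DNA_BASES))
      DNA_BASES[which.max(counts)]
    })
    agree <- vapply(seq_len(nrow(M)),
                    function(i) mean(M[i, ] == plur), 0)
    keep <- agree >= mean(agree)
    if (all(keep)) break
    if (sum(keep) < minRows)
      keep <- rank(-agree, ties.method = "first") <= minRows
    rows <- rows[keep]
  }
  rows
}

#' Consensus candidate sequence from a set of sequences
#'
#' Takes the plurality base per column (ties alphabetical) after dropping
#' columns with gap fraction >= 0.5. Already-gapped rows and equal-length
#' inputs (fixed-length SELEX reads, decoder outputs) are used as columns
#' directly; ragged ungapped inputs are aligned with [progressiveMSA()]
#' first. Equal-length inputs deliberately skip re-alignment: for diverse
#' sets, end-free progressive alignment degenerates toward concatenation
#' and every column becomes mostly gaps.
#'
#' @param sequences character vector (plain or gapped).
#' @return a single A/C/G/T string.
#' @export
candidateConsensus <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  if (length(sequences) == 1L) return(gsub("-", "", sequences))
  rows <- if (any(grepl("-", sequences)) ||
              length(unique(nchar(sequences))) == 1L) sequences else
    progressiveMSA(sequences)
  M <- .columnMatrix(rows)
  out <- character(0)
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    if (mean(col == "-") >= 0.5) next
    counts <- table(factor(col[col != "-"], levels = DNA_BASES))
    out <- c(out, DNA_BASES[which.max(counts)])
  }
  if (length(out) == 0L) stop("consensus empty: alignment too gappy",
                              call. = FALSE)
  paste(out, collapse = "")
}

#' Position-wise base counts for a sequence logo
#'
#' @param sequences equal-length (or alignable) character vector; ragged
#'   inputs are aligned with [progressiveMSA()] first.
#' @return integer matrix, positions x 4 (A,C,G,T). For gap-free input every
#'   row sums to the member count.
#' @export
sequenceLogoCounts <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  lens <- nchar(sequences)
  rows <- if (length(unique(lens)) > 1L) progressiveMSA(sequences) else
    sequences
  M <- .columnMatrix(rows)
  counts <- t(apply(M, 2L, function(col)
    table(factor(col[col %in% DNA_BASES], levels = DNA_BASES))))
  storage.mode(counts) <- "integer"
  colnames(counts) <- DNA_BASES
  counts
}
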