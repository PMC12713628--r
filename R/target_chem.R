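## Small-molecule target handling: a subset SMILES parser, topological
## adjacency/distance matrices, ECFP-style circular fingerprints, and the
## 3-slab "sandwich" tensor joining target matrices with the aptamer's
## structure encoding. The built-in parser/fingerprint is the reference
## implementation; a cheminformatics backend can be substituted upstream by
## supplying precomputed matrices.

ORGANIC_ATOMS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Supports the organic subset: atoms B,C,N,O,P,S,F,Cl,Br,I (aromatic
#' lowercase b,c,n,o,p,s normalized to bond order 1.5), branches, ring
#' closures (digits and \code{\%nn}) and bond orders \code{-}, \code{=},
#' \code{#}. Hydrogens are implicit and ignored.
#'
#' @param smiles SMILES string.
#' @return a list with \code{atoms} (element symbols), \code{aromatic}
#'   (logical per atom) and \code{bonds} (matrix with columns \code{i},
#'   \code{j}, \code{order}; 1-based indices).
#' @examples
#' parseSmiles("C1CC1")$bonds
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("SMILES must be a single non-empty string", call. = FALSE)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- character(0); aromatic <- logical(0)
  bonds <- list()
  prev <- NA_integer_            # atom awaiting the next bond
  stack <- integer(0)            # branch points
  pending <- NA_real_            # explicit bond order for the next bond
  ring <- list()                 # closure digit -> list(atom, order)
  perr <- function(tok, pos)
    stop(sprintf("unsupported SMILES token '%s' at position %d", tok, pos),
         call. = FALSE)
  addBond <- function(i, j, order) {
    bonds[[length(bonds) + 1L]] <<- c(i, j, order)
  }
  addAtom <- function(elem, arom, pos) {
    atoms <<- c(atoms, elem); aromatic <<- c(aromatic, arom)
    idx <- length(atoms)
    if (!is.na(prev)) {
      order <- if (!is.na(pending)) pending
               else if (arom && aromatic[prev]) 1.5 else 1
      addBond(prev, idx, order)
    }
    pending <<- NA_real_
    prev <<- idx
  }
  closeRing <- function(key, pos) {
    if (is.na(prev)) perr(key, pos)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, order = pending)
    } else {
      other <- ring[[key]]
      order <- if (!is.na(pending)) pending
               else if (!is.na(other$order)) other$order
               else if (aromatic[prev] && aromatic[other$atom]) 1.5 else 1
      addBond(other$atom, prev, order)
      ring[[key]] <<- NULL
    }
    pending <<- NA_real_
  }
  p <- 1L
  while (p <= n) {
    ch <- chars[p]
    two <- if (p < n) paste0(ch, chars[p + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      addAtom(two, FALSE, p); p <- p + 2L; next
    }
    if (ch %in% ORGANIC_ATOMS) { addAtom(ch, FALSE, p); p <- p + 1L; next }
    if (ch %in% AROMATIC_ATOMS) { addAtom(toupper(ch), TRUE, p); p <- p + 1L; next }
    if (ch == "-") { pending <- 1; p <- p + 1L; next }
    if (ch == "=") { pending <- 2; p <- p + 1L; next }
    if (ch == "#") { pending <- 3; p <- p + 1L; next }
    if (ch == "(") {
      if (is.na(prev)) perr("(", p)
      stack <- c(stack, prev); p <- p + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) perr(")", p)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      p <- p + 1L; next
    }
    if (grepl("[0-9]", ch)) { closeRing(ch, p); p <- p + 1L; next }
    if (ch == "%") {
      if (p + 2L > n || !grepl("^[0-9]{2}$", two <- paste0(chars[p + 1L], chars[p + 2L])))
        perr("%", p)
      closeRing(two, p); p <- p + 3L; next
    }
    perr(ch, p)
  }
  if (length(stack)) stop("unbalanced branch: '(' without ')'", call. = FALSE)
  open <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open))
    stop("unclosed ring bond(s): ", paste(open, collapse = ", "), call. = FALSE)
  if (!is.na(pending)) stop("dangling bond symbol at end of SMILES", call. = FALSE)
  if (length(atoms) == 0L) stop("SMILES contains no atoms", call. = FALSE)
  B <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(numeric(0), ncol = 3)
  colnames(B) <- c("i", "j", "order")
  list(atoms = atoms, aromatic = aromatic, bonds = B)
}

#' Adjacency matrix of a molecular graph
#'
#' @param g graph from [parseSmiles()].
#' @return symmetric n x n binary matrix; \code{A[i,j] = 1} iff a bond of any
#'   order joins atoms i and j.
#' @export
adjacencyMatrix <- function(g) {
  n <- length(g$atoms)
  A <- matrix(0, n, n)
  if (nrow(g$bonds)) {
    A[g$bonds[, 1:2, drop = FALSE]] <- 1
    A[g$bonds[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Topological distance matrix (shortest bond-count paths)
#'
#' Breadth-first shortest paths over the bond graph; a deterministic,
#' conformer-free metric. 3D distances can be substituted by passing a
#' precomputed matrix wherever target matrices are consumed.
#'
#' @inheritParams adjacencyMatrix
#' @return symmetric non-negative n x n matrix with zero diagonal.
#' @export
distanceMatrix <- function(g) {
  A <- adjacencyMatrix(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & is.infinite(D[s, ]))
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  if (any(is.infinite(D)))
    stop("molecular graph is disconnected", call. = FALSE)
  D
}

## 32-bit FNV-1a over a string, with a seed folded into the offset basis.
## Arithmetic kept exact in doubles by 16-bit split multiplication.
.hash32 <- function(s, seed = 0) .hash32_cpp(s, seed)

#' Circular (ECFP-style) fingerprint of a molecular graph
#'
#' Iterative neighborhood hashing: each atom starts from an invariant
#' (element, degree, bond-order sum, aromaticity); each round folds in the
#' sorted (bond order, neighbor identifier) list. Identifiers from all radii
#' are hashed into \code{nBits} positions with a fixed seed, so the bits are
#' invariant to atom input order.
#'
#' @inheritParams adjacencyMatrix
#' @param radius number of hashing rounds (default 2).
#' @param nBits fingerprint length (default 2048).
#' @param seed hashing seed mixed into every identifier (default 42; record
#'   it with any saved model).
#' @return integer 0/1 vector of length \code{nBits}.
#' @export
morganFingerprint <- function(g, radius = 2L, nBits = 2048L, seed = 42L) {
  n <- length(g$atoms)
  if (n == 0L) stop("empty molecule", call. = FALSE)
  nb <- vector("list", n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds[r, 1]; j <- g$bonds[r, 2]; o <- g$bonds[r, 3]
      nb[[i]] <- rbind(nb[[i]], c(j, o))
      nb[[j]] <- rbind(nb[[j]], c(i, o))
    }
  }
  deg <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  osum <- vapply(nb, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
  ids <- vapply(seq_len(n), function(i) {
    .hash32(paste(g$atoms[i], deg[i], osum[i], g$aromatic[i], sep = "|"), seed)
  }, numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (i in seq_len(n)) {
      if (deg[i] == 0L) next  # environment cannot grow
      env <- sort(paste0(nb[[i]][, 2], ":", ids[nb[[i]][, 1]]))
      new_ids[i] <- .hash32(paste(c(ids[i], env), collapse = "|"), seed)
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids[deg > 0L])
  }
  bits <- integer(nBits)
  bits[unique(all_ids %% nBits) + 1L] <- 1L
  bits
}

#' Assemble the 3-slab sandwich tensor
#'
#' Stacks, in this order, the target distance matrix, the aptamer's
#' secondary-structure one-hot block, and the target adjacency matrix, each
#' embedded top-left in an S x S slab (zero elsewhere). The interleaving
#' mirrors the spatial picture of an aptamer clamped between views of its
#' target.
#'
#' @param enc an [EncodedSequence-class] whose structure block is filled.
#' @param adjacency,distance target matrices (n x n).
#' @param S common slab size; must be at least \code{max(n, L, 3)} where L is
#'   the unpadded sequence length.
#' @return numeric array \code{c(3, S, S)}; slabs
#'   \code{[distance, structure, adjacency]}.
#' @export
buildSandwich <- function(enc, adjacency, distance, S) {
  stopifnot(is(enc, "EncodedSequence"))
  n <- nrow(adjacency)
  if (n == 0L) stop("target has no atoms", call. = FALSE)
  if (!all(dim(adjacency) == c(n, n)) || !all(dim(distance) == c(n, n)))
    stop("adjacency and distance must be square of equal size", call. = FALSE)
  L <- sum(enc@mask)
  if (S < max(n, L, 3L))
    stop("sandwich size S=", S, " too small for n=", n, ", L=", L, call. = FALSE)
  out <- array(0, dim = c(3L, S, S))
  out[1, seq_len(n), seq_len(n)] <- distance
  out[2, seq_len(L), 1:3] <- enc@structOneHot[seq_len(L), , drop = FALSE]
  out[3, seq_len(n), seq_len(n)] <- adjacency
  out
}

#' Parse, characterize and fingerprint one target SMILES
#'
#' Convenience wrapper producing the per-target description stored in an
#' [AptamerTargetSet-class].
#'
#' @inheritParams parseSmiles
#' @inheritParams morganFingerprint
#' @return list with \code{smiles}, \code{graph}, \code{adjacency},
#'   \code{distance}, \code{fingerprint}, \code{nAtoms}.
#' @export
describeTarget <- function(smiles, radius = 2L, nBits = 2048L, seed = 42L) {
  g <- parseSmiles(smiles)
  list(smiles = smiles, graph = g,
       adjacency = adjacencyMatrix(g), distance = distanceMatrix(g),
       fingerprint = morganFingerprint(g, radius, nBits, seed),
       nAtoms = length(g$atoms))
}

#' Read a targets table (TSV: class_id, name, SMILES)
#'
#' @param path tab-separated file with columns \code{class_id}, \code{name},
#'   \code{smiles} (no header by default).
#' @param header does the file carry a header line?
#' @return data.frame with columns \code{class_id}, \code{name},
#'   \code{smiles}, ordered by class id.
#' @export
readTargetsTable <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  colnames(df)[1:3] <- c("class_id", "name", "smiles")
  df[order(df$class_id), , drop = FALSE]
}
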