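## Central S4 containers. Sequences are plain uppercase A/C/G/T character
## vectors internally; Biostrings objects are accepted at the I/O boundary.

DNA_BASES <- c("A", "C", "G", "T")
STRUCT_MARKS <- c("(", ")", ".")

#' One-hot encoded aptamer sequence and secondary structure
#'
#' Holds the padded one-hot matrices for a nucleotide sequence (columns
#' A,C,G,T) and its dot-bracket secondary structure (columns '(', ')', '.'),
#' plus the padding mask. Unmasked rows sum to one; padded rows are all-zero.
#'
#' @slot seqOneHot numeric matrix, maxLen x 4.
#' @slot structOneHot numeric matrix, maxLen x 3 (all-zero when no structure
#'   was supplied).
#' @slot mask integer vector of length maxLen; 1 for real positions, 0 for
#'   padding.
#' @seealso [encodeSequence()], [oneHotSequence()], [decodeOneHot()]
#' @export
setClass("EncodedSequence", representation(
  seqOneHot = "matrix", structOneHot = "matrix", mask = "integer"
))

setValidity("EncodedSequence", function(object) {
  m <- object@mask
  S <- object@seqOneHot
  D <- object@structOneHot
  if (nrow(S) != length(m) || nrow(D) != length(m))
    return("matrix rows and mask length disagree")
  if (ncol(S) != 4L) return("seqOneHot must have 4 columns")
  if (ncol(D) != 3L) return("structOneHot must have 3 columns")
  if (!all(m %in% c(0L, 1L))) return("mask must be binary")
  if (any(rowSums(S)[m == 1L] != 1)) return("unmasked sequence rows must sum to 1")
  if (any(rowSums(S)[m == 0L] != 0)) return("masked sequence rows must be zero")
  has_struct <- any(D != 0)
  if (has_struct && any(rowSums(D)[m == 1L] != 1))
    return("unmasked structure rows must sum to 1")
  if (any(rowSums(D)[m == 0L] != 0)) return("masked structure rows must be zero")
  TRUE
})

#' Training set of aptamer-target pairs
#'
#' One record per training pair: aptamer sequence, dot-bracket structure,
#' target identity (index into \code{targets}), class label in
#' \code{1..nClasses} and a relative binding score in [0,1]. \code{targets}
#' holds one parsed target per class: a list with elements \code{smiles},
#' \code{graph} (see [parseSmiles()]), \code{matrices} (adjacency/distance)
#' and \code{fingerprint}.
#'
#' @slot sequences character vector of A/C/G/T strings.
#' @slot structures character vector of dot-bracket strings (same lengths).
#' @slot classLabels integer vector, values in \code{1..length(targets)}.
#' @slot scores numeric vector in [0,1].
#' @slot targets list of per-class target descriptions.
#' @seealso [genPairs()], [trainAptaVAE()]
#' @export
setClass("AptamerTargetSet", representation(
  sequences = "character", structures = "character",
  classLabels = "integer", scores = "numeric", targets = "list"
))

setValidity("AptamerTargetSet", function(object) {
  n <- length(object@sequences)
  if (length(object@structures) != n || length(object@classLabels) != n ||
      length(object@scores) != n)
    return("per-pair slots must have equal length")
  if (n == 0L) return("at least one pair required")
  if (any(nchar(object@structures) != nchar(object@sequences)))
    return("structure length must equal sequence length")
  if (any(!grepl("^[ACGT]+$", object@sequences)))
    return("sequences must be non-empty A/C/G/T strings")
  k <- length(object@targets)
  if (k < 1L) return("at least one target required")
  if (any(object@classLabels < 1L | object@classLabels > k))
    return("class labels out of range")
  if (any(object@scores < 0 | object@scores > 1))
    return("scores must lie in [0,1]")
  TRUE
})

#' Unique sequences with read counts for one SELEX round
#'
#' @slot roundId integer round index (e.g. 3, 5 or 7).
#' @slot sequences character vector of unique A/C/G/T strings.
#' @slot counts integer read counts (>= 1), parallel to \code{sequences}.
#' @seealso [simulateSelex()], [trainAptaClux()], [readPool()]
#' @export
setClass("PoolRound", representation(
  roundId = "integer", sequences = "character", counts = "integer"
))

setValidity("PoolRound", function(object) {
  if (length(object@sequences) != length(object@counts))
    return("sequences and counts must be parallel")
  if (length(object@sequences) == 0L) return("empty pool")
  if (anyDuplicated(object@sequences)) return("sequences must be unique")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  if (any(!grepl("^[ACGT]+$", object@sequences)))
    return("sequences must be A/C/G/T strings")
  TRUE
})

#' Guided initial library template
#'
#' Per-position template symbols (a confined base A/C/G/T or N for a free
#' position), 1-based from the 5' end, flanked by lowercase primers when
#' rendered. A useful library keeps at least one N so diversity remains;
#' [emitLibrary()] warns when none is left.
#'
#' @slot symbols character vector over A,C,G,T,N.
#' @slot confined integer indices of confined (fixed-base) positions.
#' @slot forwardPrimer,reversePrimer character primers ("" when absent).
#' @seealso [consensusTemplate()], [emitLibrary()]
#' @export
setClass("LibraryTemplate", representation(
  symbols = "character", confined = "integer",
  forwardPrimer = "character", reversePrimer = "character"
))

setValidity("LibraryTemplate", function(object) {
  if (!all(object@symbols %in% c(DNA_BASES, "N")))
    return("template symbols must be A,C,G,T or N")
  if (length(object@symbols) == 0L) return("empty template")
  conf <- which(object@symbols != "N")
  if (!identical(sort(object@confined), conf))
    return("confined indices inconsistent with symbols")
  TRUE
})

#' Diagonal-Gaussian latent posterior
#'
#' Mean and log-variance of a variational posterior q(z|x); sampling and the
#' closed-form KL divergence to the standard normal prior operate on this.
#'
#' @slot mu,logvar numeric vectors of equal length.
#' @seealso [klGaussian()], [encodePair()]
#' @export
setClass("LatentDistribution", representation(mu = "numeric", logvar = "numeric"))

setValidity("LatentDistribution", function(object) {
  if (length(object@mu) != length(object@logvar))
    return("mu and logvar must have equal length")
  if (!all(is.finite(object@mu)) || !all(is.finite(object@logvar)))
    return("latent parameters must be finite")
  TRUE
})

## Trained models: parameter lists plus the frozen configuration and
## preprocessing dimensions needed to encode/decode consistently.

#' Trained guided-library VAE
#' @slot params named list of weight matrices/vectors (best-validation copy).
#' @slot config named list of training configuration (see [aptaVAEConfig()]).
#' @slot dims named list of preprocessing sizes (maxLen, sandwich size, ...).
#' @slot history data.frame of per-epoch loss breakdowns.
#' @slot targets list of per-class target descriptions used in training.
#' @export
setClass("AptaVAEModel", representation(
  params = "list", config = "list", dims = "list",
  history = "data.frame", targets = "list"
))

#' Trained pool-summarization VAE
#' @slot params named list of weight matrices/vectors (best-validation copy).
#' @slot config named list of training configuration (see [cluxConfig()]).
#' @slot dims named list of preprocessing sizes.
#' @slot history data.frame of per-epoch loss breakdowns.
#' @export
setClass("AptaCluxModel", representation(
  params = "list", config = "list", dims = "list", history = "data.frame"
))

## ---- accessors and show methods ----

#' @describeIn AptamerTargetSet number of pairs
#' @param x object
#' @export
setMethod("length", "AptamerTargetSet", function(x) length(x@sequences))

#' @describeIn PoolRound number of unique sequences
#' @param x object
#' @export
setMethod("length", "PoolRound", function(x) length(x@sequences))

#' Accessors for AptaDesign containers
#'
#' \code{aptSequences} returns the sequence strings, \code{aptStructures}
#' the dot-bracket strings, \code{classLabels} the class indices,
#' \code{aptScores} the relative scores, \code{poolCounts} the read counts
#' and \code{roundId} the SELEX round index.
#'
#' @param x an \code{AptamerTargetSet} or \code{PoolRound}.
#' @return the corresponding vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("aptSequences", function(x) standardGeneric("aptSequences"))
#' @rdname accessors
#' @export
setGeneric("aptStructures", function(x) standardGeneric("aptStructures"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("aptScores", function(x) standardGeneric("aptScores"))
#' @rdname accessors
#' @export
setGeneric("poolCounts", function(x) standardGeneric("poolCounts"))
#' @rdname accessors
#' @export
setGeneric("roundId", function(x) standardGeneric("roundId"))

#' @rdname accessors
#' @export
setMethod("aptSequences", "AptamerTargetSet", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("aptSequences", "PoolRound", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("aptStructures", "AptamerTargetSet", function(x) x@structures)
#' @rdname accessors
#' @export
setMethod("classLabels", "AptamerTargetSet", function(x) x@classLabels)
#' @rdname accessors
#' @export
setMethod("aptScores", "AptamerTargetSet", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("poolCounts", "PoolRound", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("roundId", "PoolRound", function(x) x@roundId)

#' @describeIn AptamerTargetSet subset pairs
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "AptamerTargetSet", function(x, i, j, ..., drop = TRUE) {
  new("AptamerTargetSet",
      sequences = x@sequences[i], structures = x@structures[i],
      classLabels = x@classLabels[i], scores = x@scores[i],
      targets = x@targets)
})

setMethod("show", "AptamerTargetSet", function(object) {
  cat(sprintf("AptamerTargetSet: %d pairs, %d target classes\n",
              length(object), length(object@targets)))
  cat(sprintf("  sequence lengths %d-%d, mean score %.3f\n",
              min(nchar(object@sequences)), max(nchar(object@sequences)),
              mean(object@scores)))
})

setMethod("show", "PoolRound", function(object) {
  cat(sprintf("PoolRound %d: %d unique sequences, %d reads\n",
              object@roundId, length(object), sum(object@counts)))
})

setMethod("show", "LibraryTemplate", function(object) {
  cat("LibraryTemplate:", renderLibrary(object), "\n")
  cat(sprintf("  %d confined / %d positions\n",
              length(object@confined), length(object@symbols)))
})

setMethod("show", "LatentDistribution", function(object) {
  cat(sprintf("LatentDistribution: %d dims, KL to prior %.4f\n",
              length(object@mu), klGaussian(object)))
})

setMethod("show", "AptaVAEModel", function(object) {
  cat(sprintf("AptaVAEModel: latent %d, maxLen %d, sandwich %d, %d epochs trained\n",
              object@config$latent_dim, object@dims$maxLen, object@dims$S,
              nrow(object@history)))
  cat(sprintf("  best validation loss %.4f at epoch %d\n",
              min(object@history$val_total), which.min(object@history$val_total)))
})

setMethod("show", "AptaCluxModel", function(object) {
  cat(sprintf("AptaCluxModel: latent %d, maxLen %d, %d epochs trained\n",
              object@config$latent_dim, object@dims$maxLen, nrow(object@history)))
  cat(sprintf("  best validation loss %.4f at epoch %d\n",
              min(object@history$val_total), which.min(object@history$val_total)))
})
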