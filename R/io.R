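## Format glue: FASTA/FASTQ (via Biostrings), dot-bracket sidecars,
## sequence+count pool TSVs, training-pair TSVs and JSON manifests.

#' Read DNA sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write DNA sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector (names become headers).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named", call. = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write dot-bracket sidecar files
#'
#' Plain text, one record per line: \code{ID<TAB>SEQ<TAB>DOTBRACKET}.
#'
#' @param path sidecar file.
#' @return \code{readDotBracket}: data.frame with \code{id},
#'   \code{sequence}, \code{structure}.
#' @export
readDotBracket <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "sequence", "structure"))
  if (any(nchar(df$sequence) != nchar(df$structure)))
    stop("sidecar structure length differs from sequence length",
         call. = FALSE)
  df
}

#' @rdname readDotBracket
#' @param ids,sequences,structures parallel record vectors.
#' @export
writeDotBracket <- function(ids, sequences, structures, path) {
  stopifnot(length(ids) == length(sequences),
            length(sequences) == length(structures))
  writeLines(paste(ids, sequences, structures, sep = "\t"), path)
  invisible(path)
}

#' Predict structures for a FASTA file into a sidecar
#'
#' The built-in adapter for the external-predictor interface: consumes a
#' FASTA, runs [foldStructure()] on each record and writes the dot-bracket
#' sidecar. An external predictor can replace this by honoring the same
#' file contract.
#'
#' @param fastaPath input FASTA.
#' @param sidecarPath output sidecar path.
#' @param minLoop,wobble folding parameters.
#' @return invisibly, the sidecar data.frame.
#' @export
foldFastaToSidecar <- function(fastaPath, sidecarPath, minLoop = 3L,
                               wobble = FALSE) {
  seqs <- readFastaSeqs(fastaPath)
  dbs <- vapply(seqs, foldStructure, "", minLoop = minLoop, wobble = wobble)
  writeDotBracket(names(seqs), unname(seqs), unname(dbs), sidecarPath)
  invisible(data.frame(id = names(seqs), sequence = unname(seqs),
                       structure = unname(dbs), stringsAsFactors = FALSE))
}

#' Read a SELEX pool round
#'
#' Accepts either a sequence+count TSV (\code{SEQ<TAB>COUNT}) or
#' FASTA/FASTQ reads (counts = read multiplicity), chosen by file
#' extension (\code{.fastq}/\code{.fq} = FASTQ, \code{.fasta}/\code{.fa} =
#' FASTA, anything else = TSV).
#'
#' @param path input file.
#' @param roundId SELEX round index to record.
#' @return a [PoolRound-class].
#' @export
readPool <- function(path, roundId) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fastq", "fq", "fasta", "fa", "fna")) {
    fmt <- if (ext %in% c("fastq", "fq")) "fastq" else "fasta"
    reads <- toupper(as.character(Biostrings::readDNAStringSet(path,
                                                               format = fmt)))
    tab <- table(reads)
    seqs <- names(tab); counts <- as.integer(tab)
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("sequence", "count"))
    agg <- tapply(as.integer(df$count), df$sequence, sum)
    seqs <- names(agg); counts <- as.integer(agg)
  }
  new("PoolRound", roundId = as.integer(roundId),
      sequences = as.character(seqs), counts = counts)
}

#' Write a SELEX pool round as a sequence+count TSV
#'
#' @param pool a [PoolRound-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePool <- function(pool, path) {
  ord <- order(pool@sequences)
  writeLines(paste(pool@sequences[ord], pool@counts[ord], sep = "\t"), path)
  invisible(path)
}

#' Read / write training pairs
#'
#' TSV with one pair per line:
#' \code{SEQ<TAB>DOTBRACKET<TAB>SMILES<TAB>CLASS<TAB>SCORE}. Each class
#' must map to exactly one SMILES; targets are parsed once per class with
#' [describeTarget()].
#'
#' @param path TSV file.
#' @return \code{readTrainingPairs}: an [AptamerTargetSet-class].
#' @export
readTrainingPairs <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sequence", "structure", "smiles",
                                        "class", "score"))
  cls <- as.integer(df$class)
  k <- max(cls)
  smilesByClass <- character(k)
  for (c in seq_len(k)) {
    sm <- unique(df$smiles[cls == c])
    if (length(sm) > 1L)
      stop("class ", c, " maps to multiple SMILES", call. = FALSE)
    if (length(sm) == 0L)
      stop("no pairs for class ", c, call. = FALSE)
    smilesByClass[c] <- sm
  }
  new("AptamerTargetSet",
      sequences = toupper(df$sequence), structures = df$structure,
      classLabels = cls, scores = as.numeric(df$score),
      targets = lapply(smilesByClass, describeTarget))
}

#' @rdname readTrainingPairs
#' @param pairs an [AptamerTargetSet-class].
#' @export
writeTrainingPairs <- function(pairs, path) {
  smiles <- vapply(pairs@targets, `[[`, "", "smiles")
  writeLines(paste(pairs@sequences, pairs@structures,
                   smiles[pairs@classLabels], pairs@classLabels,
                   format(pairs@scores, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' Write candidate sequences as FASTA with provenance headers
#'
#' Headers carry \code{route=}, \code{round=} and \code{seed=} fields so a
#' candidate's origin is recoverable from the file alone.
#'
#' @param candidates named character vector (names = candidate IDs).
#' @param path output FASTA.
#' @param route provenance route label (e.g. "HD", "CC", "frequency").
#' @param round SELEX round the pool came from.
#' @param seed seed used by the producing stage.
#' @return invisibly, \code{path}.
#' @export
writeCandidates <- function(candidates, path, route = "HD", round = NA,
                            seed = NA) {
  nm <- sprintf("%s route=%s round=%s seed=%s", names(candidates), route,
                round, seed)
  writeFastaSeqs(stats::setNames(candidates, nm), path)
}

#' Write / read a JSON manifest
#'
#' @param x named list.
#' @param path JSON file.
#' @return \code{readManifest}: the parsed list.
#' @export
writeManifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
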