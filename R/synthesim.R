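## Synthetic fixtures: aptamer-target training pairs with planted
## class-specific motifs whose presence tracks the binding score, and a
## SELEX enrichment simulator (fitness-weighted multinomial resampling with
## PCR-style per-base mutation) producing per-round pools around a planted
## binder. Everything is seeded and reproducible.

#' Specification of a synthetic aptamer-target family
#'
#' Emulates a curated literature training set for one small-molecule family:
#' a handful of classes sharing a chemical scaffold, each with its own
#' sequence motif whose presence correlates with the reported binding score.
#'
#' @param n_classes number of target classes (default 8).
#' @param motif_length motif length in nt (default 10, within 8-12).
#' @param seq_len aptamer length (default 40).
#' @param n_pairs number of training pairs (default 195).
#' @param score_noise_sd Gaussian noise added to scores before clipping
#'   (default 0.05).
#' @param seed RNG seed.
#' @return named list.
#' @export
syntheticFamilySpec <- function(n_classes = 8L, motif_length = 10L,
                                seq_len = 40L, n_pairs = 195L,
                                score_noise_sd = 0.05, seed = 1L) {
  stopifnot(n_pairs >= n_classes, motif_length >= 8L, motif_length <= 12L,
            seq_len > motif_length)
  list(n_classes = as.integer(n_classes),
       motif_length = as.integer(motif_length),
       seq_len = as.integer(seq_len), n_pairs = as.integer(n_pairs),
       score_noise_sd = score_noise_sd, seed = as.integer(seed))
}

#' Specification of a synthetic SELEX campaign
#'
#' @param pool_size reads per round (default 2000, >= 1000).
#' @param rounds rounds to report (default c(3, 5, 7)).
#' @param binder planted binder sequence (default: random, drawn from the
#'   seed).
#' @param seq_len read length when the binder is drawn (default 40).
#' @param sharpness selection strength: fitness weight
#'   \code{exp(sharpness * (-editDist / L))} (default 4).
#' @param mutation_rate per-base substitution rate applied after resampling
#'   (PCR-error analogue; default 0.002, must be <= 0.1).
#' @param plant_frac fraction of round-0 reads drawn as mutated copies of
#'   the binder (default 0.02).
#' @param plant_mut per-base mutation rate of those planted copies
#'   (default 0.05).
#' @param seed RNG seed.
#' @return named list.
#' @export
syntheticSelexSpec <- function(pool_size = 2000L, rounds = c(3L, 5L, 7L),
                               binder = NULL, seq_len = 40L, sharpness = 4,
                               mutation_rate = 0.002, plant_frac = 0.02,
                               plant_mut = 0.05, seed = 1L) {
  stopifnot(pool_size >= 1000L, mutation_rate >= 0, mutation_rate <= 0.1)
  list(pool_size = as.integer(pool_size), rounds = as.integer(rounds),
       binder = binder, seq_len = as.integer(seq_len), sharpness = sharpness,
       mutation_rate = mutation_rate, plant_frac = plant_frac,
       plant_mut = plant_mut, seed = as.integer(seed))
}

## steroid-like synthetic scaffold: four fused carbon rings plus a short
## tail the class substituent hangs off
.SCAFFOLD <- "C1CCC2C1CCC1C2CCC2C1CCCC2C"
.SUBSTITUENTS <- c("O", "N", "S", "CO", "CN", "CS", "C=O", "CC")

#' Generate synthetic target molecules sharing a fused-ring scaffold
#'
#' All classes share the same four-fused-ring carbon skeleton (a stand-in
#' for a steroid backbone) and differ by a small substituent -- the kind of
#' hydroxyl/ketone/methyl-scale edits that distinguish members of one
#' chemical family.
#'
#' @param spec a [syntheticFamilySpec()].
#' @return data.frame with \code{class_id}, \code{name}, \code{smiles},
#'   plus attribute \code{targets}: the [describeTarget()] list per class.
#' @export
genTargets <- function(spec = syntheticFamilySpec()) {
  k <- spec$n_classes
  if (k > length(.SUBSTITUENTS))
    stop("at most ", length(.SUBSTITUENTS), " synthetic classes supported",
         call. = FALSE)
  smiles <- paste0(.SCAFFOLD, .SUBSTITUENTS[seq_len(k)])
  df <- data.frame(class_id = seq_len(k),
                   name = paste0("synthetic_steroid_", seq_len(k)),
                   smiles = smiles, stringsAsFactors = FALSE)
  attr(df, "targets") <- lapply(smiles, describeTarget)
  df
}

.randomSeq <- function(L) paste(sample(DNA_BASES, L, replace = TRUE),
                                collapse = "")

.mutateSeq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate synthetic aptamer-target training pairs
#'
#' Per pair: a class is drawn uniformly; the score is Beta(2,2) plus noise,
#' clipped to [0,1]; the sequence is uniform random with the class motif
#' implanted at the class-fixed position with probability equal to the
#' score (so high-scoring pairs carry the motif); the structure is
#' predicted with [foldStructure()].
#'
#' @param spec a [syntheticFamilySpec()].
#' @param targets optional [genTargets()] output to reuse.
#' @return list with \code{pairs} (an [AptamerTargetSet-class]),
#'   \code{motifs} (per-class strings), \code{motifStarts} (per-class
#'   1-based implant positions) and \code{spec}.
#' @export
genPairs <- function(spec = syntheticFamilySpec(), targets = NULL) {
  # force arguments before seeding: a lazily evaluated targets expression
  # could otherwise consume the stream after set.seed
  force(targets)
  set.seed(spec$seed)
  k <- spec$n_classes; L <- spec$seq_len; m <- spec$motif_length
  if (is.null(targets)) targets <- genTargets(spec)
  motifs <- character(k)
  repeat {
    motifs <- vapply(seq_len(k), function(i) .randomSeq(m), "")
    if (!anyDuplicated(motifs)) break
  }
  maxStart <- L - m + 1L
  motifStarts <- (((seq_len(k) - 1L) * 4L) %% maxStart) + 1L
  n <- spec$n_pairs
  cls <- sample(k, n, replace = TRUE)
  score <- pmin(pmax(rbeta(n, 2, 2) + rnorm(n, 0, spec$score_noise_sd), 0), 1)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- .randomSeq(L)
    if (runif(1) < score[i]) {
      st <- motifStarts[cls[i]]
      substr(s, st, st + m - 1L) <- motifs[cls[i]]
    }
    seqs[i] <- s
  }
  dbs <- vapply(seqs, foldStructure, "", USE.NAMES = FALSE)
  ats <- new("AptamerTargetSet", sequences = seqs, structures = dbs,
             classLabels = as.integer(cls), scores = score,
             targets = attr(targets, "targets"))
  list(pairs = ats, motifs = motifs, motifStarts = motifStarts, spec = spec)
}

#' Simulate SELEX enrichment rounds around a planted binder
#'
#' Round 0 draws \code{pool_size} reads: a \code{plant_frac} fraction as
#' lightly mutated copies of the binder, the rest uniform random. Each
#' subsequent round resamples reads multinomially with probabilities
#' proportional to \code{count * exp(sharpness * fitness)}, where fitness is
#' the negative edit distance to the binder scaled by the read length; a
#' per-base substitution (PCR-error analogue) is then applied. Selection
#' therefore concentrates the pool around the binder family round over
#' round.
#'
#' @param spec a [syntheticSelexSpec()].
#' @return list with \code{rounds} (named list of [PoolRound-class] for the
#'   reported rounds), \code{binder} (ground-truth sequence) and
#'   \code{spec}.
#' @export
simulateSelex <- function(spec = syntheticSelexSpec()) {
  set.seed(spec$seed)
  L <- spec$seq_len
  binder <- spec$binder
  if (is.null(binder)) binder <- .randomSeq(L)
  nPlant <- round(spec$plant_frac * spec$pool_size)
  reads <- c(vapply(seq_len(nPlant), function(i)
    .mutateSeq(binder, spec$plant_mut), ""),
    vapply(seq_len(spec$pool_size - nPlant), function(i) .randomSeq(L), ""))
  tab <- table(reads)
  seqs <- names(tab); counts <- as.integer(tab)
  out <- list()
  maxRound <- max(spec$rounds)
  for (t in seq_len(maxRound)) {
    d <- as.numeric(utils::adist(seqs, binder))
    fitness <- -d / L
    w <- counts * exp(spec$sharpness * fitness)
    newCounts <- as.integer(rmultinom(1, spec$pool_size, w / sum(w)))
    keep <- newCounts > 0L
    seqs <- seqs[keep]; counts <- newCounts[keep]
    if (spec$mutation_rate > 0) {
      pMut <- 1 - (1 - spec$mutation_rate)^L
      mutated <- character(0)
      for (i in seq_along(seqs)) {
        nm <- stats::rbinom(1, counts[i], pMut)
        if (nm > 0L) {
          counts[i] <- counts[i] - nm
          mutated <- c(mutated, vapply(seq_len(nm), function(j)
            .mutateSeq(seqs[i], spec$mutation_rate), ""))
        }
      }
      if (length(mutated)) {
        all <- c(rep(seqs, counts), mutated)
        tab <- table(all)
        seqs <- names(tab); counts <- as.integer(tab)
      } else {
        keep <- counts > 0L
        seqs <- seqs[keep]; counts <- counts[keep]
      }
    }
    if (t %in% spec$rounds)
      out[[paste0("R", t)]] <- new("PoolRound", roundId = t,
                                   sequences = as.character(seqs),
                                   counts = counts)
  }
  list(rounds = out, binder = binder, spec = spec)
}

#' Write all synthetic artifacts for a pipeline run
#'
#' Writes the training-pairs TSV, targets TSV, per-round pool TSVs, the
#' ground-truth binder FASTA and a manifest JSON recording every seed.
#'
#' @param dir output directory (created if needed).
#' @param familySpec a [syntheticFamilySpec()].
#' @param selexSpec a [syntheticSelexSpec()].
#' @return invisibly, the manifest list.
#' @export
writeSyntheticBundle <- function(dir, familySpec = syntheticFamilySpec(),
                                 selexSpec = syntheticSelexSpec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tg <- genTargets(familySpec)
  gp <- genPairs(familySpec, targets = tg)
  sim <- simulateSelex(selexSpec)
  writeTrainingPairs(gp$pairs, file.path(dir, "training_pairs.tsv"))
  utils::write.table(tg, file.path(dir, "targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (nm in names(sim$rounds))
    writePool(sim$rounds[[nm]], file.path(dir, paste0("pool_", nm, ".tsv")))
  writeLines(c(">planted_binder", sim$binder),
             file.path(dir, "truth.fasta"))
  manifest <- list(family_spec = familySpec, selex_spec = selexSpec,
                   motifs = gp$motifs, motif_starts = gp$motifStarts,
                   rounds = names(sim$rounds))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
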