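## Run configuration: flat key=value files with dotted namespaces, a
## strict known-key schema, and deterministic fan-out of one global seed
## into per-stage seeds.

#' Default run configuration
#'
#' Flat named list of every tunable pipeline key, with dotted namespaces
#' per stage. [readRunConfig()] overlays a key=value file onto these
#' defaults and rejects unknown keys.
#'
#' @return named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    outdir = "aptadesign_run",
    `fold.min_loop` = 3L,
    `fold.wobble` = FALSE,
    `embedding.dim` = 64L,
    `embedding.seed` = 1L,
    `fingerprint.bits` = 2048L,
    `fingerprint.radius` = 2L,
    `fingerprint.seed` = 42L,
    `synth.n_classes` = 8L,
    `synth.motif_length` = 10L,
    `synth.seq_len` = 40L,
    `synth.n_pairs` = 195L,
    `synth.score_noise_sd` = 0.05,
    `selex.pool_size` = 2000L,
    `selex.rounds` = "3,5,7",
    `selex.sharpness` = 4,
    `selex.mutation_rate` = 0.002,
    `selex.plant_frac` = 0.02,
    `selex.plant_mut` = 0.05,
    `aptavae.latent_dim` = 256L,
    `aptavae.epochs` = 500L,
    `aptavae.patience` = 50L,
    `aptavae.batch_size` = 16L,
    `aptavae.lr` = 1e-3,
    `aptavae.use3d` = TRUE,
    `aptavae.useSkip` = TRUE,
    `aptavae.useAttention` = TRUE,
    `aptavae.alpha` = 0.3,
    `aptavae.beta` = 0.4,
    `bga.batch_size` = 128L,
    `bga.n_batches` = 50L,
    `bga.threshold` = 0.9,
    `bga.convergence_tolerance` = 0.01,
    `bga.convergence_window` = 5L,
    `library.conservation` = 0.8,
    `library.max_gap_fraction` = 0.5,
    `library.forward_primer` = "",
    `library.reverse_primer` = "",
    `clux.latent_dim` = 256L,
    `clux.epochs` = 300L,
    `clux.patience` = 30L,
    `clux.batch_size` = 64L,
    `clux.lr` = 1e-3,
    `clux.bandwidth` = 0.5,
    `clux.density_fraction` = 0.01,
    `clux.k_clusters` = 10L,
    `kde.pca_dims` = 8L,
    `eval.top_n` = 10L
  )
}

.parseConfigValue <- function(v) {
  v <- trimws(v)
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  n <- suppressWarnings(as.numeric(v))
  if (!is.na(n)) {
    if (n == round(n) && abs(n) < 2^31 && !grepl("[.eE]", v))
      return(as.integer(n))
    return(n)
  }
  v
}

#' Read a run-configuration file
#'
#' Flat text format, one \code{key = value} per line; \code{#} starts a
#' comment; blank lines ignored. Keys use dotted namespaces (e.g.
#' \code{bga.threshold}). Any key absent from [defaultRunConfig()] is an
#' error listing the offending keys.
#'
#' @param path config file, or \code{NULL} for pure defaults.
#' @param overrides optional named list applied after the file (same
#'   schema check).
#' @return named list (full schema, file values overlaid on defaults).
#' @export
readRunConfig <- function(path = NULL, overrides = NULL) {
  cfg <- defaultRunConfig()
  entries <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    bad <- !grepl("=", lines, fixed = TRUE)
    if (any(bad))
      stop("config lines without '=': ",
           paste(sQuote(lines[bad]), collapse = ", "), call. = FALSE)
    keys <- trimws(sub("=.*$", "", lines))
    vals <- sub("^[^=]*=", "", lines)
    entries <- stats::setNames(lapply(vals, .parseConfigValue), keys)
  }
  if (!is.null(overrides)) entries[names(overrides)] <- overrides
  unknown <- setdiff(names(entries), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(entries)] <- entries
  cfg
}

#' Deterministic per-stage seed fan-out
#'
#' Derives an independent, reproducible seed for each pipeline stage from
#' the single global seed by hashing \code{"stage:globalSeed"} (FNV-1a),
#' so stages can be re-run in isolation. The mapping is recorded in run
#' manifests.
#'
#' @param globalSeed integer global seed.
#' @param stage stage name (e.g. \code{"bga"}, \code{"train-aptavae"}).
#' @return integer seed in \code{[1, 2^31 - 2]}.
#' @export
stageSeed <- function(globalSeed, stage) {
  h <- .hash32(paste0(stage, ":", as.integer(globalSeed)))
  as.integer(h %% 2147483645) + 1L
}

#' Parse a comma-separated integer list config value
#' @param v string like \code{"3,5,7"} (or an already-numeric vector).
#' @return integer vector.
#' @export
configIntList <- function(v) {
  if (is.numeric(v)) return(as.integer(v))
  as.integer(strsplit(as.character(v), ",", fixed = TRUE)[[1]])
}
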