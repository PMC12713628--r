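---
title: "Methods: two-VAE aptamer library design and pool summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-VAE aptamer library design and pool summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(AptaDesign)
```

# Overview

AptaDesign implements a two-stage, deep-generative workflow for selecting
DNA aptamers against small-molecule targets:

1. **Library design** (`trainAptaVAE`, `bgaSample`, `consensusTemplate`):
   a conditional variational autoencoder is trained on curated
   aptamer–target pairs — sequence, predicted secondary structure, target
   chemistry and a relative binding score — and then sampled from its
   latent prior. High-scoring decoded sequences are aligned per target
   class and collapsed into a degenerate initial-library template whose
   conserved positions are *confined* (fixed) while the rest stay `N`.
2. **Pool summarization** (`trainAptaClux`, `summarizePool`): after
   (simulated or real) SELEX rounds, a second, unconditional VAE is fitted
   to the unique sequences of an enriched sequencing pool. Two latent
   routes summarize the pool into candidates: the consensus of the
   highest-density latent region (Gaussian KDE) and the consensus of
   decoded k-means cluster centers.

Both models are small multilayer perceptrons trained with analytic
gradients and Adam in plain R (with a C++ kernel for the Adam update), so
the package has no deep-learning framework dependency and every run is
bit-reproducible from a seed.

# Input representations

## Sequence and structure

Sequences are one-hot encoded over `A/C/G/T`; secondary structures are
predicted by the built-in base-pair-maximization folder (`foldStructure`,
a Nussinov dynamic program with a minimum hairpin loop of 3 nt and
optional G·T wobble pairs) and one-hot encoded over `( . )`. The folder is
deliberately simple and deterministic; an external thermodynamic predictor
can replace it through the dot-bracket sidecar contract
(`foldFastaToSidecar`, `readDotBracket`).

## Target chemistry

Targets enter as SMILES strings. `parseSmiles` builds the molecular graph
(atoms, bonds, rings) without external cheminformatics dependencies, and
`describeTarget` derives three views used by the model:

* a **Morgan-style circular fingerprint** (`morganFingerprint`): iterated
  neighborhood hashing folded into a fixed-width bit vector;
* a **distance matrix** (graph-shortest-path) and the **adjacency
  matrix**;
* a **sandwich slab** (`buildSandwich`): the atom one-hots stacked with
  the distance and adjacency matrices into one 3-D tensor, giving the
  encoder a joint geometric/topological target view.

## Modified co-attention

`coAttend` aligns target tokens (queries) with sequence k-mers
(keys/values) through hashed token embeddings and the modified attention
operator

\[
\mathrm{Att}(Q,K,V)=\mathrm{softmax}\!\left(\frac{QK^{\top}}{\sqrt{d_K}}\right)V+\frac{Q}{\sqrt{d_Q}},
\]

i.e. scaled dot-product attention with a scaled residual query term. The
pooled context vector becomes part of the encoder input, and the decoder
reconstructs it as an auxiliary task.

# The library-design VAE

`trainAptaVAE` encodes each pair's concatenated features into a diagonal
Gaussian latent, then decodes the latent (plus an optional skip pathway)
through per-facet heads. The training loss is the sum

```
total = sequence + target + class + 2 * score + attention + matrix + KL
```

with binary cross-entropy for one-hot/bit facets, mean squared error for
the score, attention context and distance facets, and

```
matrix = 0.3 * distance + 0.4 * structure + 0.3 * adjacency
```

for the 3-D slab. The score term is doubled because downstream retention
hinges on score calibration. Every reconstruction term is summed over a
sample's elements and averaged over the batch — the same reduction the KL
uses over latent dimensions. (With per-element means instead, the KL term
dominates by orders of magnitude and the optimum is a collapsed latent.)
The logged history always reports the full (un-annealed) KL, so `total`
reproduces the displayed arithmetic exactly at every epoch.

## Posterior-collapse countermeasures

Three mechanisms, all package design choices, keep the latent informative:

* **KL warm-up** (`klWarmup`): the KL weight ramps linearly from 0 to 1.
* **Skip dropout** (`skipDropout`): the decoder's skip input is zeroed
  per sample with this probability during training, forcing the latent
  (the only pathway available when sampling the prior) to carry the
  signal. Prior-sample decoding always uses the latent-only pathway.
* **Free bits** (`klFreeBits`): per-dimension KL below this floor is
  excluded from the KL *gradient* (the logged loss is unchanged), so the
  optimizer cannot profit from collapsing individual dimensions to the
  prior.

# Batch-generated analysis and library templating

`bgaSample` draws latent batches from the standard normal prior, decodes
them, and retains sequences whose decoded score exceeds the threshold
(default 0.9) together with their predicted class. Running per-batch and
cumulative statistics (mean, SD, retention proportion) feed
`bgaConverged`, a relative-change stability check. An empty retained set
is reported as an explicit `"empty"` status rather than an error.

Retained sequences are assigned to target classes by majority vote over
their nearest training sequences in edit distance
(`assignClassByNeighbors`; the latent class head scores a latent, not the
emitted sequence, and the two can disagree on prior samples), grouped
(`groupAndSort`), filtered toward each class's top-scoring training
binders (`filterByTrainingAnchors`: members beyond the median minimum
edit distance to the class's five highest-scoring training sequences are
dropped, removing the divergent tail without referencing the consensus
being built), stacked by position (`positionalAlignment` — decoder
outputs are positionally comparable by construction, and re-aligning
diverse sets with end-free gaps degenerates toward concatenation),
trimmed of divergent rows (`refineAlignment`: rows whose agreement with
the column plurality falls below the mean are dropped, at most twice),
and collapsed by
`consensusTemplate`: columns with ≥ 50 % gaps are dropped; columns whose
modal base reaches the conservation threshold (default 0.8) are confined;
all others stay `N`. `renderLibrary`/`emitLibrary` format the template
with lowercase flanking primers for synthesis.

# The pool-summarization VAE

`trainAptaClux` autoencodes the unique sequences of an enriched pool
(sequence + predicted structure one-hots) with loss
`sequence + structure + KL`, sharing the warm-up/free-bits machinery.
`summarizePool` then runs both summarization routes on the latent means:

* **High density**: latents are PCA-reduced (default 8 dimensions — an
  isotropic bandwidth of 0.5 in the raw 256-dimensional space would make
  all cross-kernel terms vanish numerically), a Gaussian KDE scores every
  sequence, and the top fraction (default 1 %) is aligned and collapsed
  into one consensus candidate.
* **Cluster consensus**: seeded k-means++ initialization plus Lloyd
  iterations partition the latents (default k = 10); the cluster centers
  are decoded back into sequences and collapsed into a second consensus.

Candidates are named by round and route (e.g. `R3HD`, `R3CC`) and written
with provenance headers. Per-cluster position-wise base counts
(`sequenceLogoCounts`) support logo rendering.

# Evaluation harness and baselines

`editDistance`/`avgEditDistance` (Levenshtein), `pca2d` +
`centroidDistance` (shared-basis PCA centroid geometry) and
`rankingMetrics` (rank-sum AUROC, step-interpolated AUPRC, Top-1) quantify
candidate quality. Conventional NGS analyses provide the comparison
points: `baselineFrequency` (count ranking), `baselineEnrichment`
(round-over-round frequency ratio with pseudocounts) and
`baselineClusterConsensus` (greedy edit-distance clustering).

# Synthetic study system

Because curated affinity datasets and wet-lab SELEX are out of scope, the
package ships a fully seeded simulator:

* `genTargets`/`genPairs`: 8 target classes sharing a fused-ring scaffold
  with small substituents; 195 pairs; per-class 10-nt motifs implanted at
  class-fixed positions with probability equal to the pair's
  Beta(2,2)-distributed score, so motif presence tracks affinity.
* `simulateSelex`: a planted 40-nt binder, 2 % planted mutated copies in
  round 0, fitness-weighted multinomial resampling with
  `exp(4 · (−editDistance/L))` selection and 0.002 per-base mutation,
  reported at rounds 3, 5 and 7.

These defaults constitute the package's reference study conditions; the
unit and acceptance tests run against them unchanged.

# Reproducibility

Every stochastic stage takes an explicit seed; the CLI
(`runAptaDesignCLI`, installed as `exec/aptadesign`) derives per-stage
seeds from one global seed via a recorded hash (`stageSeed`) and writes a
manifest JSON serializing the full configuration next to each stage's
outputs, so any stage can be reproduced bit-identically from its manifest
alone.

```{r, eval = FALSE}
# end-to-end, programmatic
gp  <- genPairs(syntheticFamilySpec(seed = 1))
vae <- trainAptaVAE(gp$pairs, aptaVAEConfig(seed = 1, useSkip = FALSE))
bga <- bgaSample(vae, bgaConfig(seed = 1, n_batches = 100))
cls <- assignClassByNeighbors(bga$retained$sequence, gp$pairs)
grp <- groupAndSort(bga$retained$sequence, cls, bga$retained$score,
                    nClasses = 8)
mem <- filterByTrainingAnchors(grp[["1"]]$sequence, gp$pairs, 1)
tpl <- consensusTemplate(refineAlignment(
  positionalAlignment(mem, width = 40)))
renderLibrary(tpl)
```

# Session info

```{r}
sessionInfo()
```
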