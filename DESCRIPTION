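Package: AptaDesign
Title: Structure-Guided SELEX Library Design and NGS Pool Summarization
    with Variational Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a two-stage variational-autoencoder workflow for
    small-molecule aptamer selection. The first stage learns from
    aptamer-target training pairs (sequence, secondary structure, target
    chemistry, relative binding score) and designs guided initial SELEX
    libraries with confined bases via latent sampling, batch-generated
    analysis and alignment consensus. The second stage summarizes enriched
    SELEX sequencing pools into consensus aptamer candidates by latent
    density estimation and k-means clustering. Includes a built-in
    secondary-structure folder, a small-molecule SMILES encoder with
    circular fingerprints, a modified target-sequence co-attention layer,
    conventional frequency/enrichment/cluster baselines, an evaluation
    harness (edit distance, PCA centroid distance, ranking metrics) and a
    synthetic-data simulator so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Biostrings, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
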