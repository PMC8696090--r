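Package: sccut
Title: Single-Cell CUT&RUN/CUT&Tag Fragment Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of single-cell CUT&RUN/CUT&Tag data starting
    from barcode-tagged fragment files: per-cell quality control (duplicate
    rate, mitochondrial fraction, fragment-size distribution, fraction of
    reads in peaks), aggregate Poisson sliding-window peak calling, feature
    selection (called peaks, genome-wide bins, or user-defined elements),
    binarized feature-by-cell matrix construction with prevalence filtering,
    latent semantic indexing (TF-IDF plus truncated SVD) embedding, k-means
    cell clustering, pseudo-bulk aggregation with bedGraph track generation
    and stringent per-cluster peak calling, and spike-in scale factors. A
    seeded synthetic fragment simulator with ground-truth manifests makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    rtracklayer,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
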