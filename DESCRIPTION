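Package: samsplice
Title: Sparse Adjusted Motif Models of RNA Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An interpretable, modular neural model of RNA splicing built
    from three anchored components: local splice-site identifier (LSSI)
    networks scoring 23-nt acceptor and 9-nt donor windows, fixed-motif (FM)
    scoring of RNA-binding-protein binding affinity from position-specific
    affinity matrices (PSAMs), and an aggregator network that combines both
    into per-position splice-site probabilities. A sparsity bottleneck with
    density annealing caps the information flowing through the motif layer
    (with an analytic entropy bound), and an adjusted-motif (AM) layer tunes
    motif scores end-to-end while constraining their support to
    high-scoring FM sites. Downstream interpretability tooling includes in
    silico knockdowns, RNA maps, regulatory landscapes, eCLIP peak
    enrichment, massively parallel splicing-reporter (MPRA) activity
    statistics, and knockdown sign/magnitude evaluation, together with a
    ground-truthed synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
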