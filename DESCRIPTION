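Package: regionstack
Title: Multi-Scale Region-Set Pileups, Embeddings and Locus-Overlap Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Headless analysis core for exploratory epigenomics around genomic
    region sets. Models point and interval region sets at multiple resolutions
    ("resolution stacks"), extracts and averages 1D coverage and 2D contact-map
    snippets (metaprofiles, aggregate maps, stacked line profiles with coupled
    sorting), builds per-region feature representations embedded with UMAP and
    clustered with k-means, and computes per-bin locus-overlap (LOLA-style)
    odds-ratio enrichment against a genome-wide bin universe. Ships a seeded
    synthetic-data generator (toy genomes, coverage tracks with planted peaks,
    Hi-C-like contact matrices with distance decay, stripes and insulation,
    feature sets with planted positional enrichment) so every analysis is
    testable without downloads, plus a reproducible command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    uwot
Suggests:
    rhdf5,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
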