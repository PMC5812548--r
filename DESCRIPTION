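Package: dynotu
Title: Dynamic Taxon-Dependent Cut-Offs for OTU Clustering of 16S rRNA
    Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains per-family OTU-clustering cut-offs for any 16S rRNA
    amplicon from an aligned type-strain reference database, and clusters
    amplicon reads into operational taxonomic units (OTUs) using those
    dynamic cut-offs instead of a fixed 97% similarity threshold. Includes
    per-column conservation (bit-score) profiling of family alignments,
    extraction of artificial amplicons (variable-region combinations and
    fixed-length sliding windows), one-gap pairwise distances with
    average-neighbor agglomerative clustering, overmerging and
    oversplitting evaluation metrics, and a synthetic-data generator with
    controlled family- and region-specific divergence for testing the
    whole pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
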