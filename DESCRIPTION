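Package: clonoSpat
Title: Immune Repertoire Analytics and Spatial Gene-Pair Coincidence for
    Injured Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing T- and B-cell receptor repertoires and
    spatial transcriptomics of injured tissue. Reads AIRR Rearrangement
    tables and 10x-style filtered contig annotations; computes CDR3 length
    distributions, V-segment usage, positional amino-acid composition and
    chemistry-class profiles, and motif conformity; scores per-clone
    self-reactivity from CDR3 positions 6 and 7 of 13-mer junctions;
    quantifies clonal expansion, shared and treatment-unique clones, and
    cross-tissue clone tracking; computes gene-signature module scores with
    expression-binned control genes and kernel-weighted local Pearson
    coincidence maps for gene pairs on spot lattices, with
    area-above-threshold summaries. Includes seeded synthetic-data
    generators with ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, Spatial, ImmunoOncology, Software
RoxygenNote: 7.3.3
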