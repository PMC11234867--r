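Package: tpsmine
Title: Structural-Model-Based Genome Mining of Non-Canonical Terpene Synthases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-mining pipeline that discovers non-canonical terpene
    synthase (TPS) candidates by structural similarity rather than sequence
    homology. Starting from annotated genomes and per-protein 3D structure
    models, the pipeline locates E-isoprenyl diphosphate synthase (E-IDS)
    anchor genes, extracts hypothetical proteins within a gene-count window
    around each anchor, screens their Calpha models against reference class I,
    IB and IC TPS structures by TM-score after iterative Kabsch superposition,
    excludes sequences resembling known TPSs by Karlin-Altschul E-value,
    clusters survivors into types by pairwise E-value, extracts active-site
    proximity motifs, and builds neighbor-joining trees over homolog sets.
    A synthetic-fixture generator provides genomes, protein families and
    structure models with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    bio3d,
    ape,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Genetics, Alignment, StructuralPrediction, Phylogenetics
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'scoring.R'
    'align.R'
    'genome-io.R'
    'structure-io.R'
    'fixtures.R'
    'superpose.R'
    'motifs.R'
    'neighborhood.R'
    'phylo.R'
    'typing.R'
    'pipeline.R'
    'tpsmine-package.R'
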